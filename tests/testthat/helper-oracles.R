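# Independent oracles used to cross-check the package implementation.
# Deliberately written as plain explicit loops, not shared with R/.

# small random network; the mass/perimeter biases are kept positive so
# toy inputs land in the tension layer's smooth active region
make_toy_net <- function(sizes, seed) {
  set.seed(seed)
  lay <- function(n_in, n_out, b) {
    dense_layer(matrix(runif(n_out * n_in, -0.5, 0.5), n_out, n_in), b)
  }
  pst_network(
    lay(sizes[1], sizes[2], runif(sizes[2], -0.3, 0.3)),
    lay(sizes[2], sizes[3], runif(sizes[3], -0.3, 0.3)),
    lay(sizes[3], 2, c(runif(1, 0.5, 1.5), runif(1, 2, 3))),
    n_inputs = sizes[1]
  )
}

# forward pass as explicit per-neuron loops
oracle_forward <- function(net, x) {
  dense <- function(layer, v) {
    out <- numeric(nrow(layer$weights))
    for (k in seq_along(out)) {
      s <- layer$biases[k]
      for (i in seq_along(v)) s <- s + v[i] * layer$weights[k, i]
      out[k] <- s
    }
    out
  }
  ht <- function(y) 2 / (1 + exp(-2 * y)) - 1
  Y1 <- ht(dense(net$layer1, x))
  Y2 <- ht(dense(net$layer2, Y1))
  Y3 <- dense(net$layer3, Y2)
  m <- Y3[1]; Per <- Y3[2]
  Tk <- net$tension$tensions; g <- net$tension$gravity
  O <- numeric(4)
  for (k in 1:4) O[k] <- 1 - exp(-m * g / (Tk[k] * Per))
  list(Y1 = Y1, Y2 = Y2, m = m, Per = Per, O = O)
}

# central finite differences of the per-sample loss over every parameter
fd_gradients <- function(net, x, lvl, eps = 1e-6) {
  tgt <- encode_risk(lvl)
  lossfn <- function(nn) mse_loss(forward_pass(nn, x)$O, tgt)
  out <- list()
  for (ln in c("layer1", "layer2", "layer3")) {
    for (fld in c("weights", "biases")) {
      ref <- net[[ln]][[fld]]
      grad <- ref
      for (idx in seq_along(ref)) {
        np <- net
        np[[ln]][[fld]][idx] <- ref[idx] + eps
        f_plus <- lossfn(np)
        np[[ln]][[fld]][idx] <- ref[idx] - eps
        f_minus <- lossfn(np)
        grad[idx] <- (f_plus - f_minus) / (2 * eps)
      }
      out[[paste0("d_", ln, "_", substr(fld, 1, 1))]] <- grad
    }
  }
  out
}

# brute-force multi-class ReliefF: per-pair diff and Chebyshev loops
oracle_relieff <- function(X, cls, k) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, max) - apply(X, 2, min)
  dif <- function(a, i, j) if (rng[a] == 0) 0 else abs(X[i, a] - X[j, a]) / rng[a]
  cheb <- function(i, j) {
    mx <- 0
    for (a in seq_len(p)) mx <- max(mx, dif(a, i, j))
    mx
  }
  prior <- tabulate(cls, 4) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) cheb(i, j), numeric(1))
    for (cl in sort(unique(cls))) {
      mem <- setdiff(which(cls == cl), i)
      if (length(mem) == 0) next
      kc <- min(k, length(mem))
      nb <- mem[order(d[mem], mem)][seq_len(kc)]
      for (a in seq_len(p)) {
        s <- sum(vapply(nb, function(j) dif(a, i, j), numeric(1))) / (n * kc)
        if (cl == cls[i]) W[a] <- W[a] - s
        else W[a] <- W[a] + prior[cl] / (1 - prior[cls[i]]) * s
      }
    }
  }
  W
}

# AUC as the exhaustive pairwise-comparison statistic, ties counted 1/2
auc_pairwise <- function(score, pos) {
  sp <- score[pos]; sn <- score[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a normalized 20-input cohort ready for training, built once per run
separable_training_cohort <- function(n = 400, effect = 5, seed = 2) {
  co <- generate_cohort(cohort_spec(n_subjects = n, effect_size = effect,
                                    seed = seed))
  con <- apply_normalization(co, fit_normalization(co))
  suppressWarnings(select_inputs(relieff_weights(con, k = 10), con))
}
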