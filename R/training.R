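#' Mean squared error of one output against its target pattern
#'
#' `sum((O_k - E_k)^2) / 2` — the per-sample training loss. The divisor
#' is 2 (half the summed squared error), not the number of outputs.
#'
#' @param O Numeric vector of four tension activations.
#' @param target A [encode_risk()] target, an integer level in 1..4, or a
#'   binary pattern vector of length 4.
#' @return Non-negative scalar loss.
#' @export
mse_loss <- function(O, target) {
  E <- target_pattern(target)
  sum((O - E)^2) / 2
}

target_pattern <- function(target) {
  if (inherits(target, "risk_target")) return(target$pattern)
  if (length(target) == 1) return(encode_risk(target)$pattern)
  if (length(target) == 4) return(as.numeric(target))
  stop_pstnn("invalid_label", "cannot interpret target of length %d", length(target))
}

target_levels <- function(targets) {
  if (is.list(targets)) {
    vapply(targets, function(t) {
      if (inherits(t, "risk_target")) t$level else encode_risk(t)$level
    }, integer(1))
  } else {
    vapply(as.numeric(targets), function(t) encode_risk(t)$level, integer(1))
  }
}

empty_gradients <- function(net) {
  structure(list(
    d_layer1_w = net$layer1$weights * 0, d_layer1_b = net$layer1$biases * 0,
    d_layer2_w = net$layer2$weights * 0, d_layer2_b = net$layer2$biases * 0,
    d_layer3_w = net$layer3$weights * 0, d_layer3_b = net$layer3$biases * 0
  ), class = "pst_gradients")
}

#' Backpropagate the loss through one forward trace
#'
#' Applies the analytic derivative chain of the surface-tension network
#' to a single sample: the error signal at the outputs is `O_k - E_k`;
#' it flows into the mass through `dO_k/dm = (g / (T_k Per)) exp(-m g /
#' (T_k Per))` and into the perimeter through `dO_k/dPer = (-m g /
#' (T_k Per^2)) exp(-m g / (T_k Per))`, summed over the four tension
#' neurons; the tanh layers contribute the factor `1 - Y^2`; weight and
#' bias partials follow by the chain rule. The exponential reuses the
#' clamped exponent of the forward pass.
#'
#' @param net A [pst_network()].
#' @param trace A `"forward_trace"` produced by [forward_pass()] on
#'   `net` for the same input.
#' @param target Target as accepted by [mse_loss()].
#' @return An object of class `"pst_gradients"` whose fields mirror the
#'   network parameter layout.
#' @export
backprop_sample <- function(net, trace, target) {
  if (!inherits(trace, "forward_trace")) {
    stop_pstnn("shape", "`trace` must come from forward_pass()")
  }
  if (any(!vapply(trace, function(v) all(is.finite(v)), logical(1)))) {
    stop_pstnn("invalid_output", "trace contains non-finite values")
  }
  E <- target_pattern(target)
  g <- net$tension$gravity
  Tk <- net$tension$tensions
  m <- trace$Y3[["m"]]; Per <- trace$Y3[["Per"]]
  if (Per == 0) stop_pstnn("degenerate_geometry", "perimeter is zero")

  dO <- trace$O - E
  z <- -m * g / (Tk * Per)
  ez <- ifelse(abs(z) < EXP_CLAMP, exp(z), 0)   # flat outside the clamp
  dm <- sum(dO * (g / (Tk * Per)) * ez)
  dPer <- sum(dO * (-m * g / (Tk * Per^2)) * ez)

  delta3 <- c(dm, dPer)
  dW3 <- delta3 %o% trace$Y2
  db3 <- delta3

  dY2 <- drop(crossprod(net$layer3$weights, delta3))
  delta2 <- dY2 * (1 - trace$Y2^2)
  dW2 <- delta2 %o% trace$Y1
  db2 <- delta2

  dY1 <- drop(crossprod(net$layer2$weights, delta2))
  delta1 <- dY1 * (1 - trace$Y1^2)
  dW1 <- delta1 %o% trace$input
  db1 <- delta1

  structure(list(d_layer1_w = dW1, d_layer1_b = db1,
                 d_layer2_w = dW2, d_layer2_b = db2,
                 d_layer3_w = dW3, d_layer3_b = db3),
            class = "pst_gradients")
}

#' Mean gradient and loss over a batch
#'
#' Averages the per-sample gradients and losses over the rows of `X`.
#' Implemented with matrix operations; agrees with averaging
#' [backprop_sample()] calls to within rounding.
#'
#' @param net A [pst_network()].
#' @param X Numeric matrix, subjects in rows.
#' @param targets Integer vector of risk levels or list of
#'   [encode_risk()] targets, one per row.
#' @return List with `gradients` (a `"pst_gradients"`) and `mean_mse`.
#' @export
batch_gradient <- function(net, X, targets) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop_pstnn("empty_input", "batch is empty")
  lev <- target_levels(targets)
  if (length(lev) != n) {
    stop_pstnn("shape", "%d targets for %d rows", length(lev), n)
  }
  fb <- forward_batch(net, X)
  gradients_from_forward(net, X, lev, fb)
}

# backpropagation over a batch from an existing forward_batch() result
gradients_from_forward <- function(net, X, lev, fb) {
  n <- nrow(X)
  Epat <- risk_patterns()[lev, , drop = FALSE]
  D <- fb$O - Epat                                   # n x 4 output error
  g <- net$tension$gravity; Tk <- net$tension$tensions
  Gm <- sweep(fb$EZg, 2, g / Tk, "*") / fb$Per       # dO/dm
  dm <- rowSums(D * Gm)
  dPer <- rowSums(D * sweep(fb$EZg, 2, g / Tk, "*") * (-fb$m / fb$Per^2))
  Delta3 <- cbind(dm, dPer)

  dW3 <- crossprod(Delta3, fb$Y2) / n
  db3 <- colMeans(Delta3)
  Delta2 <- (Delta3 %*% net$layer3$weights) * (1 - fb$Y2^2)
  dW2 <- crossprod(Delta2, fb$Y1) / n
  db2 <- colMeans(Delta2)
  Delta1 <- (Delta2 %*% net$layer2$weights) * (1 - fb$Y1^2)
  dW1 <- crossprod(Delta1, X) / n
  db1 <- colMeans(Delta1)

  grads <- structure(list(d_layer1_w = dW1, d_layer1_b = db1,
                          d_layer2_w = dW2, d_layer2_b = db2,
                          d_layer3_w = unname(dW3), d_layer3_b = unname(db3)),
                     class = "pst_gradients")
  list(gradients = grads, mean_mse = mean(rowSums(D^2) / 2))
}

#' Training configuration
#'
#' The optimizer stops at the first of: gradient norm below
#' `gradient_tolerance` (default 1e-6), mean training MSE at or below
#' `mse_goal` (default 0, i.e. only exact fits qualify), or
#' `max_iterations` (default 300).
#'
#' @param max_iterations Maximum conjugate-gradient iterations.
#' @param gradient_tolerance Euclidean-norm stop threshold on the mean
#'   gradient.
#' @param mse_goal Target mean training MSE.
#' @param seed Integer recorded with the run (training itself is
#'   deterministic given the initial network and data).
#' @param cg_variant Conjugate-direction update; only `"polak_ribiere"`.
#' @param line_search Step-size rule; only `"armijo"` backtracking with
#'   initial step `armijo_initial`, shrink factor `armijo_shrink` and
#'   sufficient-decrease constant `armijo_c`.
#' @param armijo_initial,armijo_shrink,armijo_c Armijo parameters.
#' @param max_direction_norm Cap on the Euclidean norm of the search
#'   direction handed to the line search, bounding the per-iteration
#'   parameter displacement. The surface-tension exponent can make
#'   gradients astronomically large (a near-zero perimeter for one
#'   sample); capping the direction keeps the Armijo threshold finite
#'   and prevents a single wild step from overshooting samples toward
#'   the activation's pole at zero perimeter.
#' @param boundary_margin Samples whose |perimeter| is below this are
#'   treated as sitting against the activation's pole; their
#'   perimeter-gradients are projected out of the search direction (see
#'   Details in [pst_train()]).
#' @param max_boundary_set At most this many near-pole samples are
#'   projected out per iteration (the nearest ones).
#' @param verbose Emit one message per iteration.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(max_iterations = 300L, gradient_tolerance = 1e-6,
                         mse_goal = 0, seed = 0L,
                         cg_variant = "polak_ribiere", line_search = "armijo",
                         armijo_initial = 1.0, armijo_shrink = 0.5,
                         armijo_c = 1e-4, max_direction_norm = 1,
                         boundary_margin = 1e-2, max_boundary_set = 60L,
                         verbose = FALSE) {
  cg_variant <- match.arg(cg_variant)
  line_search <- match.arg(line_search)
  if (max_iterations < 0 || gradient_tolerance < 0 || mse_goal < 0) {
    stop_pstnn("invalid_architecture",
               "iterations and tolerances must be non-negative")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance, mse_goal = mse_goal,
                 seed = as.integer(seed), cg_variant = cg_variant,
                 line_search = line_search, armijo_initial = armijo_initial,
                 armijo_shrink = armijo_shrink, armijo_c = armijo_c,
                 max_direction_norm = max_direction_norm,
                 boundary_margin = boundary_margin,
                 max_boundary_set = as.integer(max_boundary_set),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

flatten_params <- function(net) {
  c(as.vector(net$layer1$weights), net$layer1$biases,
    as.vector(net$layer2$weights), net$layer2$biases,
    as.vector(net$layer3$weights), net$layer3$biases)
}

flatten_gradients <- function(gr) {
  c(as.vector(gr$d_layer1_w), gr$d_layer1_b,
    as.vector(gr$d_layer2_w), gr$d_layer2_b,
    as.vector(gr$d_layer3_w), gr$d_layer3_b)
}

# writes a flat parameter vector back into a network of the same shape;
# skips constructor validation (shapes are preserved by construction)
unflatten_params <- function(theta, net) {
  pos <- 0L
  take <- function(k) {
    v <- theta[(pos + 1L):(pos + k)]
    pos <<- pos + k
    v
  }
  for (nm in c("layer1", "layer2", "layer3")) {
    net[[nm]]$weights[] <- take(length(net[[nm]]$weights))
    net[[nm]]$biases <- take(length(net[[nm]]$biases))
  }
  net
}

#' Train a surface-tension network by conjugate gradient
#'
#' Full-batch training: each iteration computes the mean gradient over
#' all training rows, forms a Polak-Ribiere conjugate direction
#' (restarting to steepest descent whenever the direction fails to be a
#' descent direction, or after one restart cycle per parameter count),
#' chooses the step by Armijo backtracking, and updates every weight and
#' bias. Training loss never increases across accepted iterations.
#'
#' @details
#' The tension activation `1 - exp(-m g / (T_k Per))` has a pole at
#' `Per = 0`, and the cumulative all-ones target of the highest risk
#' level pulls well-fit samples toward it (their optimum is an infinite
#' exponent). A sample sitting just above the pole would veto every
#' step with a component on its perimeter — crossing the pole explodes
#' the loss, so the line search would pin the step near zero. The
#' optimizer therefore projects the search direction onto the
#' complement of the perimeter-gradients of near-pole samples
#' (`boundary_margin`, `max_boundary_set`), an active-set strategy that
#' freezes those samples' perimeters and lets everything else continue
#' to move.
#'
#' @param net Initial [pst_network()] (see [init_nguyen_widrow()]).
#' @param X Numeric training matrix, subjects in rows, normalized
#'   features in columns.
#' @param targets Risk levels (integer vector in 1..4) or list of
#'   [encode_risk()] targets.
#' @param config A [train_config()].
#' @param test_X,test_targets Optional held-out set whose mean MSE is
#'   recorded per iteration (never used for stopping).
#' @return List with `network` (trained) and `history`, a
#'   `"train_history"` data frame (iteration, mse, test_mse,
#'   gradient_norm, step) whose `stop_reason` attribute is one of
#'   `"gradient"`, `"goal"`, `"max_iterations"`, `"line_search"`.
#' @export
pst_train <- function(net, X, targets, config = train_config(),
                      test_X = NULL, test_targets = NULL) {
  X <- as.matrix(X)
  lev <- target_levels(targets)
  test_lev <- if (!is.null(test_X)) target_levels(test_targets)
  n_par <- n_parameters(net)
  theta <- flatten_params(net)

  # trial points where a sample's perimeter is exactly zero are treated
  # as infinitely bad rather than an error: the line search backs off
  objective <- function(th) {
    tryCatch({
      fb <- forward_batch(unflatten_params(th, net), X)
      Epat <- risk_patterns()[lev, , drop = FALSE]
      mean(rowSums((fb$O - Epat)^2) / 2)
    }, pstnn_error_degenerate_geometry = function(e) Inf)
  }
  test_mse <- function(th) {
    if (is.null(test_X)) return(NA_real_)
    fb <- forward_batch(unflatten_params(th, net), test_X)
    mean(rowSums((fb$O - risk_patterns()[test_lev, , drop = FALSE])^2) / 2)
  }

  hist <- vector("list", config$max_iterations)
  stop_reason <- "max_iterations"
  d <- NULL; g_prev <- NULL
  since_restart <- 0L
  n_hist <- 0L
  iter <- 0L

  while (iter < config$max_iterations) {
    net_cur <- unflatten_params(theta, net)
    fb <- forward_batch(net_cur, X)
    bg <- gradients_from_forward(net_cur, X, lev, fb)
    g <- flatten_gradients(bg$gradients)
    f0 <- bg$mean_mse
    if (!all(is.finite(g))) {
      stop_pstnn("divergence", "non-finite gradient at iteration %d", iter + 1L)
    }
    gnorm <- safe_norm(g)
    if (gnorm < config$gradient_tolerance) { stop_reason <- "gradient"; break }
    if (f0 <= config$mse_goal) { stop_reason <- "goal"; break }

    # Polak-Ribiere+ direction with restarts
    if (is.null(d) || since_restart >= n_par) {
      d <- -g; since_restart <- 0L
    } else {
      beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev^2))
      if (!is.finite(beta)) beta <- 0
      d <- -g + beta * d
      if (!all(is.finite(d)) || safe_dot(d, g) >= 0) { d <- -g; since_restart <- 0L }
    }

    # Boundary projection: the tension activation has a pole at Per = 0,
    # and well-fit high-risk samples settle just above it. A step with
    # any component on such a sample's perimeter would cross the pole
    # and be rejected, pinning the line search; orthogonalizing the
    # direction against those samples' perimeter-gradients lets the
    # remaining parameters keep moving.
    parked <- which(abs(fb$Per) < config$boundary_margin)
    if (length(parked) > 0) {
      parked <- parked[order(abs(fb$Per[parked]))]
      parked <- parked[seq_len(min(length(parked), config$max_boundary_set))]
      A <- vapply(parked, function(i) {
        perimeter_gradient(net_cur, X[i, ], fb$Y1[i, ], fb$Y2[i, ])
      }, numeric(length(theta)))
      Q <- qr.Q(qr(matrix(A, ncol = length(parked))))
      d <- d - as.numeric(Q %*% crossprod(Q, d))
      if (!all(is.finite(d)) || safe_dot(d, g) >= 0) { d <- -g; since_restart <- 0L }
    }

    dnorm <- safe_norm(d)
    if (dnorm > config$max_direction_norm) {
      d <- d * (config$max_direction_norm / dnorm)
    }

    ls <- armijo_search(objective, theta, f0, g, d, config)
    if (is.null(ls) && since_restart > 0L) { # retry along steepest descent
      d <- -g; since_restart <- 0L
      dnorm <- safe_norm(d)
      if (dnorm > config$max_direction_norm) {
        d <- d * (config$max_direction_norm / dnorm)
      }
      ls <- armijo_search(objective, theta, f0, g, d, config)
    }
    if (is.null(ls)) { stop_reason <- "line_search"; break }

    theta <- theta + ls$eta * d
    if (!is.finite(ls$f)) {
      stop_pstnn("divergence", "non-finite loss at iteration %d", iter + 1L)
    }
    g_prev <- g
    since_restart <- since_restart + 1L
    iter <- iter + 1L
    n_hist <- n_hist + 1L
    hist[[n_hist]] <- data.frame(iteration = iter, mse = ls$f,
                                 test_mse = test_mse(theta),
                                 gradient_norm = gnorm, step = ls$eta)
    if (config$verbose) {
      message(sprintf("iter %3d  mse %.6g  |grad| %.3g  step %.3g",
                      iter, ls$f, gnorm, ls$eta))
    }
  }

  history <- if (n_hist > 0) do.call(rbind, hist[seq_len(n_hist)]) else
    data.frame(iteration = integer(), mse = numeric(), test_mse = numeric(),
               gradient_norm = numeric(), step = numeric())
  attr(history, "stop_reason") <- stop_reason
  class(history) <- c("train_history", "data.frame")
  list(network = unflatten_params(theta, net), history = history)
}

# gradient of one sample's perimeter (layer-3 neuron 2) with respect to
# every parameter, flattened in parameter order; used by the boundary
# projection
perimeter_gradient <- function(net, x, Y1, Y2) {
  dW3 <- rbind(0, Y2)
  db3 <- c(0, 1)
  delta2 <- net$layer3$weights[2, ] * (1 - Y2^2)
  dW2 <- delta2 %o% Y1
  delta1 <- drop(crossprod(net$layer2$weights, delta2)) * (1 - Y1^2)
  dW1 <- delta1 %o% x
  c(as.vector(dW1), delta1, as.vector(dW2), delta2, as.vector(dW3), db3)
}

# overflow-safe Euclidean norm and dot product (entries can reach 1e200+
# in the clamped-exponent regime; naive sums of squares overflow)
safe_norm <- function(v) {
  m <- max(abs(v))
  if (m == 0 || !is.finite(m)) return(m)
  m * sqrt(sum((v / m)^2))
}

safe_dot <- function(a, b) {
  s <- sum(a * b)
  if (is.finite(s)) return(s)
  m <- max(abs(a))
  m * sum((a / m) * b)
}

# Armijo backtracking; returns list(eta, f) or NULL when no acceptable
# step exists. When the sufficient-decrease threshold is non-finite
# (astronomical initial losses/gradients), falls back to simple decrease.
# Backtracking gives up once the best possible decrease along the
# direction (eta * |slope|) falls below rounding relative to f0: smaller
# steps could not change the loss measurably.
armijo_search <- function(objective, theta, f0, g, d, config) {
  slope <- safe_dot(g, d)
  if (slope >= 0) return(NULL)
  floor_eta <- 1e-20 * max(min(abs(f0), 1e250), 1) / max(abs(slope), 1)
  floor_eta <- max(floor_eta, 1e-300)
  eta <- config$armijo_initial
  while (eta >= floor_eta) {
    f_new <- objective(theta + eta * d)
    thr <- f0 + config$armijo_c * eta * slope
    ok <- if (is.finite(f_new) && is.finite(thr)) f_new <= thr
          else is.finite(f_new) && f_new < f0
    if (ok) return(list(eta = eta, f = f_new))
    eta <- eta * config$armijo_shrink
  }
  # step pinned by a sample sitting against the Per = 0 wall: accept the
  # floor step if it at least does not increase the loss, so later
  # iterations can wiggle into unpinned directions
  f_new <- objective(theta + floor_eta * d)
  if (is.finite(f_new) && f_new <= f0) return(list(eta = floor_eta, f = f_new))
  NULL
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("Training history: %d iterations, stopped on '%s'\n",
              nrow(x), attr(x, "stop_reason")))
  if (nrow(x) > 0) {
    cat(sprintf("  final mse %.6g, final |grad| %.3g\n",
                x$mse[nrow(x)], x$gradient_norm[nrow(x)]))
  }
  invisible(x)
}
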