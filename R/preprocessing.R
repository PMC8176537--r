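#' Cohort container
#'
#' A cohort is a numeric feature matrix (subjects in rows), a group tag
#' per column — psychosocial, physiological or musculoskeletal — and an
#' ordinal risk label in 1..4 per subject. Column names carry the group
#' as a prefix (`psy_`, `phys_`, `msk_`) in the CSV dialect.
#'
#' @param features Numeric matrix with column names; no missing values.
#' @param groups Character vector, one of `"psychosocial"`,
#'   `"physiological"`, `"musculoskeletal"` per column. Defaults to
#'   parsing the column-name prefixes.
#' @param labels Integer vector of risk levels in 1..4, one per row.
#' @param normalized Whether the features have been min-max scaled.
#' @return An object of class `"risk_cohort"`.
#' @export
risk_cohort <- function(features, groups = NULL, labels, normalized = FALSE) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features)) {
    stop_pstnn("parse", "features must be numeric with no missing values")
  }
  if (is.null(colnames(features))) {
    stop_pstnn("parse", "feature columns must be named")
  }
  if (is.null(groups)) groups <- groups_from_prefix(colnames(features))
  valid <- c("psychosocial", "physiological", "musculoskeletal")
  if (length(groups) != ncol(features) || !all(groups %in% valid)) {
    stop_pstnn("parse", "every column needs a group tag in {%s}",
               paste(valid, collapse = ", "))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(features) || anyNA(labels) ||
      any(labels < 1 | labels > 4)) {
    stop_pstnn("invalid_label", "labels must be integers in 1..4, one per subject")
  }
  structure(list(features = features, groups = groups, labels = labels,
                 normalized = isTRUE(normalized)),
            class = "risk_cohort")
}

groups_from_prefix <- function(nm) {
  g <- rep(NA_character_, length(nm))
  g[startsWith(nm, "psy_")] <- "psychosocial"
  g[startsWith(nm, "phys_")] <- "physiological"
  g[startsWith(nm, "msk_")] <- "musculoskeletal"
  if (anyNA(g)) {
    stop_pstnn("parse", "cannot infer group for column(s): %s",
               paste(nm[is.na(g)], collapse = ", "))
  }
  g
}

#' @export
print.risk_cohort <- function(x, ...) {
  cat(sprintf("Risk cohort: %d subjects x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  groups: %d psychosocial, %d physiological, %d musculoskeletal\n",
              sum(x$groups == "psychosocial"), sum(x$groups == "physiological"),
              sum(x$groups == "musculoskeletal")))
  cat("  risk levels: ", paste(sprintf("%d:%d", 1:4, tabulate(x$labels, 4)),
                               collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Fit per-feature min-max normalization parameters
#'
#' Extracts each feature's minimum and maximum. Fit these on the
#' training partition only, then apply them to both partitions, so no
#' information from held-out subjects leaks into the scaling. Constant
#' features (max equal to min) are flagged; they normalize to 0.
#'
#' @param cohort A [risk_cohort()].
#' @return An object of class `"normalization_params"` with fields
#'   `feature`, `min`, `max`, `constant`.
#' @export
fit_normalization <- function(cohort) {
  stopifnot(inherits(cohort, "risk_cohort"))
  if (nrow(cohort$features) == 0) stop_pstnn("empty_input", "empty cohort")
  mn <- apply(cohort$features, 2, min)
  mx <- apply(cohort$features, 2, max)
  structure(list(feature = colnames(cohort$features), min = unname(mn),
                 max = unname(mx), constant = unname(mx <= mn)),
            class = "normalization_params")
}

#' Min-max scale values
#'
#' `(E - E_min) / (E_max - E_min)`: training-range values map into
#' \[0, 1\]; out-of-range values extrapolate linearly (they are not
#' clipped); a constant feature maps to 0.
#'
#' @param x Numeric vector.
#' @param fmin,fmax Feature minimum and maximum from the training data.
#' @return Scaled numeric vector.
#' @export
minmax_scale <- function(x, fmin, fmax) {
  if (fmax <= fmin) return(rep(0, length(x)))
  (x - fmin) / (fmax - fmin)
}

#' Apply fitted normalization to a cohort
#'
#' @param cohort A [risk_cohort()].
#' @param params A [fit_normalization()] result; features are matched by
#'   name and must all be present.
#' @return The normalized cohort (`normalized = TRUE`).
#' @export
apply_normalization <- function(cohort, params) {
  stopifnot(inherits(cohort, "risk_cohort"),
            inherits(params, "normalization_params"))
  idx <- match(colnames(cohort$features), params$feature)
  if (anyNA(idx)) {
    stop_pstnn("parse", "normalization parameters missing for: %s",
               paste(colnames(cohort$features)[is.na(idx)], collapse = ", "))
  }
  f <- cohort$features
  for (j in seq_len(ncol(f))) {
    f[, j] <- minmax_scale(f[, j], params$min[idx[j]], params$max[idx[j]])
  }
  risk_cohort(f, cohort$groups, cohort$labels, normalized = TRUE)
}

#' ReliefF predictor weights with Chebyshev-metric neighbors
#'
#' Multi-class ReliefF (Robnik-Sikonja & Kononenko): every sampled
#' subject `R_i` contributes a penalty for each of its `k` nearest
#' same-class neighbors (hits) and a prior-weighted reward for each of
#' its `k` nearest neighbors in every other class (misses):
#' `W[A] <- W[A] - sum_j diff(A, R_i, H_j) / (m k)
#'               + sum_{C != class(R_i)} P(C)/(1 - P(class(R_i)))
#'                 * sum_j diff(A, R_i, M_j(C)) / (m k)`
#' where `diff` is the absolute difference of range-normalized values
#' and neighbors are found under the Chebyshev (L-infinity) metric.
#' Distance and weight ties are broken toward the lower subject index.
#'
#' @param cohort A normalized [risk_cohort()].
#' @param k Number of neighbors per class (default 10). Classes with
#'   fewer than `k` available neighbors use all of them, with a warning.
#' @param n_sampled Number of subjects sampled as `R_i`; default all
#'   subjects, processed in order (fully deterministic).
#' @param seed Seed for subject sampling when `n_sampled` is less than
#'   the cohort size.
#' @return An object of class `"relieff_weights"`: list with `weights`
#'   (named per feature), `k`, `n_sampled`.
#' @export
relieff_weights <- function(cohort, k = 10L, n_sampled = NULL, seed = 0L) {
  stopifnot(inherits(cohort, "risk_cohort"))
  if (!cohort$normalized) {
    warning("ReliefF expects normalized features; distances may be dominated by large-range columns")
  }
  X <- cohort$features
  n <- nrow(X)
  cls <- cohort$labels
  if (is.null(n_sampled) || n_sampled >= n) {
    samp <- seq_len(n)
  } else {
    set.seed(seed)
    samp <- sort(sample.int(n, n_sampled))
  }
  m <- length(samp)

  rng <- apply(X, 2, max) - apply(X, 2, min)
  Xd <- X
  Xd[, rng > 0] <- sweep(X[, rng > 0, drop = FALSE], 2, rng[rng > 0], "/")
  Xd[, rng == 0] <- 0                      # constant feature: diff always 0

  prior <- tabulate(cls, 4) / n
  classes <- which(tabulate(cls, 4) > 0)
  by_class <- lapply(1:4, function(c) which(cls == c))
  W <- numeric(ncol(X))
  warned <- FALSE

  for (i in samp) {
    # Chebyshev distance from subject i to everyone (on scaled features)
    A <- abs(sweep(Xd, 2, Xd[i, ], "-"))
    d <- A[, 1]
    for (j in seq_len(ncol(A))[-1]) d <- pmax(d, A[, j])

    for (c in classes) {
      members <- by_class[[c]]
      if (c == cls[i]) members <- members[members != i]
      if (length(members) == 0) next
      kc <- min(k, length(members))
      if (kc < k && !warned) {
        warning(sprintf("class %d has only %d neighbors available; using k = %d",
                        c, length(members), kc))
        warned <- TRUE
      }
      nb <- members[order(d[members], members)][seq_len(kc)]
      contrib <- colSums(A[nb, , drop = FALSE]) / (m * kc)
      if (c == cls[i]) {
        W <- W - contrib
      } else {
        W <- W + prior[c] / (1 - prior[cls[i]]) * contrib
      }
    }
  }
  structure(list(weights = stats::setNames(W, colnames(X)),
                 k = as.integer(k), n_sampled = m),
            class = "relieff_weights")
}

#' Select the network's input columns
#'
#' Keeps the `n_psychosocial` psychosocial columns with the largest
#' ReliefF weights (weight ties broken toward the lower column index)
#' and all physiological and musculoskeletal columns. With the defaults
#' (12 psychosocial + 3 physiological + 5 musculoskeletal) the result has
#' 20 input variables.
#'
#' @param weights A [relieff_weights()] computed on `cohort`.
#' @param cohort A [risk_cohort()].
#' @param n_psychosocial Number of psychosocial columns to retain.
#' @return The reduced cohort, with attribute `"selected_columns"`.
#' @export
select_inputs <- function(weights, cohort, n_psychosocial = 12L) {
  stopifnot(inherits(weights, "relieff_weights"), inherits(cohort, "risk_cohort"))
  psy <- which(cohort$groups == "psychosocial")
  if (length(psy) < n_psychosocial) {
    stop_pstnn("selection", "requested %d psychosocial columns but cohort has %d",
               n_psychosocial, length(psy))
  }
  w <- weights$weights[match(colnames(cohort$features)[psy], names(weights$weights))]
  if (anyNA(w)) stop_pstnn("selection", "weights missing for some psychosocial columns")
  keep_psy <- psy[order(-w, seq_along(psy))][seq_len(n_psychosocial)]
  keep <- sort(c(keep_psy, which(cohort$groups != "psychosocial")))
  out <- risk_cohort(cohort$features[, keep, drop = FALSE],
                     cohort$groups[keep], cohort$labels,
                     normalized = cohort$normalized)
  attr(out, "selected_columns") <- colnames(cohort$features)[keep]
  out
}

#' Stratified train/test split
#'
#' Partitions a cohort into disjoint, exhaustive training and test sets.
#' By default the split is stratified by risk level: each class
#' contributes a share of the training set proportional to its size
#' (largest-remainder apportionment so the overall training size is
#' exactly `round(train_fraction * n)`).
#'
#' @param cohort A [risk_cohort()].
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param stratified Stratify by risk level (default TRUE).
#' @return List with elements `train` and `test`, each a [risk_cohort()]
#'   carrying its row indices in attribute `"indices"`.
#' @export
split_train_test <- function(cohort, train_fraction = 0.8, seed = 0L,
                             stratified = TRUE) {
  stopifnot(inherits(cohort, "risk_cohort"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_pstnn("invalid_architecture", "train_fraction must be in (0, 1)")
  }
  n <- nrow(cohort$features)
  n_train <- round(train_fraction * n)
  set.seed(seed)
  if (stratified) {
    counts <- tabulate(cohort$labels, 4)
    present <- which(counts > 0)
    if (any(counts[present] < 2)) {
      stop_pstnn("degenerate_split",
                 "stratified split needs at least 2 subjects per class")
    }
    quota <- integer(4)
    quota[present] <- largest_remainder(counts[present], n_train)
    train_idx <- unlist(lapply(present, function(c) {
      members <- which(cohort$labels == c)
      sample(members, quota[c])
    }), use.names = FALSE)
  } else {
    train_idx <- sample.int(n, n_train)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_rows <- function(idx) {
    out <- risk_cohort(cohort$features[idx, , drop = FALSE], cohort$groups,
                       cohort$labels[idx], normalized = cohort$normalized)
    attr(out, "indices") <- idx
    out
  }
  list(train = subset_rows(train_idx), test = subset_rows(test_idx))
}

#' Read a cohort from CSV
#'
#' Expects a header with `psy_`/`phys_`/`msk_`-prefixed feature columns
#' and a final `risk_level` column in 1..4.
#'
#' @param path CSV path.
#' @return A [risk_cohort()] (`normalized = FALSE`).
#' @export
read_cohort <- function(path) {
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop_pstnn("parse", "cannot read '%s': %s",
                                                path, conditionMessage(e)))
  if (!"risk_level" %in% names(df)) {
    stop_pstnn("parse", "'%s' has no 'risk_level' column", path)
  }
  feats <- df[, setdiff(names(df), "risk_level"), drop = FALSE]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad)) {
    stop_pstnn("parse", "non-numeric feature column(s): %s", paste(bad, collapse = ", "))
  }
  risk_cohort(as.matrix(feats), labels = df$risk_level)
}

#' Write a cohort to CSV
#'
#' @param cohort A [risk_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "risk_cohort"))
  df <- as.data.frame(cohort$features)
  df$risk_level <- cohort$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
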