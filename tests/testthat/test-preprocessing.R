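make_cohort <- function(X, labels) {
  colnames(X) <- paste0("psy_", seq_len(ncol(X)))
  risk_cohort(X, labels = labels)
}

test_that("min-max normalization: extrema, degenerate features, determinism", {
  X <- cbind(c(2, 4, 6), c(1, 1, 1))
  co <- make_cohort(X, c(1, 2, 3))
  p <- fit_normalization(co)
  expect_equal(p$min, c(2, 1))
  expect_equal(p$max, c(6, 1))
  expect_equal(p$constant, c(FALSE, TRUE))
  expect_equal(minmax_scale(c(2, 6, 4), 2, 6), c(0, 1, 0.5))
  expect_equal(minmax_scale(c(0, 5), 1, 1), c(0, 0))    # constant maps to 0
  # out-of-range values extrapolate linearly, not clipped
  expect_equal(minmax_scale(8, 2, 6), 1.5)
  expect_identical(p, fit_normalization(co))
  single <- fit_normalization(make_cohort(matrix(3, 1, 1), 2))
  expect_true(single$constant)
  norm <- apply_normalization(co, p)
  expect_true(norm$normalized)
  expect_equal(unname(norm$features[, 1]), c(0, 0.5, 1))
  expect_equal(unname(norm$features[, 2]), c(0, 0, 0))
})

test_that("every non-constant feature normalizes onto [0, 1] hitting both ends", {
  co <- generate_cohort(cohort_spec(n_subjects = 80, seed = 4))
  norm <- apply_normalization(co, fit_normalization(co))
  expect_true(all(norm$features >= 0 & norm$features <= 1))
  expect_true(all(abs(apply(norm$features, 2, min)) < 1e-12))
  expect_true(all(abs(apply(norm$features, 2, max) - 1) < 1e-12))
})

test_that("ReliefF weights: constant features, informative vs noise", {
  # 8 subjects, 2 classes; feature 1 = class indicator, feature 2 = noise,
  # feature 3 constant
  set.seed(11)
  cls <- rep(1:2, each = 4)
  X <- cbind(cls - 1 + rnorm(8, 0, 0.01), runif(8), rep(2, 8))
  co <- make_cohort(X, cls)
  co$normalized <- TRUE
  w <- suppressWarnings(relieff_weights(co, k = 3))
  expect_identical(unname(w$weights[3]), 0)
  expect_gt(w$weights[1], w$weights[2])
})

test_that("ReliefF equals the brute-force update loop on random instances", {
  for (s in 1:8) {
    set.seed(400 + s)
    n <- sample(8:20, 1)
    p <- sample(2:5, 1)
    ncls <- sample(2:3, 1)
    cls <- sample(seq_len(ncls), n, replace = TRUE)
    while (min(tabulate(cls, ncls)) < 2) cls <- sample(seq_len(ncls), n, replace = TRUE)
    X <- matrix(runif(n * p), n, p)
    co <- make_cohort(X, cls)
    co$normalized <- TRUE
    k <- sample(1:3, 1)
    w <- suppressWarnings(relieff_weights(co, k = k))
    expect_equal(unname(w$weights), oracle_relieff(X, cls, k),
                 tolerance = 1e-12)
  }
})

test_that("ReliefF warns and reduces k for small classes", {
  set.seed(12)
  cls <- c(rep(1, 10), rep(2, 3))
  co <- make_cohort(matrix(runif(26), 13, 2), cls)
  co$normalized <- TRUE
  expect_warning(relieff_weights(co, k = 5), "neighbors available")
})

test_that("input selection keeps top psychosocial plus all others", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, seed = 5))
  norm <- apply_normalization(co, fit_normalization(co))
  w <- relieff_weights(norm, k = 10)
  sel <- select_inputs(w, norm)
  expect_equal(ncol(sel$features), 20)
  expect_equal(sum(sel$groups == "psychosocial"), 12)
  expect_equal(sum(sel$groups == "physiological"), 3)
  expect_equal(sum(sel$groups == "musculoskeletal"), 5)
  # idempotent on its own output (all 12 psychosocial columns retained)
  w2 <- relieff_weights(sel, k = 10)
  sel2 <- select_inputs(w2, sel)
  expect_identical(colnames(sel2$features), colnames(sel$features))
  expect_error(select_inputs(w, norm, n_psychosocial = 200),
               class = "pstnn_error_selection")
})

test_that("selection recovers the ground-truth informative columns", {
  co <- generate_cohort(cohort_spec(n_subjects = 500, seed = 6))
  norm <- apply_normalization(co, fit_normalization(co))
  w <- relieff_weights(norm, k = 10)
  sel <- select_inputs(w, norm)
  truth <- attr(co, "informative_psychosocial")
  hit <- length(intersect(colnames(sel$features), truth))
  expect_gte(hit, 10)
  # informative features carry more ReliefF weight than noise on average
  noise <- setdiff(colnames(norm$features)[norm$groups == "psychosocial"], truth)
  expect_gt(mean(w$weights[truth]), mean(w$weights[noise]))
})

test_that("train/test split is an exact stratified partition", {
  co <- generate_cohort(cohort_spec(n_subjects = 100, seed = 8))
  sp <- split_train_test(co, 0.8, seed = 1)
  expect_equal(nrow(sp$train$features), 80)
  expect_equal(nrow(sp$test$features), 20)
  idx_tr <- attr(sp$train, "indices")
  idx_te <- attr(sp$test, "indices")
  expect_length(intersect(idx_tr, idx_te), 0)
  expect_setequal(c(idx_tr, idx_te), 1:100)
  # stratified: per-class train share close to the global fraction
  for (c in 1:4) {
    n_c <- sum(co$labels == c)
    expect_lte(abs(sum(sp$train$labels == c) - 0.8 * n_c), 1)
  }
  sp2 <- split_train_test(co, 0.8, seed = 1)
  expect_identical(attr(sp2$train, "indices"), idx_tr)
  sp3 <- split_train_test(co, 0.8, seed = 2)
  expect_false(identical(attr(sp3$train, "indices"), idx_tr))
  # a class with fewer than 2 members cannot be stratified
  tiny <- risk_cohort(matrix(runif(8), 4, 2,
                             dimnames = list(NULL, c("psy_1", "psy_2"))),
                      labels = c(1, 1, 2, 3))
  expect_error(split_train_test(tiny, 0.5, seed = 1),
               class = "pstnn_error_degenerate_split")
  expect_error(split_train_test(co, 1.2, seed = 1),
               class = "pstnn_error_invalid_architecture")
})

test_that("cohort CSV round trip preserves values and groups", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$features, co$features, tolerance = 1e-12)
  expect_identical(back$labels, co$labels)
  expect_identical(back$groups, co$groups)
  # missing risk_level column is a parse error
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(psy_1 = 1:3), bad, row.names = FALSE)
  expect_error(read_cohort(bad), class = "pstnn_error_parse")
})
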