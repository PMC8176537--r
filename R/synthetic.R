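#' Specification for a synthetic psychosocial-risk cohort
#'
#' The generator emulates the statistical structure the pipeline
#' assumes: a large block of candidate psychosocial features of which
#' only a few are informative, small physiological and musculoskeletal
#' blocks that are all informative, and a 4-level ordinal outcome driven
#' by a latent severity axis. Defaults mirror a held-out test cohort of
#' 1,101 subjects with class counts 116/117/347/521.
#'
#' @param n_subjects Number of subjects (default 1101).
#' @param class_proportions Four proportions summing to 1; default
#'   116/117/347/521 over 1101.
#' @param n_psychosocial Candidate psychosocial features (default 123).
#' @param n_informative_psychosocial How many of them load on the latent
#'   severity (default 12).
#' @param n_physiological,n_musculoskeletal Sizes of the always-
#'   informative blocks (defaults 3 and 5).
#' @param effect_size Latent-mean separation between adjacent risk
#'   levels, in units of `noise_sd` (default 2.0).
#' @param noise_sd Standard deviation of the latent and feature noise
#'   (default 1.0).
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 1101L,
                        class_proportions = c(116, 117, 347, 521) / 1101,
                        n_psychosocial = 123L,
                        n_informative_psychosocial = 12L,
                        n_physiological = 3L,
                        n_musculoskeletal = 5L,
                        effect_size = 2.0,
                        noise_sd = 1.0,
                        seed = 0L) {
  if (n_subjects < 1) stop_pstnn("spec", "n_subjects must be positive")
  if (length(class_proportions) != 4 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop_pstnn("spec", "class_proportions must be 4 non-negative values summing to 1")
  }
  if (n_informative_psychosocial > n_psychosocial) {
    stop_pstnn("spec", "informative features cannot exceed psychosocial features")
  }
  if (any(largest_remainder(class_proportions, n_subjects) == 0)) {
    stop_pstnn("spec", "class proportions leave a class empty at n = %d", n_subjects)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 class_proportions = class_proportions,
                 n_psychosocial = as.integer(n_psychosocial),
                 n_informative_psychosocial = as.integer(n_informative_psychosocial),
                 n_physiological = as.integer(n_physiological),
                 n_musculoskeletal = as.integer(n_musculoskeletal),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Class sizes come from largest-remainder rounding of the proportions.
#' Each subject draws a latent severity
#' `z = level * effect_size + N(0, noise_sd)`; informative features are
#' `loading * z + N(0, noise_sd)` with per-feature loadings drawn once
#' from Uniform(0.5, 1.5); the remaining psychosocial features are
#' independent standard normal noise. Every column is then shifted so
#' its minimum is 1, giving strictly positive ranges suitable for
#' min-max normalization. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A raw [risk_cohort()] with attributes
#'   `"informative_psychosocial"` (the ground-truth informative column
#'   names) and `"spec"`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sizes <- largest_remainder(spec$class_proportions, spec$n_subjects)
  labels <- rep(1:4, sizes)
  n <- spec$n_subjects

  info_psy <- sort(sample.int(spec$n_psychosocial,
                              spec$n_informative_psychosocial))
  n_info <- spec$n_informative_psychosocial + spec$n_physiological +
    spec$n_musculoskeletal
  loadings <- runif(n_info, 0.5, 1.5)
  z <- labels * spec$effect_size + rnorm(n, 0, spec$noise_sd)

  p_total <- spec$n_psychosocial + spec$n_physiological + spec$n_musculoskeletal
  X <- matrix(0, n, p_total)
  li <- 0L
  informative_col <- function() {
    li <<- li + 1L
    loadings[li] * z + rnorm(n, 0, spec$noise_sd)
  }
  for (j in seq_len(spec$n_psychosocial)) {
    X[, j] <- if (j %in% info_psy) informative_col() else rnorm(n)
  }
  for (j in seq_len(spec$n_physiological + spec$n_musculoskeletal)) {
    X[, spec$n_psychosocial + j] <- informative_col()
  }
  X <- sweep(X, 2, apply(X, 2, min) - 1)   # strictly positive ranges

  colnames(X) <- c(paste0("psy_", seq_len(spec$n_psychosocial)),
                   paste0("phys_", seq_len(spec$n_physiological)),
                   paste0("msk_", seq_len(spec$n_musculoskeletal)))
  out <- risk_cohort(X, labels = labels, normalized = FALSE)
  attr(out, "informative_psychosocial") <- paste0("psy_", info_psy)
  attr(out, "spec") <- spec
  out
}

#' Read or write a cohort specification as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns the validated [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 17)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  do.call(cohort_spec, yaml::read_yaml(path))
}

#' Reference confusion matrix fixture
#'
#' The published held-out confusion matrix of a surface-tension network
#' classifying 1,101 subjects into four psychosocial-risk levels
#' (target-class counts 116/117/347/521). Used as a worked example for
#' the metric functions and in tests.
#'
#' @return A [confusion_matrix4()] (rows = output class, columns =
#'   target class).
#' @export
risk_confusion_fixture <- function() {
  m <- matrix(c(107, 1, 1, 0,
                3, 91, 19, 0,
                4, 13, 309, 13,
                2, 12, 18, 508),
              nrow = 4, byrow = TRUE)
  cm <- matrix(0L, 4, 4, dimnames = list(predicted = paste0("risk", 1:4),
                                         truth = paste0("risk", 1:4)))
  cm[] <- as.integer(m)
  structure(cm, class = c("confusion_matrix4", class(cm)))
}
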