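# pooled variance explained of a maxent fit for one trait matrix, shared by
# the observed fit and every permutation; uses the compiled batch solver.
maxent_pooled_stat <- function(Tmat, RA, tol, max_iter, lambda_cap) {
  B <- RA %*% Tmat
  q <- rep(1 / nrow(Tmat), nrow(Tmat))
  res <- .maxent_dual_batch_cpp(Tmat, B, q, tol, as.integer(max_iter), lambda_cap)
  Pm <- res$p_hat
  1 - sum((RA - Pm)^2) / sum((RA - mean(RA))^2)
}

#' Permutation test of trait-based abundance prediction
#'
#' Tests whether the community-weighted mean trait constraints predict species
#' relative abundances better than chance (Shipley's test). Each permutation
#' reassigns whole trait rows among species — the trait vectors stay intact, so
#' trait covariance is preserved, but the species-to-abundance link is broken —
#' then recomputes the CWMs from the observed abundances, refits the maxent
#' model in every plot, and records the pooled variance explained. The test is
#' one-sided (better-than-chance fit).
#'
#' The Monte-Carlo p-value uses the add-one formula
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}. With
#' `exhaustive = TRUE` (feasible for S at most about 7) all `S!` row
#' permutations are enumerated and the p-value is the exact fraction of
#' permutations (identity included) whose statistic is at least the observed
#' one.
#'
#' @param traits Trait table; preprocessed internally with
#'   [preprocess_traits()] unless `preprocess = FALSE`.
#' @param cm Community matrix tibble.
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Integer seed; the test is fully reproducible from it.
#' @param exhaustive Enumerate all `S!` permutations instead of sampling.
#' @param preprocess Apply [preprocess_traits()] first (default `TRUE`).
#' @param meta Trait metadata for preprocessing.
#' @inheritParams solve_maxent
#' @return An object of class `"cats_permutation"`: `observed_stat`,
#'   `null_stats`, `p_value`, `n_perm`, `seed`, `exhaustive`.
#' @export
permutation_test <- function(traits, cm, n_perm = 999, seed = 1,
                             exhaustive = FALSE, preprocess = TRUE,
                             meta = attr(traits, "trait_meta"),
                             tol = 1e-7, max_iter = 1e5, lambda_cap = 1e3) {
  validate_community_matrix(cm, traits)
  if (nrow(traits) < 3) stop("need at least 3 species for a permutation test")
  if (!exhaustive && n_perm < 1) stop("n_perm must be at least 1")
  if (preprocess) traits <- preprocess_traits(traits, meta)
  Tmat <- trait_matrix(traits)
  RA <- abundance_matrix(relative_abundance(cm))
  S <- nrow(Tmat)

  observed <- maxent_pooled_stat(Tmat, RA, tol, max_iter, lambda_cap)

  if (exhaustive) {
    if (S > 7) stop("exhaustive mode is limited to 7 species (S! permutations)")
    perms <- all_permutations(S)
    null_stats <- vapply(perms, function(idx) {
      maxent_pooled_stat(Tmat[idx, , drop = FALSE], RA, tol, max_iter, lambda_cap)
    }, numeric(1))
    p_value <- mean(null_stats >= observed - 1e-12)
    n_perm <- length(null_stats)
  } else {
    null_stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        idx <- sample.int(S)
        maxent_pooled_stat(Tmat[idx, , drop = FALSE], RA, tol, max_iter,
                           lambda_cap)
      }, numeric(1))
    })
    p_value <- (1 + sum(null_stats >= observed - 1e-12)) / (1 + n_perm)
  }

  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p_value, n_perm = n_perm, seed = seed,
                 exhaustive = exhaustive),
            class = "cats_permutation")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' @export
print.cats_permutation <- function(x, ...) {
  cat("permutation test of maxent fit (",
      if (x$exhaustive) "exhaustive" else "Monte-Carlo", ")\n", sep = "")
  cat("  observed variance explained: ", format(x$observed_stat, digits = 4),
      "\n  p-value: ", format(x$p_value, digits = 4), " (",
      x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.cats_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_stats), null_stat = x$null_stats)
}

#' @export
glance.cats_permutation <- function(x, ...) {
  tibble::tibble(observed_stat = x$observed_stat, p_value = x$p_value,
                 n_perm = x$n_perm, seed = x$seed, exhaustive = x$exhaustive)
}
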