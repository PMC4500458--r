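# fit one trait subset across all plots and return the pooled variance
# explained plus mean |lambda| per trait (compiled batch path).
subset_fit_stat <- function(Tmat, RA, cols, tol, max_iter, lambda_cap,
                            B = NULL) {
  Tsub <- Tmat[, cols, drop = FALSE]
  Bsub <- if (is.null(B)) RA %*% Tsub else B[, cols, drop = FALSE]
  q <- rep(1 / nrow(Tmat), nrow(Tmat))
  res <- .maxent_dual_batch_cpp(Tsub, Bsub, q, tol, as.integer(max_iter),
                                lambda_cap)
  list(ve = 1 - sum((RA - res$p_hat)^2) / sum((RA - mean(RA))^2),
       mean_abs_lambda = colMeans(abs(res$lambda)),
       converged = as.logical(res$converged))
}

#' Backward stepwise trait elimination for the maxent model
#'
#' Starting from the full trait set, fits the maxent model to every plot with
#' the observed CWM constraints, computes the mean absolute \eqn{\lambda} per
#' trait across plots, removes the trait with the smallest mean
#' \eqn{|\lambda|} (ties broken by trait-table column order), refits, and
#' repeats down to a single trait. Traits must be on a unit-variance scale for
#' the \eqn{|\lambda|} values to be comparable, so the table is preprocessed
#' with standardization unless `preprocess = FALSE`. Because each step drops a
#' constraint, the recorded variance explained is non-increasing from the last
#' step (1 trait) up to the full set.
#'
#' @inheritParams permutation_test
#' @return An object of class `"stepwise_path"` (direction `"backward"`):
#'   tibble `steps` with one row per evaluated trait set — `step`, `n_traits`,
#'   `traits` (list column), `changed_trait` (the trait removed after this
#'   evaluation; `NA` at the final single-trait step), `variance_explained` —
#'   and `mean_abs_lambda`, a list of named vectors per step.
#' @export
backward_stepwise <- function(traits, cm, preprocess = TRUE,
                              meta = attr(traits, "trait_meta"),
                              tol = 1e-7, max_iter = 1e5, lambda_cap = 1e3) {
  validate_community_matrix(cm, traits)
  if (preprocess) traits <- preprocess_traits(traits, meta, standardize = TRUE)
  Tmat <- trait_matrix(traits)
  if (ncol(Tmat) < 1) stop("need at least one trait")
  RA <- abundance_matrix(relative_abundance(cm))
  active <- colnames(Tmat)
  steps <- list(); mal <- list()
  for (s in seq_along(colnames(Tmat))) {
    fit <- subset_fit_stat(Tmat, RA, active, tol, max_iter, lambda_cap)
    drop <- if (length(active) > 1) {
      # which.min keeps the first minimum: ties resolve by column order
      active[which.min(fit$mean_abs_lambda)]
    } else NA_character_
    steps[[s]] <- tibble::tibble(step = s, n_traits = length(active),
                                 traits = list(active), changed_trait = drop,
                                 variance_explained = fit$ve)
    mal[[s]] <- fit$mean_abs_lambda
    if (is.na(drop)) break
    active <- setdiff(active, drop)
  }
  structure(list(steps = dplyr::bind_rows(steps), mean_abs_lambda = mal,
                 direction = "backward"),
            class = "stepwise_path")
}

#' Forward trait entry ordered by depth-gradient predictability
#'
#' Ranks traits by how well the depth gradient predicts their CWM (descending
#' marginal \eqn{R^2} from [fit_cwm_vs_depth()]), then solves the maxent model
#' with the *fitted* CWMs — the constraints a plot's environment alone implies —
#' for growing trait sets, recording the variance in the observed relative
#' abundances explained at each step. Fitted CWMs are unconstrained regression
#' predictions and can fall outside the trait's convex hull, where no maxent
#' solution exists; such values are clipped to the hull with a small relative
#' inset and the clipping is reported.
#'
#' @inheritParams permutation_test
#' @param gradient_fit A `"gradient_fit"` from [fit_cwm_vs_depth()] computed on
#'   the same (preprocessed) traits; computed internally when omitted.
#' @return A `"stepwise_path"` (direction `"forward"`): `steps` has one row per
#'   growing trait set with `changed_trait` the trait added, plus the gradient
#'   `r2` ranking used and `n_clipped`, the count of clipped constraint cells.
#' @export
forward_gradient_order <- function(traits, cm, gradient_fit = NULL,
                                   preprocess = TRUE,
                                   meta = attr(traits, "trait_meta"),
                                   tol = 1e-7, max_iter = 1e5,
                                   lambda_cap = 1e3) {
  validate_community_matrix(cm, traits)
  if (preprocess) traits <- preprocess_traits(traits, meta, standardize = TRUE)
  Tmat <- trait_matrix(traits)
  ra <- relative_abundance(cm)
  RA <- abundance_matrix(ra)
  if (is.null(gradient_fit))
    gradient_fit <- fit_cwm_vs_depth(compute_cwm(ra, traits))
  stopifnot(inherits(gradient_fit, "gradient_fit"))
  if (!setequal(gradient_fit$coef$trait, colnames(Tmat)))
    stop("gradient fit traits do not match the trait table")

  # stable sort: ties in r2 resolve by trait-table column order
  r2 <- gradient_fit$coef$r2[match(colnames(Tmat), gradient_fit$coef$trait)]
  order_in <- colnames(Tmat)[order(-r2)]

  # fitted CWM constraints, clipped into the hull of each trait column
  Bfit <- as.matrix(gradient_fit$fitted_cwm[, colnames(Tmat), drop = FALSE])
  n_clipped <- 0L
  for (j in seq_len(ncol(Tmat))) {
    rng <- range(Tmat[, j])
    inset <- 1e-6 * max(diff(rng), 1e-12)
    lo <- rng[1] + inset; hi <- rng[2] - inset
    bad <- Bfit[, j] < lo | Bfit[, j] > hi
    n_clipped <- n_clipped + sum(bad)
    Bfit[bad, j] <- pmin(pmax(Bfit[bad, j], lo), hi)
  }
  if (n_clipped > 0)
    message(n_clipped, " fitted CWM value(s) clipped to the trait convex hull")

  steps <- list(); mal <- list()
  for (s in seq_along(order_in)) {
    active <- order_in[seq_len(s)]
    fit <- subset_fit_stat(Tmat, RA, active, tol, max_iter, lambda_cap, B = Bfit)
    steps[[s]] <- tibble::tibble(step = s, n_traits = s, traits = list(active),
                                 changed_trait = order_in[s],
                                 variance_explained = fit$ve)
    mal[[s]] <- fit$mean_abs_lambda
  }
  structure(list(steps = dplyr::bind_rows(steps), mean_abs_lambda = mal,
                 direction = "forward", ranking = order_in,
                 r2 = setNames(r2, colnames(Tmat)), n_clipped = n_clipped),
            class = "stepwise_path")
}

#' @export
print.stepwise_path <- function(x, ...) {
  cat(x$direction, "stepwise maxent path\n")
  print(dplyr::select(x$steps, -"traits"), n = nrow(x$steps))
  invisible(x)
}

#' @export
tidy.stepwise_path <- function(x, ...) {
  dplyr::select(x$steps, "step", "n_traits", "changed_trait",
                "variance_explained")
}

#' @export
glance.stepwise_path <- function(x, ...) {
  tibble::tibble(direction = x$direction, n_steps = nrow(x$steps),
                 best_variance_explained = max(x$steps$variance_explained))
}
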