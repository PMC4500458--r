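#' Maximum entropy distribution under CWM trait constraints
#'
#' Solves the CATS (Community Assembly by Trait Selection) problem for one
#' community: find the distribution `p` over species that maximizes entropy
#' relative to a prior `q` subject to the community-weighted mean constraints
#' \eqn{\sum_i p_i t_{ij} = b_j}. The solution has the exponential form
#' \eqn{p_i \propto q_i \exp(\sum_j \lambda_j t_{ij})}; the Lagrange
#' multipliers \eqn{\lambda_j} measure how strongly trait \eqn{j} filters
#' abundance (positive: species with larger values are favoured relative to
#' the prior).
#'
#' Two solvers are available. `"dual"` (default) runs a damped Newton ascent
#' on the dual log-likelihood in \eqn{\lambda}; `"iis"` is the classical
#' Improved Iterative Scaling fixed point, which requires nonnegative trait
#' values (hence the nonnegative preprocessing). Both terminate when the
#' largest change in any single predicted relative abundance between two
#' iterations drops below `tol`, which also handles constraints on the
#' boundary of the trait convex hull, where \eqn{\lambda} diverges while `p`
#' converges; `lambda_cap` bounds the multipliers in that case and the fit is
#' flagged unconverged.
#'
#' @param traits Trait table (tibble with `species` column) or numeric S x m
#'   matrix of nonnegative preprocessed trait values.
#' @param constraints Numeric vector of target CWMs, one per trait (names, if
#'   present, must match the trait columns).
#' @param prior Prior distribution over species; default uniform. Must be
#'   strictly positive; it is normalized to sum to 1.
#' @param tol Convergence threshold on the per-species change in predicted
#'   relative abundance. Default `1e-7`.
#' @param max_iter Iteration cap. Default `1e5`.
#' @param lambda_cap Bound on `|lambda|` (on the working trait scale) guarding
#'   boundary solutions. Default `1e3`.
#' @param method `"dual"` (Newton on the dual, compiled) or `"iis"`
#'   (Improved Iterative Scaling in R, kept as the reference algorithm).
#' @return An object of class `"maxent_fit"`: a list with `p_hat` (named
#'   predicted relative abundances, summing to 1), `lambda` (named
#'   multipliers), `iterations`, `converged`, `max_step`, and
#'   `constraint_residual` (achieved CWM minus target).
#' @export
#' @examples
#' fit <- solve_maxent(matrix(c(0, 1, 2), ncol = 1), constraints = 1.5)
#' fit$p_hat     # ~ (0.116, 0.268, 0.616)
#' fit$lambda    # ~ 0.834
solve_maxent <- function(traits, constraints, prior = NULL, tol = 1e-7,
                         max_iter = 1e5, lambda_cap = 1e3,
                         method = c("dual", "iis")) {
  method <- match.arg(method)
  T <- if (is.data.frame(traits)) trait_matrix(traits) else as.matrix(traits)
  storage.mode(T) <- "double"
  if (anyNA(T) || any(!is.finite(T))) stop("non-finite values in traits")
  S <- nrow(T); m <- ncol(T)
  constraints <- as.numeric(constraints)
  if (length(constraints) != m)
    stop("length of constraints (", length(constraints),
         ") does not match number of traits (", m, ")")
  if (anyNA(constraints)) stop("non-finite constraint values")
  if (is.null(prior)) prior <- rep(1 / S, S)
  if (length(prior) != S || any(prior <= 0)) stop("prior must be positive, length S")
  prior <- prior / sum(prior)
  if (m > S - 1)
    warning("more constraints (", m, ") than species minus one (", S - 1,
            "); lambda is not identifiable")
  if (method == "iis" && any(T < 0))
    stop("Improved Iterative Scaling requires nonnegative trait values")

  res <- if (method == "dual") {
    .maxent_dual_cpp(T, constraints, prior, tol, as.integer(max_iter), lambda_cap)
  } else {
    maxent_iis(T, constraints, prior, tol, max_iter, lambda_cap)
  }
  new_maxent_fit(res, T, constraints, method)
}

new_maxent_fit <- function(res, T, constraints, method) {
  p <- as.numeric(res$p_hat)
  names(p) <- rownames(T)
  lam <- as.numeric(res$lambda)
  names(lam) <- colnames(T)
  structure(list(
    p_hat = p,
    lambda = lam,
    iterations = as.integer(res$iterations),
    converged = isTRUE(as.logical(res$converged)),
    max_step = as.numeric(res$max_step),
    constraint_residual = setNames(as.numeric(crossprod(T, p)) - constraints,
                                   colnames(T)),
    constraints = setNames(constraints, colnames(T)),
    method = method
  ), class = "maxent_fit")
}

# Improved Iterative Scaling, the classical fitting algorithm for
# maximum-entropy exponential models with nonnegative features. Each sweep
# solves, per feature j, the 1-d equation
#   sum_i p_i t_ij exp(delta_j T#_i) = b_j,   T#_i = sum_j t_ij,
# by safeguarded Newton in delta_j, then updates lambda_j += delta_j.
maxent_iis <- function(T, b, q, tol, max_iter, lambda_cap) {
  S <- nrow(T); m <- ncol(T)
  lambda <- rep(0, m)
  Tsum <- rowSums(T)
  p <- q
  converged <- m == 0L
  max_step <- 0
  it <- 0L
  while (m > 0L && it < max_iter) {
    it <- it + 1L
    p_old <- p
    for (j in seq_len(m)) {
      tj <- T[, j]
      if (b[j] <= 0 && all(tj >= 0)) next  # boundary target; leave to cap logic
      delta <- 0
      for (nr in 1:50) {
        w <- p * tj * exp(delta * Tsum)
        f <- sum(w) - b[j]
        if (abs(f) < 1e-12 * max(1, abs(b[j]))) break
        fp <- sum(w * Tsum)
        if (!is.finite(fp) || fp <= 0) break
        step <- f / fp
        step <- max(min(step, 50), -50)
        delta <- delta - step
        if (abs(step) < 1e-14) break
      }
      lambda[j] <- max(min(lambda[j] + delta, lambda_cap), -lambda_cap)
      eta <- drop(T %*% lambda) + log(q)
      eta <- eta - max(eta)
      p <- exp(eta); p <- p / sum(p)
    }
    max_step <- max(abs(p - p_old))
    if (max_step < tol) {
      converged <- all(abs(lambda) < lambda_cap)
      break
    }
  }
  list(p_hat = p, lambda = lambda, iterations = it, converged = converged,
       max_step = max_step)
}

#' Fit the maxent model to every plot of a community matrix
#'
#' Runs [solve_maxent()] independently for each plot, using that plot's CWM
#' vector as the constraint set and a shared (default uniform) prior. Also
#' reports the condition number of the centered trait matrix: with nearly as
#' many traits as species the individual \eqn{\lambda} can be ill-conditioned
#' even though the predicted distribution is stable, so a warning is emitted
#' above `1e8`.
#'
#' @inheritParams solve_maxent
#' @param cwm CWM tibble from [compute_cwm()] (or any tibble with `plot_id`
#'   and one column per trait); trait columns must match `traits`.
#' @return An object of class `"maxent_ensemble"`: list of `maxent_fit`s
#'   (`fits`), `plot_ids`, `species`, `traits` (names), `condition_number`,
#'   and the solver settings. `tidy()` returns the per-plot lambda table,
#'   `glance()` the convergence summary, [predict_abundance()] the predicted
#'   relative abundances.
#' @export
solve_all_plots <- function(traits, cwm, prior = NULL, tol = 1e-7,
                            max_iter = 1e5, lambda_cap = 1e3,
                            method = c("dual", "iis")) {
  method <- match.arg(method)
  T <- trait_matrix(traits)
  B <- cwm_matrix(cwm)
  if (!identical(colnames(B), colnames(T)))
    stop("CWM columns must match trait columns, in order")
  S <- nrow(T)
  if (is.null(prior)) prior <- rep(1 / S, S)
  prior <- prior / sum(prior)

  kappa <- if (ncol(T) > 0) kappa(scale(T, center = TRUE, scale = FALSE),
                                  exact = TRUE) else 1
  if (is.finite(kappa) && kappa > 1e8)
    warning("centered trait matrix is near-singular (condition number ",
            format(kappa, digits = 3),
            "); individual lambda values are ill-conditioned")

  fits <- lapply(seq_len(nrow(B)), function(k) {
    fit <- solve_maxent(T, B[k, ], prior = prior, tol = tol,
                        max_iter = max_iter, lambda_cap = lambda_cap,
                        method = method)
    fit
  })
  names(fits) <- rownames(B)
  structure(list(
    fits = fits, plot_ids = rownames(B), species = rownames(T),
    traits = colnames(T), condition_number = kappa,
    settings = list(tol = tol, max_iter = max_iter, lambda_cap = lambda_cap,
                    method = method)
  ), class = "maxent_ensemble")
}

#' Predicted relative abundances from a fitted ensemble
#'
#' @param ensemble A `maxent_ensemble` from [solve_all_plots()].
#' @param long Return long format (`plot_id`, `species`, `p_pred`) instead of
#'   a plots-by-species tibble. Default `FALSE`.
#' @return A tibble of predicted relative abundances.
#' @export
predict_abundance <- function(ensemble, long = FALSE) {
  P <- do.call(rbind, lapply(ensemble$fits, function(f) f$p_hat))
  out <- dplyr::bind_cols(tibble::tibble(plot_id = ensemble$plot_ids),
                          tibble::as_tibble(P))
  if (long)
    out <- tidyr::pivot_longer(out, -"plot_id", names_to = "species",
                               values_to = "p_pred")
  out
}

lambda_matrix <- function(ensemble) {
  L <- do.call(rbind, lapply(ensemble$fits, function(f) f$lambda))
  rownames(L) <- ensemble$plot_ids
  L
}

#' Variance in observed relative abundance explained by the model
#'
#' Pools all plot-by-species pairs and computes
#' \eqn{R^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2} with
#' grand-mean centering, the usual reading of an observed-versus-predicted
#' scatter across all communities. The squared Pearson correlation between
#' observed and predicted values is reported alongside, and a per-plot
#' \eqn{R^2} vector (same formula within each plot) for diagnostics.
#'
#' @param obs Relative-abundance tibble ([relative_abundance()]) with the same
#'   plots and species order as the ensemble.
#' @param ensemble A `maxent_ensemble`, or a plots-by-species matrix/tibble of
#'   predictions.
#' @return An object of class `"maxent_fit_summary"` with
#'   `variance_explained`, `pearson_r2`, `per_plot_r2`, and `n_pairs`.
#' @export
variance_explained <- function(obs, ensemble) {
  O <- abundance_matrix(obs)
  P <- if (inherits(ensemble, "maxent_ensemble")) {
    do.call(rbind, lapply(ensemble$fits, function(f) f$p_hat))
  } else if (is.data.frame(ensemble)) {
    as.matrix(ensemble[setdiff(names(ensemble), c("plot_id", "site_id", "depth_m"))])
  } else as.matrix(ensemble)
  if (!all(dim(O) == dim(P)))
    stop("observed and predicted tables have different dimensions")
  sse <- sum((O - P)^2)
  sstot <- sum((O - mean(O))^2)
  if (sstot == 0) stop("observed relative abundances have zero total variance")
  per_plot <- vapply(seq_len(nrow(O)), function(k) {
    sst <- sum((O[k, ] - mean(O[k, ]))^2)
    if (sst == 0) NA_real_ else 1 - sum((O[k, ] - P[k, ])^2) / sst
  }, numeric(1))
  structure(list(
    variance_explained = 1 - sse / sstot,
    pearson_r2 = suppressWarnings(stats::cor(as.vector(O), as.vector(P)))^2,
    per_plot_r2 = setNames(per_plot, rownames(O)),
    n_pairs = length(O)
  ), class = "maxent_fit_summary")
}

#' Mean lambda coefficients across plots
#'
#' Arithmetic mean of each trait's \eqn{\lambda} over plots, together with the
#' mean absolute value used by the backward stepwise procedure (a trait whose
#' \eqn{\lambda} flips sign across plots can have mean near zero yet still
#' filter strongly; the magnitude captures that).
#'
#' @param ensemble A `maxent_ensemble`.
#' @return A tibble `trait`, `mean_lambda`, `mean_abs_lambda`.
#' @export
mean_lambda <- function(ensemble) {
  if (!length(ensemble$fits)) stop("no fitted plots")
  L <- lambda_matrix(ensemble)
  tibble::tibble(trait = ensemble$traits,
                 mean_lambda = unname(colMeans(L)),
                 mean_abs_lambda = unname(colMeans(abs(L))))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.maxent_fit <- function(x, ...) {
  cat("maxent fit (", x$method, "): ", length(x$p_hat), " species, ",
      length(x$lambda), " constraints\n", sep = "")
  cat("  converged: ", x$converged, " after ", x$iterations,
      " iterations (max step ", format(x$max_step, digits = 3), ")\n", sep = "")
  if (length(x$lambda)) {
    cat("  lambda:\n")
    print(round(x$lambda, 4))
  }
  invisible(x)
}

#' @export
tidy.maxent_fit <- function(x, ...) {
  tibble::tibble(trait = names(x$lambda), lambda = unname(x$lambda),
                 constraint = unname(x$constraints),
                 residual = unname(x$constraint_residual))
}

#' @export
glance.maxent_fit <- function(x, ...) {
  tibble::tibble(n_species = length(x$p_hat), n_constraints = length(x$lambda),
                 iterations = x$iterations, converged = x$converged,
                 max_step = x$max_step,
                 max_abs_residual = if (length(x$lambda))
                   max(abs(x$constraint_residual)) else 0)
}

#' @export
print.maxent_ensemble <- function(x, ...) {
  cat("maxent ensemble: ", length(x$fits), " plots, ", length(x$species),
      " species, ", length(x$traits), " trait constraints\n", sep = "")
  cat("  converged plots: ", sum(vapply(x$fits, `[[`, TRUE, "converged")),
      "/", length(x$fits), "\n", sep = "")
  cat("  trait matrix condition number: ",
      format(x$condition_number, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.maxent_ensemble <- function(x, ...) {
  purrr::map_dfr(x$plot_ids, function(pid) {
    f <- x$fits[[pid]]
    dplyr::mutate(tidy(f), plot_id = pid, converged = f$converged,
                  .before = 1)
  })
}

#' @export
glance.maxent_ensemble <- function(x, ...) {
  conv <- vapply(x$fits, `[[`, TRUE, "converged")
  iters <- vapply(x$fits, `[[`, 1L, "iterations")
  tibble::tibble(n_plots = length(x$fits), n_species = length(x$species),
                 n_traits = length(x$traits), n_converged = sum(conv),
                 mean_iterations = mean(iters),
                 condition_number = x$condition_number)
}

#' @export
print.maxent_fit_summary <- function(x, ...) {
  cat("maxent fit: variance explained ",
      format(100 * x$variance_explained, digits = 4), "% (pooled R²), ",
      "squared Pearson r ", format(x$pearson_r2, digits = 4), ", ",
      x$n_pairs, " plot x species pairs\n", sep = "")
  invisible(x)
}

#' @export
glance.maxent_fit_summary <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 pearson_r2 = x$pearson_r2, n_pairs = x$n_pairs)
}
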