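# random-intercept regression of y on depth with site grouping; falls back to
# OLS when the mixed fit is singular or sites do not support a random
# intercept. Returns fixed coefficients, marginal (fixed-effects) R2, fixed
# fitted values, and the slope's F test.
depth_lmm <- function(y, depth, site, warn_label = "response") {
  d <- data.frame(y = y, depth = depth, site = factor(site))
  use_lmm <- nlevels(d$site) > 1
  fit <- NULL
  if (use_lmm) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(y ~ depth + (1 | site), data = d)),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) fit <- NULL
  }
  if (!is.null(fit)) {
    beta <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_re <- sum(vc$vcov[vc$grp != "Residual"])
    var_res <- vc$vcov[vc$grp == "Residual"]
    fitted_fixed <- beta[1] + beta[2] * d$depth
    var_fix <- mean((fitted_fixed - mean(fitted_fixed))^2)
    r2 <- var_fix / (var_fix + var_re + var_res)
    an <- suppressMessages(stats::anova(fit))
    Fv <- an[["F value"]][1]
    pv <- an[["Pr(>F)"]][1]
    ddf <- an[["DenDF"]][1]
    # Satterthwaite df degenerate (e.g. zero residual variance): fall back to
    # a classical F reference with n - 2 denominator df
    if (!is.finite(pv) || (is.finite(ddf) && ddf < 0.5))
      pv <- stats::pf(Fv, 1, max(length(y) - 2, 1), lower.tail = FALSE)
    ranefs <- lme4::ranef(fit)$site[, 1]
    names(ranefs) <- rownames(lme4::ranef(fit)$site)
    list(slope = unname(beta[2]), intercept = unname(beta[1]), r2 = r2,
         fitted = fitted_fixed, F = Fv, p = pv, site_intercepts = ranefs,
         model = "lmm")
  } else {
    if (use_lmm)
      warning("singular mixed fit for ", warn_label,
              "; falling back to ordinary least squares")
    fit <- lm(y ~ depth, data = d)
    beta <- coef(fit)
    an <- suppressWarnings(anova(fit))
    r2 <- summary(fit)$r.squared
    Fv <- an[["F value"]][1]
    pv <- an[["Pr(>F)"]][1]
    if (!is.finite(pv) && isTRUE(r2 > 1 - 1e-10)) { Fv <- Inf; pv <- 0 }
    list(slope = unname(beta[2]), intercept = unname(beta[1]), r2 = r2,
         fitted = unname(fitted(fit)), F = Fv, p = pv,
         site_intercepts = setNames(rep(0, nlevels(d$site)), levels(d$site)),
         model = "ols")
  }
}

#' Regress CWM traits on the water depth gradient
#'
#' Fits, per trait, a Gaussian random-intercept model
#' \eqn{CWM = \beta_0 + \beta_1 depth + u_{site} + \epsilon} and returns the
#' fixed coefficients, the marginal (fixed-effects-only) \eqn{R^2}, and the
#' fitted CWM for each plot computed from the fixed effects alone — i.e. the
#' CWM predicted from the plot's environmental conditions only, which is what
#' the gradient-constrained maxent model uses. Singular fits (a single site,
#' or no between-site variance) fall back to ordinary least squares with a
#' warning.
#'
#' @param cwm CWM tibble from [compute_cwm()] (must carry `depth_m` and
#'   `site_id`).
#' @param depth,site Optional overrides for the depth and site columns.
#' @return An object of class `"gradient_fit"`: tibble `coef` (`trait`,
#'   `slope`, `intercept`, `r2`, `F`, `p`, `model`), tibble `fitted_cwm`
#'   (plot metadata + fitted CWM per trait), and `site_intercepts`.
#' @export
fit_cwm_vs_depth <- function(cwm, depth = cwm$depth_m, site = cwm$site_id) {
  if (length(unique(depth)) < 2) stop("need at least 2 distinct depths")
  tn <- setdiff(names(cwm), c("plot_id", "site_id", "depth_m"))
  fits <- lapply(tn, function(j)
    depth_lmm(cwm[[j]], depth, site, warn_label = paste0("CWM of '", j, "'")))
  names(fits) <- tn
  coef_tbl <- purrr::map_dfr(tn, function(j) {
    f <- fits[[j]]
    tibble::tibble(trait = j, slope = f$slope, intercept = f$intercept,
                   r2 = f$r2, F = f$F, p = f$p, model = f$model)
  })
  fitted_tbl <- dplyr::bind_cols(
    cwm[intersect(c("plot_id", "site_id", "depth_m"), names(cwm))],
    tibble::as_tibble(setNames(lapply(tn, function(j) fits[[j]]$fitted), tn)))
  structure(list(coef = coef_tbl, fitted_cwm = fitted_tbl,
                 site_intercepts = lapply(fits, `[[`, "site_intercepts")),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("CWM ~ depth gradient fits (", nrow(x$coef), " traits)\n", sep = "")
  print(dplyr::arrange(x$coef, dplyr::desc(.data$r2)), n = nrow(x$coef))
  invisible(x)
}

#' @export
tidy.gradient_fit <- function(x, ...) x$coef

#' @export
glance.gradient_fit <- function(x, ...) {
  tibble::tibble(n_traits = nrow(x$coef), mean_r2 = mean(x$coef$r2),
                 n_ols_fallback = sum(x$coef$model == "ols"))
}

#' Trends of lambda coefficients along the depth gradient
#'
#' Regresses each trait's \eqn{\lambda} (from maxent fits on unstandardized
#' but nonnegative traits) on water depth with site random intercepts, and
#' reports the slope, F and p of the depth effect. `direction_shift` flags a
#' sign change of the fixed-effect fitted \eqn{\lambda} between the shallowest
#' and deepest plot; `significant_shift` additionally requires the depth
#' effect to be significant at `alpha`, which is the operational version of a
#' filtering effect that flips from favouring to penalizing a trait along the
#' gradient. Plots whose maxent fit did not converge are excluded (their
#' \eqn{\lambda} is boundary-capped, not an estimate).
#'
#' @param ensemble `maxent_ensemble` fitted with unstandardized traits.
#' @param depth,site Per-plot depth (m) and site ids, aligned with the
#'   ensemble's plots.
#' @param alpha Significance level for `significant_shift` (default 0.05).
#' @return An object of class `"lambda_trend"` whose `trend` tibble has one
#'   row per trait: `slope`, `F`, `p`, `lambda_shallow`, `lambda_deep`,
#'   `direction_shift`, `significant_shift`; plus the per-plot lambda table
#'   used (`data`) and the number of excluded plots.
#' @export
lambda_depth_trend <- function(ensemble, depth, site, alpha = 0.05) {
  conv <- vapply(ensemble$fits, `[[`, TRUE, "converged")
  n_excluded <- sum(!conv)
  if (n_excluded > 0)
    message(n_excluded, " non-converged plot(s) excluded from lambda trends")
  if (sum(conv) < 3) stop("fewer than 3 converged plots; cannot fit trends")
  L <- lambda_matrix(ensemble)[conv, , drop = FALSE]
  depth <- depth[conv]; site <- site[conv]
  dmin <- min(depth); dmax <- max(depth)
  trend <- purrr::map_dfr(colnames(L), function(j) {
    f <- depth_lmm(L[, j], depth, site, warn_label = paste0("lambda of '", j, "'"))
    lam_lo <- f$intercept + f$slope * dmin
    lam_hi <- f$intercept + f$slope * dmax
    shift <- sign(lam_lo) * sign(lam_hi) < 0
    tibble::tibble(trait = j, slope = f$slope, intercept = f$intercept,
                   F = f$F, p = f$p, lambda_shallow = lam_lo,
                   lambda_deep = lam_hi, direction_shift = shift,
                   significant_shift = shift && is.finite(f$p) && f$p < alpha,
                   model = f$model)
  })
  data <- dplyr::bind_cols(
    tibble::tibble(plot_id = ensemble$plot_ids[conv], depth_m = depth,
                   site_id = site),
    tibble::as_tibble(L))
  structure(list(trend = trend, data = data, n_excluded = n_excluded,
                 alpha = alpha),
            class = "lambda_trend")
}

#' @export
print.lambda_trend <- function(x, ...) {
  cat("lambda ~ depth trends (", nrow(x$trend), " traits, ",
      x$n_excluded, " plots excluded)\n", sep = "")
  print(x$trend, n = nrow(x$trend))
  invisible(x)
}

#' @export
tidy.lambda_trend <- function(x, ...) x$trend

#' @export
glance.lambda_trend <- function(x, ...) {
  tibble::tibble(n_traits = nrow(x$trend),
                 n_direction_shift = sum(x$trend$direction_shift),
                 n_significant_shift = sum(x$trend$significant_shift),
                 n_excluded_plots = x$n_excluded, alpha = x$alpha)
}
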