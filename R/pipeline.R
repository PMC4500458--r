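#' Configuration for a full maxent analysis run
#'
#' @param traits,trait_meta,abundance Paths to the trait, trait-metadata and
#'   abundance CSVs (formats as in [read_trait_table()] and
#'   [read_community_matrix()]).
#' @param out_dir Output directory for artifacts; created if absent.
#' @param tol,max_iter,lambda_cap Solver settings, see [solve_maxent()].
#' @param n_perm Permutations for the significance test.
#' @param seed Integer seed.
#' @param standardize Standardize traits to unit variance (default `TRUE`).
#' @return A validated list of class `"run_config"`, serialized verbatim into
#'   every report.
#' @export
run_config <- function(traits, trait_meta, abundance, out_dir,
                       tol = 1e-7, max_iter = 1e5, lambda_cap = 1e3,
                       n_perm = 999, seed = 1, standardize = TRUE) {
  for (p in c(traits, trait_meta, abundance))
    if (!file.exists(p)) stop("input file not found: ", p)
  stopifnot(tol > 0, max_iter > 0, lambda_cap > 0, n_perm > 0)
  structure(list(traits = traits, trait_meta = trait_meta,
                 abundance = abundance, out_dir = out_dir, tol = tol,
                 max_iter = max_iter, lambda_cap = lambda_cap,
                 n_perm = n_perm, seed = as.integer(seed),
                 standardize = standardize),
            class = "run_config")
}

read_config_inputs <- function(config) {
  traits <- read_trait_table(config$traits, config$trait_meta)
  cm <- read_community_matrix(config$abundance, traits)
  list(traits = traits, cm = cm)
}

write_artifact <- function(x, config, name) {
  path <- file.path(config$out_dir, name)
  readr::write_csv(x, path, progress = FALSE)
  path
}

#' Run the observed-CWM maxent analysis end to end
#'
#' Preprocesses traits, computes relative abundances and observed CWMs, fits
#' the maxent model in every plot, summarizes fit (pooled variance explained),
#' tabulates mean lambda per trait, runs the permutation significance test,
#' and runs the backward stepwise trait elimination. All tables are written as
#' CSV into `config$out_dir` together with a JSON report embedding the exact
#' configuration; artifacts are only written once every stage has succeeded,
#' so a failed run leaves no partial outputs.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (also written to `report_observed.json`).
#' @export
run_observed_cwm_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- read_config_inputs(config)
  pre <- preprocess_traits(inp$traits, standardize = config$standardize)
  ra <- relative_abundance(inp$cm)
  cwm <- compute_cwm(ra, pre)
  ens <- solve_all_plots(pre, cwm, tol = config$tol,
                         max_iter = config$max_iter,
                         lambda_cap = config$lambda_cap)
  fitsum <- variance_explained(ra, ens)
  ml <- mean_lambda(ens)
  pt <- permutation_test(inp$traits, inp$cm, n_perm = config$n_perm,
                         seed = config$seed, tol = config$tol,
                         max_iter = config$max_iter,
                         lambda_cap = config$lambda_cap)
  path <- backward_stepwise(inp$traits, inp$cm, tol = config$tol,
                            max_iter = config$max_iter,
                            lambda_cap = config$lambda_cap)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_artifact(predict_abundance(ens), config, "predicted_abundance.csv")
  write_artifact(tidy(ens), config, "lambda_by_plot.csv")
  write_artifact(ml, config, "mean_lambda.csv")
  write_artifact(tidy(path), config, "backward_stepwise.csv")
  report <- list(
    analysis = "observed_cwm",
    config = unclass(config),
    variance_explained = fitsum$variance_explained,
    pearson_r2 = fitsum$pearson_r2,
    permutation = list(observed_stat = pt$observed_stat, p_value = pt$p_value,
                       n_perm = pt$n_perm, seed = pt$seed),
    convergence = as.list(glance(ens)),
    condition_number = ens$condition_number
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report_observed.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the gradient-fitted-CWM maxent analysis end to end
#'
#' Regresses observed CWM traits on the depth gradient (site random
#' intercepts), uses the fitted CWMs as maxent constraints with traits entered
#' in descending gradient-R2 order, records the variance-explained curve,
#' tabulates observed and predicted species abundance trends along depth, and
#' tests the lambda-versus-depth trends on unstandardized traits. Artifacts
#' and a JSON report are written to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (also written to `report_fitted.json`).
#' @export
run_fitted_cwm_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- read_config_inputs(config)
  pre <- preprocess_traits(inp$traits, standardize = config$standardize)
  ra <- relative_abundance(inp$cm)
  cwm <- compute_cwm(ra, pre)

  gf <- fit_cwm_vs_depth(cwm)
  fwd <- forward_gradient_order(pre, inp$cm, gradient_fit = gf,
                                preprocess = FALSE, tol = config$tol,
                                max_iter = config$max_iter,
                                lambda_cap = config$lambda_cap)
  ve_obs <- variance_explained(
    ra, solve_all_plots(pre, cwm, tol = config$tol,
                        max_iter = config$max_iter,
                        lambda_cap = config$lambda_cap))$variance_explained

  # species-level abundance trends along depth, observed vs predicted from the
  # best gradient-constrained model (full forward set)
  raw <- preprocess_traits(inp$traits, standardize = FALSE)
  ens_raw <- solve_all_plots(raw, compute_cwm(ra, raw), tol = config$tol,
                             max_iter = config$max_iter,
                             lambda_cap = config$lambda_cap)
  lt <- lambda_depth_trend(ens_raw, inp$cm$depth_m, inp$cm$site_id)

  ens_fit <- solve_all_plots(
    pre, dplyr::bind_cols(cwm[c("plot_id", "site_id", "depth_m")],
                          gf$fitted_cwm[trait_names(pre)]),
    tol = config$tol, max_iter = config$max_iter,
    lambda_cap = config$lambda_cap)
  sp_trend <- species_depth_trends(ra, ens_fit)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_artifact(tidy(gf), config, "cwm_gradient_fit.csv")
  write_artifact(gf$fitted_cwm, config, "fitted_cwm.csv")
  write_artifact(tidy(fwd), config, "forward_gradient_path.csv")
  write_artifact(tidy(lt), config, "lambda_depth_trend.csv")
  write_artifact(sp_trend, config, "species_depth_trends.csv")
  report <- list(
    analysis = "fitted_cwm",
    config = unclass(config),
    variance_explained_fitted = fwd$steps$variance_explained[nrow(fwd$steps)],
    variance_explained_observed = ve_obs,
    forward_ranking = fwd$ranking,
    n_clipped_constraints = fwd$n_clipped,
    n_significant_lambda_shifts = sum(lt$trend$significant_shift),
    n_excluded_plots = lt$n_excluded
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report_fitted.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# per-species linear trend of observed and predicted relative abundance vs depth
species_depth_trends <- function(ra, ensemble) {
  pred <- predict_abundance(ensemble)
  depth <- ra$depth_m
  purrr::map_dfr(species_names(ra), function(sp) {
    tibble::tibble(
      species = sp,
      slope_observed = unname(coef(lm(ra[[sp]] ~ depth))[2]),
      slope_predicted = unname(coef(lm(pred[[sp]] ~ depth))[2]))
  })
}
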