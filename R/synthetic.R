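#' Specify one trait of a synthetic community generator
#'
#' Builds a one-row specification of a trait: its sampling distribution across
#' species (lognormal for continuous traits, Bernoulli mapped to the 1/2
#' coding for binary traits) and the trait-based filtering it exerts on
#' abundance. Filtering has a directional part with depth-dependent strength
#' \eqn{\beta(d) = \beta + \beta_{depth} (d - \bar d)} acting on the species'
#' standardized trait score, and an optional Gaussian kernel
#' \eqn{-(z - opt(d))^2 / 2\sigma^2} with a depth-dependent optimum
#' \eqn{opt(d) = opt + opt_{depth} (d - \bar d)}. A trait whose \eqn{\beta(d)}
#' changes sign across the sampled depth range produces the
#' shallow-positive/deep-negative lambda pattern (a direction shift).
#'
#' @param trait Trait name.
#' @param kind `"continuous"` or `"binary12"`.
#' @param meanlog,sdlog Lognormal parameters for continuous traits.
#' @param rate Probability of level 2 for binary12 traits.
#' @param log_transform Whether preprocessing log-transforms this trait.
#' @param unit Unit label.
#' @param beta,beta_depth Directional filtering strength (per standardized
#'   trait SD) and its linear change per metre of depth (centred on the mean
#'   sampled depth).
#' @param opt,opt_depth,sigma Gaussian kernel optimum (standardized trait
#'   scale), its drift per metre, and width; `sigma = Inf` disables the kernel.
#' @return A one-row tibble.
#' @export
trait_spec <- function(trait, kind = "continuous", meanlog = 0, sdlog = 0.5,
                       rate = 0.5, log_transform = kind == "continuous",
                       unit = "", beta = 0, beta_depth = 0, opt = 0,
                       opt_depth = 0, sigma = Inf) {
  stopifnot(kind %in% c("binary12", "continuous"), sigma > 0)
  tibble::tibble(trait = trait, kind = kind, meanlog = meanlog, sdlog = sdlog,
                 rate = rate, log_transform = log_transform, unit = unit,
                 beta = beta, beta_depth = beta_depth, opt = opt,
                 opt_depth = opt_depth, sigma = sigma)
}

#' Default synthetic trait set: 16 macrophyte functional traits
#'
#' The generator's default traits mirror a macrophyte trait set: three
#' presence-type traits coded 1/2 (floating leaves, perennial growth form,
#' tubers) and thirteen continuous traits (phenology, morphology and leaf
#' chemistry) with lognormal species distributions on realistic scales.
#' Filtering strengths encode the qualitative structure such data show: leaf
#' dry mass content the strongest overall filter, stem dry mass content and
#' leaf carbon tracking the gradient, tuber and leaf nitrogen flipping from
#' favoured in shallow water to penalized in deep water, and perenniality
#' essentially neutral.
#'
#' @return A 16-row trait specification tibble.
#' @export
default_trait_specs <- function() {
  dplyr::bind_rows(
    trait_spec("floating_leaf", "binary12", rate = 0.3, unit = "1=no,2=yes",
               beta = 0.5),
    trait_spec("perennial", "binary12", rate = 0.7, unit = "1=no,2=yes"),
    trait_spec("tuber", "binary12", rate = 0.4, unit = "1=no,2=yes",
               beta = 0.6, beta_depth = -0.8),
    trait_spec("mean_julian_flowering_date", meanlog = log(200), sdlog = 0.15,
               unit = "day", beta = 0.6),
    trait_spec("flowering_duration", meanlog = log(40), sdlog = 0.4,
               unit = "day", beta = 0.6),
    trait_spec("ramet_size", meanlog = log(50), sdlog = 0.8, unit = "mg",
               beta = 0.3),
    trait_spec("shoot_height", meanlog = log(80), sdlog = 0.6, unit = "cm",
               beta = 0.5),
    trait_spec("stem_diameter", meanlog = log(1.5), sdlog = 0.4, unit = "mm",
               log_transform = FALSE, beta = 0.2),
    trait_spec("sla", meanlog = log(20), sdlog = 0.4, unit = "m2 kg-1",
               beta = 0.6),
    trait_spec("ldmc", meanlog = log(0.12), sdlog = 0.3, unit = "g g-1",
               beta = 1.2),
    trait_spec("lamina_thickness", meanlog = log(0.2), sdlog = 0.4,
               unit = "mm", log_transform = FALSE, beta = 0.2),
    trait_spec("rooting_depth", meanlog = log(10), sdlog = 0.6, unit = "cm",
               log_transform = FALSE, beta = -0.4),
    trait_spec("sdmc", meanlog = log(0.15), sdlog = 0.3, unit = "g g-1",
               beta = 0.5, beta_depth = 0.4),
    trait_spec("leaf_n", meanlog = log(25), sdlog = 0.3, unit = "mg g-1",
               beta = 0.8, beta_depth = -0.7),
    trait_spec("leaf_c", meanlog = log(350), sdlog = 0.1, unit = "mg g-1",
               beta = -0.5, beta_depth = 0.3),
    trait_spec("leaf_cn", meanlog = log(15), sdlog = 0.3, unit = "g g-1",
               beta = 0.3)
  )
}

#' Parameters of the synthetic community generator
#'
#' Bundles everything the generator needs: community dimensions (default: 17
#' species sampled at 7 sites with 6 plots per site at 0.5 m depth intervals
#' from 0.5 to 3.0 m, i.e. 42 plots, matching a lake macrophyte survey
#' design), per-trait distributions and filtering kernels, site random-effect
#' and multiplicative lognormal noise magnitudes, a structural-zero thinning
#' rate, and the seed that makes the dataset bit-reproducible.
#'
#' @param S Number of species (default 17).
#' @param n_sites Number of sites (default 7).
#' @param depths Depths (m) sampled within each site (default
#'   `seq(0.5, 3, by = 0.5)`).
#' @param traits Trait specification tibble ([trait_spec()] rows); default
#'   [default_trait_specs()].
#' @param noise_sd SD of Gaussian noise on log abundance (lognormal
#'   multiplicative noise; default 0.5).
#' @param site_sd SD of the site random intercept on log abundance
#'   (default 0.2).
#' @param zero_rate Independent structural-zero thinning probability
#'   (default 0.1).
#' @param base_abundance Median abundance scale, kg dry weight per m2
#'   (default 0.1).
#' @param seed Integer seed (default 1).
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(S = 17, n_sites = 7, depths = seq(0.5, 3, by = 0.5),
                            traits = default_trait_specs(), noise_sd = 0.5,
                            site_sd = 0.2, zero_rate = 0.1,
                            base_abundance = 0.1, seed = 1) {
  stopifnot(S >= 2, n_sites >= 1, length(depths) >= 1, all(traits$sigma > 0),
            noise_sd >= 0, site_sd >= 0, zero_rate >= 0, zero_rate < 1,
            is.finite(traits$beta), is.finite(traits$beta_depth))
  structure(list(S = S, n_sites = n_sites, depths = depths, traits = traits,
                 noise_sd = noise_sd, site_sd = site_sd, zero_rate = zero_rate,
                 base_abundance = base_abundance, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic community truth: ", x$S, " species, ", nrow(x$traits),
      " traits, ", x$n_sites, " sites x ", length(x$depths),
      " depths (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Trait metadata implied by a synthetic truth
#' @param truth A `"synthetic_truth"`.
#' @return Tibble `trait`, `kind`, `log_transform`, `unit`.
#' @export
truth_trait_meta <- function(truth) {
  dplyr::select(truth$traits, "trait", "kind", "log_transform", "unit")
}

#' Draw a species-by-trait table from a synthetic truth
#'
#' Continuous traits are lognormal across species (so strictly positive);
#' binary traits are Bernoulli draws mapped to the 1/2 coding, with one entry
#' flipped if a draw comes out constant so that both levels are present.
#' Deterministic given `seed`.
#'
#' @param truth A `"synthetic_truth"`.
#' @param seed Seed; defaults to the truth's own seed.
#' @return A trait tibble with metadata attached, as from [read_trait_table()].
#' @export
generate_traits <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$traits
  withr::with_seed(seed, {
    cols <- lapply(seq_len(nrow(spec)), function(j) {
      if (spec$kind[j] == "binary12") {
        x <- stats::rbinom(truth$S, 1, spec$rate[j]) + 1
        # a non-degenerate rate should yield both levels (standardization
        # needs variance); degenerate rates 0/1 are honoured as constant
        if (length(unique(x)) == 1 && spec$rate[j] > 0 && spec$rate[j] < 1)
          x[sample.int(truth$S, 1)] <- 3 - x[1]
        as.numeric(x)
      } else {
        stats::rlnorm(truth$S, spec$meanlog[j], spec$sdlog[j])
      }
    })
  })
  names(cols) <- spec$trait
  out <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("sp%02d", seq_len(truth$S))),
    tibble::as_tibble(cols))
  attr(out, "trait_meta") <- truth_trait_meta(truth)
  out
}

#' Generate plot-by-species abundances by trait-based filtering
#'
#' Log abundance of species i in plot k (depth d, site s) is
#' \deqn{\log A_{ik} = \sum_j \beta_j(d) z_{ij}
#'   - \sum_j (z_{ij} - opt_j(d))^2 / 2\sigma_j^2 + u_s + \epsilon_{ik}}
#' with \eqn{z_{ij}} the species' centred unit-variance trait score on the
#' trait's working scale (log where flagged), \eqn{u_s} a
#' Gaussian site effect and \eqn{\epsilon} Gaussian noise (multiplicative
#' lognormal on the abundance scale). Abundances are then thinned to zero
#' independently at the structural-zero rate, keeping at least one positive
#' species per plot. Deterministic given `seed`.
#'
#' @param truth A `"synthetic_truth"`.
#' @param traits Trait table from [generate_traits()].
#' @param seed Seed; defaults to the truth's seed plus one (so a dataset is
#'   reproducible from the truth alone).
#' @return A community tibble (`plot_id`, `site_id`, `depth_m`, species
#'   columns) in kg dry weight per m2.
#' @export
generate_communities <- function(truth, traits, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$traits
  stopifnot(identical(trait_names(traits), spec$trait))
  # fitness acts on centred unit-variance scores of the traits on their
  # working (log where flagged) scale, so selection is exponential-linear in
  # the same features the model fits
  Tmat <- trait_matrix(preprocess_traits(traits, truth_trait_meta(truth),
                                         standardize = FALSE))
  Z <- scale(Tmat)
  Z[is.nan(Z)] <- 0           # constant column -> no contrast, no filtering
  grid <- expand.grid(site = seq_len(truth$n_sites), depth = truth$depths)
  dbar <- mean(truth$depths)
  S <- truth$S
  withr::with_seed(seed, {
    u_site <- stats::rnorm(truth$n_sites, 0, truth$site_sd)
    A <- matrix(0, nrow(grid), S)
    for (k in seq_len(nrow(grid))) {
      d <- grid$depth[k]
      beta_d <- spec$beta + spec$beta_depth * (d - dbar)
      opt_d <- spec$opt + spec$opt_depth * (d - dbar)
      fitness <- drop(Z %*% beta_d)
      for (j in which(is.finite(spec$sigma))) {
        fitness <- fitness - (Z[, j] - opt_d[j])^2 / (2 * spec$sigma[j]^2)
      }
      logA <- log(truth$base_abundance) + fitness + u_site[grid$site[k]] +
        stats::rnorm(S, 0, truth$noise_sd)
      A[k, ] <- exp(logA)
    }
    if (truth$zero_rate > 0) {
      A_full <- A
      zero <- matrix(stats::runif(length(A)) < truth$zero_rate, nrow(A))
      A[zero] <- 0
      for (k in which(rowSums(A) == 0)) {
        i <- which.max(A_full[k, ])   # fully thinned plot: keep its dominant
        A[k, i] <- A_full[k, i]
      }
    }
  })
  out <- dplyr::bind_cols(
    tibble::tibble(plot_id = sprintf("s%02d_d%.1f", grid$site, grid$depth),
                   site_id = sprintf("s%02d", grid$site),
                   depth_m = grid$depth),
    tibble::as_tibble(`colnames<-`(A, traits$species)))
  out
}

#' Validation scenario: one trait whose filtering flips sign with depth
#'
#' A ready-made truth for direction-shift experiments: one trait whose
#' directional filtering strength runs linearly from +1.25 (shallow, 0.5 m)
#' to -1.25 (deep, 3.0 m) — species with high values are favoured in shallow
#' water and penalized in deep water — plus two unfiltered traits, under the
#' default survey geometry and moderate abundance noise.
#'
#' @param seed Integer seed.
#' @param S Number of species (default 17).
#' @param n_sites Number of sites (default 7).
#' @return A `"synthetic_truth"`.
#' @export
flip_filter_truth <- function(seed = 1, S = 17, n_sites = 7) {
  synthetic_truth(
    S = S, n_sites = n_sites, depths = seq(0.5, 3, by = 0.5),
    traits = dplyr::bind_rows(
      trait_spec("flip", beta = 0, beta_depth = -1),
      trait_spec("noise1"), trait_spec("noise2")),
    noise_sd = 0.4, zero_rate = 0.05, seed = seed)
}

#' Generate a complete synthetic dataset
#'
#' @inheritParams generate_traits
#' @return A list with `truth`, `traits` (metadata attached), `meta`, and
#'   `community`, bit-reproducible from the truth's seed.
#' @export
simulate_dataset <- function(truth) {
  traits <- generate_traits(truth)
  community <- generate_communities(truth, traits)
  list(truth = truth, traits = traits, meta = truth_trait_meta(truth),
       community = community)
}

#' Recovery experiment: does the pipeline recover the generator's truth?
#'
#' For each replicate, generates a dataset from `truth` (re-seeded per
#' replicate), then measures: the pooled variance explained by maxent with
#' observed CWM constraints; the same with gradient-fitted CWM constraints
#' (full trait set); the sign agreement between each directionally filtered
#' trait's mean lambda and its mean filtering strength; and, for traits whose
#' filtering strength flips sign across the depth range, whether the lambda
#' trend flags a significant direction shift.
#'
#' @param truth A `"synthetic_truth"`.
#' @param n_replicates Number of replicates (default 10).
#' @param seed Base seed; replicate r uses `seed + 1000 * r`.
#' @inheritParams solve_maxent
#' @return An object of class `"recovery_report"`: per-replicate tibble
#'   `replicates` and aggregate tibble `summary`.
#' @export
recovery_experiment <- function(truth, n_replicates = 10, seed = 1,
                                tol = 1e-7, max_iter = 1e5, lambda_cap = 1e3) {
  spec <- truth$traits
  drange <- range(truth$depths)
  dbar <- mean(truth$depths)
  beta_lo <- spec$beta + spec$beta_depth * (drange[1] - dbar)
  beta_hi <- spec$beta + spec$beta_depth * (drange[2] - dbar)
  directional <- spec$trait[spec$beta != 0 | spec$beta_depth != 0]
  flips <- spec$trait[sign(beta_lo) * sign(beta_hi) < 0]
  mean_beta <- setNames((beta_lo + beta_hi) / 2, spec$trait)

  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    tr <- truth
    tr$seed <- as.integer(seed + 1000 * r)
    ds <- simulate_dataset(tr)
    std <- preprocess_traits(ds$traits, standardize = TRUE)
    ra <- relative_abundance(ds$community)
    cwm <- compute_cwm(ra, std)
    ens <- solve_all_plots(std, cwm, tol = tol, max_iter = max_iter,
                           lambda_cap = lambda_cap)
    ve_obs <- variance_explained(ra, ens)$variance_explained
    ml <- mean_lambda(ens)
    dir_traits <- setdiff(directional, flips)
    sign_ok <- if (length(dir_traits)) {
      mean(sign(ml$mean_lambda[match(dir_traits, ml$trait)]) ==
             sign(mean_beta[dir_traits]))
    } else NA_real_

    gf <- suppressWarnings(fit_cwm_vs_depth(cwm))
    fwd <- suppressMessages(forward_gradient_order(std, ds$community,
                                                   gradient_fit = gf,
                                                   preprocess = FALSE,
                                                   tol = tol,
                                                   max_iter = max_iter,
                                                   lambda_cap = lambda_cap))
    ve_fit <- fwd$steps$variance_explained[nrow(fwd$steps)]

    raw <- preprocess_traits(ds$traits, standardize = FALSE)
    ens_raw <- solve_all_plots(raw, compute_cwm(ra, raw), tol = tol,
                               max_iter = max_iter, lambda_cap = lambda_cap)
    lt <- suppressWarnings(suppressMessages(
      lambda_depth_trend(ens_raw, ds$community$depth_m, ds$community$site_id)))
    flip_hit <- if (length(flips))
      mean(lt$trend$significant_shift[match(flips, lt$trend$trait)]) else NA_real_
    noise_traits <- setdiff(spec$trait, directional)
    flip_false <- if (length(noise_traits))
      mean(lt$trend$significant_shift[match(noise_traits, lt$trend$trait)])
    else NA_real_

    tibble::tibble(replicate = r, ve_observed = ve_obs, ve_fitted = ve_fit,
                   lambda_sign_recovery = sign_ok,
                   flip_detection = flip_hit,
                   flip_false_positive = flip_false)
  })
  summary <- tibble::tibble(
    n_replicates = n_replicates,
    mean_ve_observed = mean(reps$ve_observed),
    mean_ve_fitted = mean(reps$ve_fitted),
    mean_lambda_sign_recovery = mean(reps$lambda_sign_recovery, na.rm = TRUE),
    flip_detection_rate = mean(reps$flip_detection, na.rm = TRUE),
    flip_false_positive_rate = mean(reps$flip_false_positive, na.rm = TRUE))
  structure(list(replicates = reps, summary = summary, truth = truth,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery experiment (", nrow(x$replicates), " replicates)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$replicates

#' @export
glance.recovery_report <- function(x, ...) x$summary
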