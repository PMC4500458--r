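test_that("noiseless linear CWM on one site falls back to OLS and is exact", {
  depth <- rep(seq(0.5, 3, 0.5), 2)
  cwm <- tibble::tibble(plot_id = sprintf("p%02d", seq_along(depth)),
                        site_id = "s1", depth_m = depth,
                        a = 1 + 2 * depth)
  gf <- suppressWarnings(fit_cwm_vs_depth(cwm))
  expect_equal(gf$coef$slope, 2, tolerance = 1e-10)
  expect_equal(gf$coef$intercept, 1, tolerance = 1e-10)
  expect_equal(gf$coef$r2, 1, tolerance = 1e-10)
  expect_equal(gf$coef$model, "ols")
  expect_equal(gf$fitted_cwm$a, 1 + 2 * depth, tolerance = 1e-10)
})

test_that("depth-independent CWM gives near-zero gradient R2", {
  set.seed(6)
  depth <- rep(seq(0.5, 3, 0.5), 9)  # 54 plots
  site <- rep(sprintf("s%d", 1:9), each = 6)
  r2s <- replicate(20, {
    cwm <- tibble::tibble(plot_id = seq_along(depth), site_id = site,
                          depth_m = depth, a = stats::rnorm(length(depth)))
    suppressWarnings(fit_cwm_vs_depth(cwm))$coef$r2
  })
  expect_lt(mean(r2s), 0.1)
})

test_that("mixed model recovers a depth slope simulated from its own model", {
  set.seed(9)
  depth <- rep(seq(0.5, 3, 0.5), 6)
  site <- rep(sprintf("s%d", 1:6), each = 6)
  hits <- replicate(100, {
    b1 <- stats::runif(1, -2, 2)
    u <- stats::rnorm(6, 0, 0.5)[as.integer(factor(site))]
    y <- 1 + b1 * depth + u + stats::rnorm(length(depth), 0, 0.3)
    d <- data.frame(y, depth, site)
    f <- suppressWarnings(suppressMessages(
      lmerTest::lmer(y ~ depth + (1 | site), data = d)))
    est <- lme4::fixef(f)[2]
    se <- sqrt(diag(as.matrix(stats::vcov(f))))[2]
    abs(est - b1) <= 2 * se
  })
  expect_gte(mean(hits), 0.93)
})

test_that("a depth-drifting trait optimum moves its CWM along the gradient", {
  truth <- synthetic_truth(
    S = 15, n_sites = 4, depths = seq(0.5, 3, 0.5),
    traits = dplyr::bind_rows(
      trait_spec("tracker", sigma = 0.6, opt = 0, opt_depth = 1.2),
      trait_spec("noise")),
    noise_sd = 0, site_sd = 0, zero_rate = 0, seed = 99)
  ds <- simulate_dataset(truth)
  std <- preprocess_traits(ds$traits)
  cwm <- compute_cwm(relative_abundance(ds$community), std)
  by_depth <- dplyr::summarise(dplyr::group_by(cwm, .data$depth_m),
                               cwm = mean(.data$tracker))
  expect_gt(stats::cor(by_depth$depth_m, by_depth$cwm, method = "spearman"), 0)
  gf <- suppressWarnings(fit_cwm_vs_depth(cwm))
  expect_gt(gf$coef$slope[gf$coef$trait == "tracker"], 0)
})

test_that("backward stepwise is single-step for one trait and non-increasing", {
  set.seed(10)
  tr <- make_traits(matrix(stats::rlnorm(8), 8, 1))
  cm <- make_cm(matrix(stats::rexp(32), 4, 8))
  path <- backward_stepwise(tr, cm)
  expect_equal(nrow(path$steps), 1)
  expect_true(is.na(path$steps$changed_trait))

  tr4 <- make_traits(matrix(stats::rlnorm(32), 8, 4))
  path4 <- backward_stepwise(tr4, cm)
  expect_equal(nrow(path4$steps), 4)
  expect_equal(path4$steps$n_traits, 4:1)
  # nested constraint sets cannot fit better
  expect_true(all(diff(path4$steps$variance_explained) <= 1e-6))
})

test_that("a pure-noise trait is eliminated before the filtering traits", {
  removed_first <- vapply(1:50, function(r) {
    truth <- synthetic_truth(
      S = 12, n_sites = 3, depths = seq(0.5, 3, 0.5)[1:4],
      traits = dplyr::bind_rows(trait_spec("sig1", beta = 1.5),
                                trait_spec("sig2", beta = -1.5),
                                trait_spec("noise")),
      noise_sd = 0.4, zero_rate = 0, seed = 100 + r)
    ds <- simulate_dataset(truth)
    path <- backward_stepwise(ds$traits, ds$community)
    path$steps$changed_trait[1]
  }, character(1))
  expect_gte(mean(removed_first == "noise"), 0.9)
})

test_that("forward entry follows descending gradient R2 with clipped fitted CWMs", {
  # fixture ranking on the trait scale of the printed forward ordering:
  # stem dry mass content first (r2 0.47), leaf carbon second (0.42)
  set.seed(14)
  tr <- make_traits(matrix(stats::rlnorm(10 * 4), 10, 4))
  names(tr)[2:5] <- c("sdmc", "leaf_c", "leaf_n", "flowering_duration")
  attr(tr, "trait_meta") <- make_meta(tr)
  cm <- make_cm(matrix(stats::rexp(40), 4, 10), depth = c(0.5, 1, 1.5, 2))
  std <- preprocess_traits(tr)
  cwm <- compute_cwm(relative_abundance(cm), std)
  gf <- suppressWarnings(fit_cwm_vs_depth(cwm))
  gf$coef$r2 <- c(0.47, 0.42, 0.26, 0.16)[match(gf$coef$trait, names(tr)[2:5])]
  fwd <- suppressMessages(
    forward_gradient_order(std, cm, gradient_fit = gf, preprocess = FALSE))
  expect_equal(fwd$ranking,
               c("sdmc", "leaf_c", "leaf_n", "flowering_duration"))
  expect_equal(fwd$steps$changed_trait, fwd$ranking)
})

test_that("with noiseless linear CWMs the forward path matches the backward path", {
  # communities whose CWMs are exactly linear in depth: regression predictions
  # equal observed CWMs, so fitted-constraint fits equal observed-constraint fits
  set.seed(15)
  S <- 6
  tr <- make_traits(matrix(stats::rlnorm(S * 2), S, 2))
  std <- preprocess_traits(tr)
  Tm <- as.matrix(std[, -1])
  depth <- seq(0.5, 3, 0.5)
  # build abundances with log-linear depth dependence -> CWMs almost linear;
  # instead construct p directly so CWM is exactly linear: mix two endpoints
  p_lo <- rep(1 / S, S)
  p_hi <- (1:S) / sum(1:S)
  w <- (depth - min(depth)) / diff(range(depth))
  P <- t(sapply(w, function(wk) (1 - wk) * p_lo + wk * p_hi))
  cm <- make_cm(P, depth = depth)
  cwm <- compute_cwm(relative_abundance(cm), std)
  for (j in c("t1", "t2"))
    expect_equal(unname(lm(cwm[[j]] ~ depth)$residuals),
                 rep(0, length(depth)), tolerance = 1e-10)
  gf <- suppressWarnings(fit_cwm_vs_depth(cwm))
  fwd <- suppressMessages(
    forward_gradient_order(std, cm, gradient_fit = gf, preprocess = FALSE))
  bwd <- backward_stepwise(std, cm, preprocess = FALSE)
  for (s in seq_len(nrow(fwd$steps))) {
    set_f <- sort(fwd$steps$traits[[s]])
    match_b <- which(vapply(bwd$steps$traits, function(x)
      identical(sort(x), set_f), logical(1)))
    if (length(match_b))
      expect_equal(fwd$steps$variance_explained[s],
                   bwd$steps$variance_explained[match_b], tolerance = 1e-3)
  }
})

test_that("lambda trends detect constancy and constructed sign changes", {
  set.seed(16)
  tr <- make_traits(matrix(stats::rlnorm(6 * 2), 6, 2))
  depth <- rep(seq(0.5, 3, 0.5), 2)
  site <- rep(c("s1", "s2"), each = 6)
  # constant lambda: identical CWM constraints in every plot
  std <- preprocess_traits(tr)
  Tm <- as.matrix(std[, -1])
  b0 <- drop(crossprod(Tm, rep(1 / 6, 6) + c(.1, -.1, .05, -.05, 0, 0)))
  cwm <- tibble::tibble(plot_id = sprintf("p%02d", seq_along(depth)),
                        site_id = site, depth_m = depth,
                        t1 = b0[1], t2 = b0[2])
  ens <- solve_all_plots(std, cwm)
  lt <- suppressWarnings(lambda_depth_trend(ens, depth, site))
  expect_equal(lt$trend$slope, c(0, 0), tolerance = 1e-6)
  expect_false(any(lt$trend$direction_shift))

  # constructed sign change: +1 at 0.5 m to -1 at 3.0 m
  fake <- ens
  lam_line <- 1 - 2 * (depth - 0.5) / 2.5
  for (k in seq_along(fake$fits))
    fake$fits[[k]]$lambda <- c(t1 = lam_line[k], t2 = 0.3)
  lt2 <- suppressWarnings(lambda_depth_trend(fake, depth, site))
  expect_true(lt2$trend$direction_shift[lt2$trend$trait == "t1"])
  expect_true(lt2$trend$significant_shift[lt2$trend$trait == "t1"])
  expect_false(lt2$trend$direction_shift[lt2$trend$trait == "t2"])
})

test_that("non-converged plots are excluded from lambda trends", {
  set.seed(18)
  tr <- make_traits(matrix(stats::rlnorm(5 * 1), 5, 1))
  std <- preprocess_traits(tr)
  depth <- seq(0.5, 3, 0.5)
  Tm <- as.matrix(std[, -1])
  b <- seq(min(Tm) + 0.01, max(Tm) - 0.01, length.out = 6)
  cwm <- tibble::tibble(plot_id = sprintf("p%d", 1:6), site_id = "s1",
                        depth_m = depth, t1 = b)
  ens <- solve_all_plots(std, cwm)
  ens$fits[[3]]$converged <- FALSE
  expect_message(
    lt <- suppressWarnings(lambda_depth_trend(ens, depth, rep("s1", 6))),
    "excluded")
  expect_equal(nrow(lt$data), 5)
  expect_equal(lt$n_excluded, 1)
})
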