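test_that("no constraints returns the prior; satisfied constraints give lambda 0", {
  fit <- solve_maxent(matrix(numeric(0), 3, 0), numeric(0))
  expect_equal(unname(fit$p_hat), rep(1 / 3, 3))
  expect_true(fit$converged)

  fit2 <- solve_maxent(matrix(c(0, 1, 2), 3, 1), constraints = 1)
  expect_equal(unname(fit2$p_hat), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(unname(fit2$lambda), 0, tolerance = 1e-9)

  prior <- c(0.5, 0.3, 0.2)
  fit3 <- solve_maxent(matrix(c(0, 1, 2), 3, 1),
                       constraints = sum(prior * c(0, 1, 2)), prior = prior)
  expect_equal(unname(fit3$p_hat), prior, tolerance = 1e-9)
})

test_that("analytic three-species worked example is reproduced by both solvers", {
  # constraint 1.5 on trait (0,1,2): e^lambda solves x^2 - x - 3 = 0
  x <- (1 + sqrt(13)) / 2
  p_exact <- c(1, x, x^2) / (1 + x + x^2)
  for (method in c("dual", "iis")) {
    fit <- solve_maxent(matrix(c(0, 1, 2), 3, 1), constraints = 1.5,
                        method = method)
    expect_equal(unname(fit$p_hat), p_exact, tolerance = 1e-6)
    expect_equal(unname(fit$lambda), log(x), tolerance = 1e-5)
    expect_true(fit$converged)
  }
  expect_equal(round(unname(solve_maxent(matrix(c(0, 1, 2), 3, 1), 1.5)$p_hat), 4),
               c(0.1162, 0.2676, 0.6162))
})

test_that("dual solver agrees with the primal entropy-maximization oracle", {
  skip_if_not_installed("MASS")
  set.seed(11)
  for (r in 1:30) {
    S <- sample(2:4, 1)
    m <- sample(1:min(2, S - 1), 1)
    T <- matrix(stats::rlnorm(S * m), S, m)
    p_true <- stats::rgamma(S, 2); p_true <- p_true / sum(p_true)
    b <- drop(crossprod(T, p_true))
    fit <- solve_maxent(T, b, lambda_cap = 1e7)
    oracle <- primal_entropy_oracle(T, p_true)
    expect_equal(unname(fit$p_hat), oracle, tolerance = 1e-5)
  }
})

test_that("IIS and dual Newton find the same fixed point", {
  set.seed(5)
  for (r in 1:20) {
    S <- sample(3:10, 1)
    m <- sample(1:min(3, S - 1), 1)  # identifiable lambda
    T <- matrix(stats::rlnorm(S * m), S, m)
    p_true <- stats::rgamma(S, 2); p_true <- p_true / sum(p_true)
    b <- drop(crossprod(T, p_true))
    # iterative scaling stops on the per-sweep change in p, which lags the
    # distance to the fixed point; run it tighter for the comparison
    f1 <- solve_maxent(T, b, method = "dual", tol = 1e-10)
    f2 <- solve_maxent(T, b, method = "iis", tol = 1e-10)
    expect_equal(f1$p_hat, f2$p_hat, tolerance = 1e-5)
    expect_equal(f1$lambda, f2$lambda, tolerance = 1e-3)
  }
})

test_that("solutions stay on the simplex and satisfy the constraints", {
  set.seed(23)
  for (r in 1:25) {
    S <- sample(3:12, 1)
    m <- sample(1:min(4, S - 1), 1)
    T <- matrix(stats::rlnorm(S * m), S, m)
    p_true <- stats::rgamma(S, 1); p_true <- p_true / sum(p_true)
    b <- drop(crossprod(T, p_true))
    fit <- solve_maxent(T, b)
    expect_equal(sum(fit$p_hat), 1, tolerance = 1e-9)
    expect_true(all(fit$p_hat > 0))
    if (fit$converged) {
      rng <- apply(T, 2, function(x) diff(range(x)))
      expect_true(all(abs(fit$constraint_residual) <= 10 * 1e-7 * rng))
    }
  }
})

test_that("lambda is translation invariant and scale covariant", {
  set.seed(99)
  for (r in 1:15) {
    S <- 6; m <- 2
    T <- matrix(stats::rlnorm(S * m), S, m)
    p_true <- stats::rgamma(S, 2); p_true <- p_true / sum(p_true)
    b <- drop(crossprod(T, p_true))
    fit <- solve_maxent(T, b)

    cshift <- stats::runif(1, 0.5, 3)
    T2 <- T; T2[, 1] <- T2[, 1] + cshift
    fit2 <- solve_maxent(T2, b + c(cshift, 0))
    expect_equal(fit2$p_hat, fit$p_hat, tolerance = 1e-6)
    expect_equal(fit2$lambda, fit$lambda, tolerance = 1e-6)

    s <- stats::runif(1, 0.2, 5)
    T3 <- T; T3[, 1] <- T3[, 1] * s
    fit3 <- solve_maxent(T3, b * c(s, 1))
    expect_equal(fit3$p_hat, fit$p_hat, tolerance = 1e-6)
    expect_equal(unname(fit3$lambda),
                 unname(fit$lambda) * c(1 / s, 1), tolerance = 1e-6)
  }
})

test_that("a near-boundary or out-of-hull constraint is flagged, not silent", {
  T <- matrix(c(0, 1, 2), 3, 1)
  fit <- solve_maxent(T, constraints = 2.5)  # outside [0, 2]
  expect_false(fit$converged)
  expect_true(abs(fit$lambda) >= 1e3 - 1e-9 || fit$iterations == 1e5)
  expect_error(solve_maxent(matrix(c(0, NA, 1), 3, 1), 0.5), "non-finite")
})

test_that("m = S - 1 full-rank constraints recover the observed distribution", {
  set.seed(17)
  for (r in 1:5) {
    S <- sample(3:8, 1)
    T <- matrix(stats::rlnorm(S * (S - 1)), S, S - 1)
    p <- stats::rgamma(S, 3); p <- p / sum(p)
    fit <- solve_maxent(T, drop(crossprod(T, p)))
    expect_equal(unname(fit$p_hat), p, tolerance = 1e-6)
  }
})

test_that("per-plot solves are independent, ordered and deterministic", {
  set.seed(31)
  tr <- make_traits(matrix(stats::rlnorm(6 * 2), 6, 2))
  cm <- make_cm(matrix(stats::rexp(18), 3, 6), depth = c(0.5, 1, 1.5))
  ra <- relative_abundance(cm)
  cwm <- compute_cwm(ra, tr)
  ens <- solve_all_plots(tr, cwm)
  expect_equal(ens$plot_ids, cm$plot_id)
  single <- solve_maxent(tr, unlist(cwm[1, c("t1", "t2")]))
  expect_equal(ens$fits[[1]]$p_hat, single$p_hat)

  # duplicated constraints give identical predictions
  cwm2 <- cwm; cwm2[2, c("t1", "t2")] <- cwm[1, c("t1", "t2")]
  ens2 <- solve_all_plots(tr, cwm2)
  expect_equal(ens2$fits[[1]]$p_hat, ens2$fits[[2]]$p_hat)

  ens3 <- solve_all_plots(tr, cwm)
  expect_identical(lambda_matrix(ens), lambda_matrix(ens3))
})

test_that("variance explained matches hand-computed pooled R2", {
  obs <- relative_abundance(make_cm(rbind(c(1, 0), c(0, 1))))
  pred <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(variance_explained(obs, pred)$variance_explained, 0.96)

  expect_equal(variance_explained(obs, rbind(c(1, 0), c(0, 1)))$variance_explained, 1)

  unif <- relative_abundance(make_cm(rbind(c(1, 1), c(1, 1))))
  expect_error(variance_explained(unif, rbind(c(.5, .5), c(.5, .5))),
               "zero total variance")
})

test_that("mean lambda averages signed and absolute values across plots", {
  set.seed(2)
  tr <- make_traits(matrix(stats::rlnorm(5), 5, 1))
  cm <- make_cm(matrix(stats::rexp(5), 1, 5))
  ens <- solve_all_plots(tr, compute_cwm(relative_abundance(cm), tr))
  ml <- mean_lambda(ens)
  expect_equal(ml$mean_lambda, unname(ens$fits[[1]]$lambda))

  fake <- ens
  fake$fits <- list(ens$fits[[1]], ens$fits[[1]])
  fake$fits[[2]]$lambda <- -fake$fits[[1]]$lambda
  fake$plot_ids <- c("a", "b")
  ml2 <- mean_lambda(fake)
  expect_equal(ml2$mean_lambda, 0)
  expect_equal(ml2$mean_abs_lambda, abs(unname(ens$fits[[1]]$lambda)))
})

test_that("mean lambda recovers the sign of a positive synthetic filter", {
  truth <- synthetic_truth(
    S = 12, n_sites = 2, depths = seq(0.5, 3, 0.5),
    traits = dplyr::bind_rows(trait_spec("driver", beta = 1.5),
                              trait_spec("noise")),
    noise_sd = 0.3, zero_rate = 0, seed = 404)
  ds <- simulate_dataset(truth)
  std <- preprocess_traits(ds$traits)
  ra <- relative_abundance(ds$community)
  ens <- solve_all_plots(std, compute_cwm(ra, std))
  ml <- mean_lambda(ens)
  expect_gt(ml$mean_lambda[ml$trait == "driver"], 0)
  expect_gt(ml$mean_abs_lambda[ml$trait == "driver"],
            ml$mean_abs_lambda[ml$trait == "noise"])
})

test_that("near-collinear trait sets trigger a condition-number warning", {
  set.seed(8)
  x <- stats::rlnorm(6)
  tr <- make_traits(cbind(a = x, b = x * (1 + 1e-12)))
  cwm <- compute_cwm(relative_abundance(make_cm(matrix(stats::rexp(6), 1, 6))), tr)
  expect_warning(solve_all_plots(tr, cwm), "condition number")
})
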