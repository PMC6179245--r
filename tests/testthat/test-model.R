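test_that("marginal likelihood matches explicit enumeration over the use state", {
  # worked values
  expect_equal(site_marginal_loglik(1, 0.5, c(1, 0)), log(0.25))
  expect_equal(site_marginal_loglik(0.6, 0.3, c(0, 0, 0)),
               log(0.6 * 0.7^3 + 0.4))
  expect_equal(site_marginal_loglik(0, 0.9, c(0, 0)), 0)
  # impossible data returns -Inf, not an error
  expect_identical(site_marginal_loglik(1, 0, c(1)), -Inf)

  # exhaustive oracle over all y-patterns for J <= 4
  for (J in 1:4) {
    pats <- as.matrix(expand.grid(rep(list(0:1), J)))
    for (psi in c(0, 0.25, 0.8, 1)) {
      p <- seq(0.1, 0.7, length.out = J)
      for (r in seq_len(nrow(pats))) {
        y <- pats[r, ]
        # independent enumeration: sum over Z in {0, 1}
        lik_z1 <- psi * prod(p^y * (1 - p)^(1 - y))
        lik_z0 <- (1 - psi) * as.numeric(all(y == 0))
        expect_equal(site_marginal_loglik(psi, p, y), log(lik_z1 + lik_z0))
      }
    }
  }
})

test_that("marginal likelihood conserves probability over all y-patterns", {
  for (J in 1:3) {
    pats <- as.matrix(expand.grid(rep(list(0:1), J)))
    p <- seq(0.2, 0.6, length.out = J)
    for (psi in c(0.1, 0.5, 0.9)) {
      tot <- sum(apply(pats, 1, function(y)
        exp(site_marginal_loglik(psi, p, y))))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("latent-use full conditional follows Bayes rule", {
  expect_equal(update_latent_Z(0.7, 0.4, c(0, 1, 0)), 1)  # detection pins Z
  expect_equal(update_latent_Z(0.5, 0.5, 0), 1 / 3)       # 0.25 / 0.75
  expect_equal(update_latent_Z(0.5, 1, 0), 0)             # certain detection
  expect_equal(update_latent_Z(0.5, 0.3, numeric(0)), 0.5) # no occasions
  # generic hand-computed case
  psi <- 0.6; p <- c(0.2, 0.5)
  q <- prod(1 - p)
  expect_equal(update_latent_Z(psi, p, c(0, 0)),
               psi * q / (psi * q + 1 - psi))
})

test_that("R-hat matches the between/within form and flags divergence", {
  set.seed(21)
  n <- 1000
  # identical chains: B = 0, so R-hat is exactly sqrt((n-1)/n)
  ch <- rnorm(n)
  expect_equal(unname(compute_rhat(cbind(ch, ch))), sqrt((n - 1) / n),
               tolerance = 1e-12)

  # two chains around 0 and 5: closed-form B/W computation
  c1 <- rnorm(n); c2 <- rnorm(n, 5)
  x <- cbind(c1, c2)
  W <- mean(c(var(c1), var(c2)))
  B_over_n <- var(c(mean(c1), mean(c2)))
  expect_equal(unname(compute_rhat(x)),
               sqrt(((n - 1) / n * W + B_over_n) / W))
  expect_gt(compute_rhat(x), 1.1)

  # three iid standard-normal chains converge
  x3 <- array(rnorm(3 * n), dim = c(n, 1, 3))
  expect_lt(compute_rhat(x3), 1.05)

  expect_error(compute_rhat(matrix(rnorm(50), ncol = 1)), "2 chains")
})

test_that("R-hat agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(22)
  n <- 500
  # near-stationary chains with a mild mean offset; the implementations
  # differ only by coda's finite-sample d.f. correction here
  x <- cbind(rnorm(n), rnorm(n, 0.3))
  ours <- unname(compute_rhat(x))
  ml <- coda::mcmc.list(coda::mcmc(x[, 1, drop = FALSE]),
                        coda::mcmc(x[, 2, drop = FALSE]))
  ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  # coda applies a d.f. correction; agreement to a few percent
  expect_equal(ours, ref, tolerance = 0.05)
})

test_that("model averaging equals direct summation over indicator draws", {
  n <- 400
  set.seed(23)
  alpha <- rnorm(n, 2)
  w <- rep(c(1, 0), n / 2)
  draws <- cbind("alpha[x]" = alpha, "w[x]" = w,
                 alpha0 = rnorm(n), beta0 = rnorm(n), Zsum = rep(3, n))
  fit <- fake_fit(draws, d = c(1, 0, 0), n = c(2, 2, 2))
  ma <- model_average_coefficients(fit)
  expect_equal(ma$w, 0.5)
  expect_equal(ma$mean_averaged, mean(w * alpha))
  expect_equal(ma$mean_conditional, mean(alpha[w == 1]))

  # all included: averaged equals the plain posterior mean
  draws1 <- draws; draws1[, "w[x]"] <- 1
  ma1 <- model_average_coefficients(fake_fit(draws1, d = c(1, 0, 0),
                                             n = c(2, 2, 2)))
  expect_equal(ma1$mean_averaged, mean(alpha))

  # never included: averaged 0, conditional undefined with a warning
  draws0 <- draws; draws0[, "w[x]"] <- 0
  expect_warning(
    ma0 <- model_average_coefficients(fake_fit(draws0, d = c(1, 0, 0),
                                               n = c(2, 2, 2))),
    "never")
  expect_equal(ma0$mean_averaged, 0)
  expect_equal(ma0$w, 0)
  expect_true(is.na(ma0$mean_conditional))
})

test_that("sites-used summary is bounded below by the detected-site count", {
  # every site detected: the posterior of the total is degenerate
  n <- 100
  draws <- cbind(alpha0 = rnorm(n), beta0 = rnorm(n), Zsum = rep(5, n))
  est <- estimate_sites_used(fake_fit(draws, d = rep(1, 5), n = rep(3, 5)))
  expect_equal(est$mean, 5)
  expect_equal(est$sd, 0)

  # real fit: minimum over draws >= number of sites with detections
  set.seed(24)
  st <- simulate_stations(n_areas = 3, stations_per_area = c(8, 8, 8),
                          zones = c("national_park", "wma", "village_land"),
                          seed = 31)
  cv <- simulate_covariates(st, seed = 32)
  tr <- synthetic_truth(alpha = c(livestock = 0, dist_river = 0,
                                  dist_household = 0, cpue = 0),
                        n_areas = 3, seed = 33)
  sim <- simulate_detection_data(st, cv, tr, J = 10, seed = 34)
  fit <- fit_site_use(sim$history, NULL, area = st$area, trail = NULL,
                      settings = fast_mcmc(35, 4000, 1000, 5))
  est2 <- estimate_sites_used(fit)
  expect_gte(est2$min, sum(sim$history$n_events > 0))

  # psi -> 0 forces the total to concentrate at the detected-site count
  sim0 <- simulate_detection_data(st, cv,
                                  synthetic_truth(alpha = tr$alpha,
                                                  area_effects = rep(-7, 3),
                                                  n_areas = 3),
                                  J = 10, seed = 36)
  fit0 <- fit_site_use(sim0$history, NULL, area = st$area, trail = NULL,
                       config = site_use_config(tau_high = 3),
                       settings = fast_mcmc(37, 4000, 1000, 5))
  est0 <- estimate_sites_used(fit0)
  ndet <- sum(sim0$history$n_events > 0)
  expect_lt(est0$mean, ndet + 0.25 * nrow(st))
})

test_that("prediction curves respond to coefficients as expected", {
  n <- 300
  X <- matrix(scale(rnorm(20)), ncol = 1, dimnames = list(NULL, "x"))
  # all coefficients zero, mu = 0: flat curve at 0.5
  draws <- cbind("alpha[x]" = rep(0, n), "w[x]" = rep(1, n),
                 "a[A]" = rep(0, n), mu = rep(0, n), tau = rep(1, n),
                 beta0 = rep(-1, n), Zsum = rep(1, n))
  fit <- fake_fit(draws, X = X, random_intercept = TRUE, area_levels = "A",
                  d = rep(0, 20), n = rep(1, 20))
  cur <- predict_site_use_curve(fit, "x", seed = 1)
  expect_true(all(abs(cur$psi - 0.5) < 1e-12))

  # coefficient +1: value at z = 0 equals plogis(mu), curve non-decreasing
  draws2 <- draws
  draws2[, "alpha[x]"] <- 1
  draws2[, "mu"] <- rnorm(n, 0.3, 0.2)
  fit2 <- fake_fit(draws2, X = X, random_intercept = TRUE, area_levels = "A",
                   d = rep(0, 20), n = rep(1, 20))
  cur2 <- predict_site_use_curve(fit2, "x", grid = seq(-2, 2, 0.25), seed = 1)
  at0 <- cur2$psi[cur2$z == 0]
  expect_equal(at0, mean(plogis(draws2[, "mu"])), tolerance = 1e-10)
  expect_true(all(diff(cur2$psi) >= 0))
  expect_true(all(cur2$lower <= cur2$psi & cur2$psi <= cur2$upper))

  expect_error(predict_site_use_curve(fit2, "nope"), "unknown covariate")
})

test_that("fit validates inputs", {
  h <- list(y = rbind(c(1, 0), c(0, 0)), effort = matrix(7, 2, 2),
            sites = c("s1", "s2"))
  Xraw <- matrix(c(5, 9), ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fit_site_use(h, Xraw, area = c("A", "A"),
                            settings = fast_mcmc(1, 200, 50, 1, 2)),
               "standardized")
  expect_error(fit_site_use(h, NULL, area = factor(c("A", "A"),
                                                   levels = c("A", "B")),
                            settings = fast_mcmc(1, 200, 50, 1, 2)),
               "no stations")
  expect_error(fit_site_use(h, NULL, area = NULL,
                            settings = fast_mcmc(1, 200, 50, 1, 2)),
               "area is required")
})

test_that("posterior is invariant to covariate location shifts", {
  set.seed(26)
  S <- 40
  x_raw <- rnorm(S, 3, 2)
  h <- list(y = matrix(rbinom(S * 6, 1, 0.3), S, 6),
            effort = matrix(7, S, 6), sites = sprintf("s%02d", 1:S))
  area <- rep(c("A", "B"), each = S / 2)
  fit_a <- fit_site_use(h, matrix(scale(x_raw), ncol = 1,
                                  dimnames = list(NULL, "x")),
                        area = area, settings = fast_mcmc(27))
  fit_b <- fit_site_use(h, matrix(scale(x_raw + 100), ncol = 1,
                                  dimnames = list(NULL, "x")),
                        area = area, settings = fast_mcmc(27))
  # shifting then standardizing gives the same design up to rounding, so the
  # posteriors agree within Monte-Carlo error
  dma <- do.call(rbind, lapply(1:3, function(k) fit_a$draws[, , k]))
  dmb <- do.call(rbind, lapply(1:3, function(k) fit_b$draws[, , k]))
  for (par in c("alpha[x]", "mu", "tau", "beta0")) {
    se <- sd(dma[, par]) / sqrt(200)
    expect_lt(abs(mean(dma[, par]) - mean(dmb[, par])), 4 * se)
  }
})

test_that("area-label permutation permutes intercepts, leaves the rest", {
  set.seed(28)
  S <- 30
  x <- matrix(scale(rnorm(S)), ncol = 1, dimnames = list(NULL, "x"))
  h <- list(y = matrix(rbinom(S * 6, 1, 0.35), S, 6),
            effort = matrix(7, S, 6), sites = sprintf("s%02d", 1:S))
  area <- rep(c("A", "B", "C"), each = 10)
  # relabel so that old A -> zz (sorts last): partition unchanged
  area2 <- c(A = "zz", B = "B", C = "C")[area]
  fit1 <- fit_site_use(h, x, area = area, settings = fast_mcmc(29, 12000, 3000, 5))
  fit2 <- fit_site_use(h, x, area = area2, settings = fast_mcmc(30, 12000, 3000, 5))
  dm1 <- do.call(rbind, lapply(1:3, function(k) fit1$draws[, , k]))
  dm2 <- do.call(rbind, lapply(1:3, function(k) fit2$draws[, , k]))
  # matched-group posteriors agree within Monte-Carlo error
  se <- function(v) sd(v) / sqrt(200)   # generous effective size
  for (pair in list(c("a[A]", "a[zz]"), c("a[B]", "a[B]"), c("a[C]", "a[C]"),
                    c("mu", "mu"), c("tau", "tau"), c("alpha[x]", "alpha[x]"),
                    c("beta0", "beta0"))) {
    delta <- abs(mean(dm1[, pair[1]]) - mean(dm2[, pair[2]]))
    expect_lt(delta, 4 * (se(dm1[, pair[1]]) + se(dm2[, pair[2]])))
  }
})

test_that("summary table has the documented shape and coherent intervals", {
  set.seed(31)
  st <- simulate_stations(n_areas = 2, stations_per_area = c(10, 10),
                          zones = c("national_park", "village_land"),
                          seed = 41)
  cv <- simulate_covariates(st, seed = 42)
  tr <- synthetic_truth(alpha = c(livestock = -1, dist_river = 0,
                                  dist_household = 1, cpue = 0),
                        n_areas = 2, seed = 43)
  sim <- simulate_detection_data(st, cv, tr, J = 8, seed = 44)
  fit <- fit_site_use(sim$history, sim$covariates, area = st$area,
                      trail = st$trail_type, settings = fast_mcmc(45))
  s <- summary(fit)
  expect_s3_class(s, "summary.siteuse_fit")
  expect_true("n_sites_used" %in% s$parameter)
  ok <- !is.na(s$mean)
  expect_true(all(s$ci_low[ok] <= s$mean[ok] & s$mean[ok] <= s$ci_high[ok]))
  wrows <- grepl("^alpha\\[|^beta\\[", s$parameter)
  expect_true(all(s$w[wrows] >= 0 & s$w[wrows] <= 1))
  expect_output(print(fit), "Bayesian site-use model")
  expect_output(print(s), "n_sites_used")
})
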