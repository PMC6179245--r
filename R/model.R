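#' Model configuration for the Bayesian site-use model
#'
#' Priors and structural switches. Slopes and detection coefficients get
#' uninformative Uniform(`coef_low`, `coef_high`) priors; the area random
#' intercepts are Normal(`mu`, `tau^2`) with hyperpriors `mu ~
#' Normal(mu_mean, mu_sd^2)` and `tau ~ Uniform(tau_low, tau_high)` on the
#' SD scale. Each slope (and, when `select_detection = TRUE`, each trail
#' contrast) carries a Bernoulli(`inclusion_prior`) inclusion indicator
#' (Kuo-Mallick construction: the effective coefficient is `w_c * alpha_c`
#' and an excluded coefficient is refreshed from its prior).
#'
#' @param coef_low,coef_high Uniform prior bounds for all slopes and
#'   detection coefficients, logit scale (default -10, 10).
#' @param mu_mean,mu_sd Hyperprior for the area-intercept mean.
#' @param tau_low,tau_high Uniform hyperprior range for the between-area SD.
#' @param inclusion_prior Prior inclusion probability of each indicator.
#' @param select Apply indicator selection to the site-use slopes?
#' @param select_detection Apply indicator selection to the trail contrasts?
#' @param random_intercept Fit area-level random intercepts? If `FALSE` a
#'   single Uniform-prior intercept is used (the "naive" pooled model used
#'   for spatial-autocorrelation comparison).
#' @param reference_trail Reference trail-type level (default `"AT"`).
#' @return List of class `site_use_config`.
#' @export
site_use_config <- function(coef_low = -10, coef_high = 10,
                            mu_mean = 0, mu_sd = 10,
                            tau_low = 0, tau_high = 10,
                            inclusion_prior = 0.5,
                            select = TRUE, select_detection = TRUE,
                            random_intercept = TRUE,
                            reference_trail = "AT") {
  stopifnot(coef_low < coef_high, tau_low < tau_high,
            inclusion_prior > 0, inclusion_prior < 1, mu_sd > 0)
  structure(list(coef_low = coef_low, coef_high = coef_high,
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 tau_low = tau_low, tau_high = tau_high,
                 inclusion_prior = inclusion_prior,
                 select = select, select_detection = select_detection,
                 random_intercept = random_intercept,
                 reference_trail = reference_trail),
            class = "site_use_config")
}

#' MCMC settings
#'
#' Defaults follow common practice for this model class: three chains of
#' 500,000 iterations, the first 50,000 discarded as burn-in, thinned by 10.
#' Test-scale analyses run fine with far shorter chains.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations Iterations per chain (including burn-in).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval for retained draws.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @return List of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, iterations = 500000, burn_in = 50000,
                          thin = 10, seed = NULL) {
  stopifnot(chains >= 1, burn_in >= 0, burn_in < iterations, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mcmc_settings")
}

chain_seed <- function(master, chain) {
  as.integer((as.double(master) * 48271 + chain * 104729) %% 2147483629)
}

#' Fit the hierarchical Bayesian site-use model
#'
#' Fits a single-season site-use (occupancy) model with imperfect detection:
#' \deqn{Z_i \sim Bern(\psi_i), \quad logit(\psi_i) = \alpha_{area(i)} +
#'   \sum_c w_c \alpha_c x_{ic}}
#' \deqn{y_{ij} | Z_i \sim Bern(Z_i p_i), \quad logit(p_i) = \beta_0 +
#'   \beta_k Trail_i}
#' with area-level random intercepts and Bernoulli inclusion indicators on
#' the covariate effects, by Metropolis-within-Gibbs MCMC (latent `Z` and
#' all indicators by exact Gibbs).
#'
#' @param history A [build_detection_history()] object (or a list with `y`
#'   and `effort` matrices). Missing cells (zero effort) drop out of the
#'   detection likelihood.
#' @param covariates Standardized site covariates aligned with
#'   `history$sites`: a [zscore_standardize()]d `covariate_table`, a numeric
#'   matrix, or `NULL` for an intercept-only site-use model. Columns must
#'   have mean 0 and SD 1 (checked).
#' @param area Factor (or character) of sampling-area membership per site;
#'   required when `config$random_intercept` is `TRUE`.
#' @param trail Factor of trail type per site, or `NULL` for intercept-only
#'   detection. The reference category is `config$reference_trail`.
#' @param config A [site_use_config()].
#' @param settings An [mcmc_settings()].
#'
#' @return Object of class `siteuse_fit` with elements `draws` (array
#'   `n_kept x n_parameters x chains`), `parameters`, `rhat`, `data`,
#'   `config`, `settings`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `residuals`.
#' @seealso [summary.siteuse_fit()], [model_average_coefficients()],
#'   [estimate_sites_used()], [predict_site_use_curve()], [site_residuals()]
#' @export
fit_site_use <- function(history, covariates = NULL, area = NULL,
                         trail = NULL, config = site_use_config(),
                         settings = mcmc_settings()) {
  y <- history$y
  eff <- history$effort
  S <- nrow(y)
  d <- as.integer(rowSums(y == 1, na.rm = TRUE))
  n <- as.integer(rowSums(!is.na(y)))
  if (any(d > n)) stop("more detections than observed occasions at a site")

  # covariate design
  if (is.null(covariates)) {
    X <- matrix(0, nrow = S, ncol = 0)
    std <- NULL
  } else {
    if (is.data.frame(covariates)) {
      cols <- setdiff(names(covariates)[vapply(covariates, is.numeric,
                                               logical(1))], "station_id")
      X <- as.matrix(as.data.frame(covariates)[, cols, drop = FALSE])
      std <- list(center = attr(covariates, "center"),
                  scale = attr(covariates, "scale"))
    } else {
      X <- as.matrix(covariates)
      std <- NULL
    }
    if (nrow(X) != S) stop("covariates do not match the number of sites")
    mns <- colMeans(X); sds <- apply(X, 2, stats::sd)
    if (any(abs(mns) > 1e-6) || any(abs(sds - 1) > 1e-6)) {
      stop("covariates must be z-score standardized (mean 0, SD 1); ",
           "see zscore_standardize()")
    }
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  C <- ncol(X)

  # area structure
  if (config$random_intercept) {
    if (is.null(area)) stop("area is required when random_intercept = TRUE")
    area <- as.factor(area)
    if (length(area) != S) stop("area does not match the number of sites")
    if (any(table(area) == 0)) {
      stop("area level(s) with no stations: ",
           paste(names(which(table(area) == 0)), collapse = ", "))
    }
    area_idx <- as.integer(area)
    area_levels <- levels(area)
  } else {
    area_idx <- rep(1L, S)
    area_levels <- "(Intercept)"
  }
  A <- length(area_levels)

  # detection structure
  if (is.null(trail)) {
    trail_idx <- rep(1L, S)
    trail_levels <- "(ref)"
  } else {
    trail <- as.factor(trail)
    if (length(trail) != S) stop("trail does not match the number of sites")
    if (config$reference_trail %in% levels(trail)) {
      trail <- stats::relevel(trail, ref = config$reference_trail)
    }
    trail_idx <- as.integer(trail)
    trail_levels <- levels(trail)
  }
  K <- length(trail_levels)

  sel_alpha <- rep(isTRUE(config$select), C)
  sel_beta <- rep(isTRUE(config$select_detection), max(K - 1, 0))

  parameters <- c(
    if (C > 0) paste0("alpha[", colnames(X), "]"),
    if (C > 0) paste0("w[", colnames(X), "]"),
    if (config$random_intercept) paste0("a[", area_levels, "]") else "alpha0",
    if (config$random_intercept) c("mu", "tau"),
    "beta0",
    if (K > 1) paste0("beta[", trail_levels[-1], "]"),
    if (K > 1) paste0("w_beta[", trail_levels[-1], "]"),
    "Zsum")

  master <- settings$seed %||% sample.int(2147483000L, 1)
  n_keep <- (settings$iterations - settings$burn_in) %/% settings$thin
  draws <- array(NA_real_, dim = c(n_keep, length(parameters),
                                   settings$chains),
                 dimnames = list(NULL, parameters, NULL))
  for (k in seq_len(settings$chains)) {
    set.seed(chain_seed(master, k))
    alpha_init <- stats::runif(C, -1, 1)
    a_init <- if (config$random_intercept) stats::rnorm(A, 0, 1) else
      stats::runif(1, -2, 2)
    mu_init <- stats::rnorm(1, 0, 1)
    tau_init <- stats::runif(1, 0.5, min(2, config$tau_high))
    beta0_init <- stats::runif(1, -2, 1)
    b_init <- stats::runif(max(K - 1, 0), -1, 1)
    ch <- cpp_run_chain(d, n, X, area_idx, A, trail_idx, K,
                        sel_alpha, sel_beta, config$random_intercept,
                        config$coef_low, config$coef_high,
                        config$mu_mean, config$mu_sd,
                        config$tau_low, config$tau_high,
                        config$inclusion_prior,
                        settings$iterations, settings$burn_in, settings$thin,
                        alpha_init, a_init, mu_init, tau_init,
                        beta0_init, b_init)
    draws[, , k] <- ch
  }

  fit <- structure(list(
    draws = draws, parameters = parameters,
    data = list(d = d, n = n, X = X, area_idx = area_idx,
                area_levels = area_levels, trail_idx = trail_idx,
                trail_levels = trail_levels, sites = history$sites %||%
                  rownames(y), standardization = std),
    config = config, settings = settings, seed = master),
    class = "siteuse_fit")
  fit$rhat <- compute_rhat(fit)
  fit
}

# flat (chains stacked) draw matrix
draw_matrix <- function(fit) {
  dm <- fit$draws
  out <- do.call(rbind, lapply(seq_len(dim(dm)[3]), function(k) dm[, , k]))
  colnames(out) <- fit$parameters
  out
}

#' Zero-inflated Bernoulli marginal log-likelihood of one site
#'
#' The site-use likelihood with the latent use state `Z` summed out:
#' \deqn{\log[\psi \prod_j p_j^{y_j} (1-p_j)^{1-y_j} + (1-\psi)
#'   I(\sum_j y_j = 0)].}
#'
#' @param psi Probability the site is used.
#' @param p Per-occasion detection probability (scalar or vector matching
#'   `y`).
#' @param y 0/1 detection vector over *observed* occasions (missing
#'   occasions must already be dropped). May be empty.
#' @return Scalar log-likelihood; `-Inf` for impossible data (e.g. a
#'   detection with `p = 0`), never an error.
#' @export
site_marginal_loglik <- function(psi, p, y) {
  stopifnot(length(psi) == 1, psi >= 0, psi <= 1, all(p >= 0), all(p <= 1))
  if (length(y) == 0) return(0)
  if (anyNA(y)) stop("y must not contain missing values")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  p <- rep_len(p, length(y))
  lp <- ifelse(y == 1, log(p), log1p(-p))
  det_ll <- sum(lp)
  t1 <- log(psi) + det_ll                       # used
  t2 <- if (all(y == 0)) log(1 - psi) else -Inf # unused (only if no detections)
  m <- max(t1, t2)
  if (!is.finite(m)) return(-Inf)
  m + log(exp(t1 - m) + exp(t2 - m))
}

#' Conditional probability that a site is used
#'
#' Full-conditional of the latent use state given the detection record:
#' 1 for any site with a detection; for an all-zero record,
#' \eqn{\psi q / (\psi q + 1 - \psi)} with \eqn{q = \prod_j (1 - p_j)} over
#' the observed occasions.
#'
#' @inheritParams site_marginal_loglik
#' @return `P(Z = 1 | y, psi, p)`.
#' @export
update_latent_Z <- function(psi, p, y) {
  if (length(y) > 0 && any(y == 1)) return(1)
  p <- rep_len(p, length(y))
  q <- prod(1 - p)
  if (psi == 0) return(0)
  psi * q / (psi * q + 1 - psi)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance form: with `m` chains of length
#' `n`, within-chain variance `W`, between-chain variance `B = n
#' var(chain means)`, \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n) / W}}.
#'
#' @param x A `siteuse_fit`, a 3-d array (`draws x parameters x chains`) or
#'   a matrix (`draws x chains`, one parameter).
#' @return Named vector of R-hat values; `NA` for parameters with zero
#'   within-chain variance (e.g. a pinned indicator).
#' @export
compute_rhat <- function(x) {
  if (inherits(x, "siteuse_fit")) x <- x$draws
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), 1, ncol(x)),
                               dimnames = list(NULL, "par", NULL))
  m <- dim(x)[3]; n <- dim(x)[1]
  if (m < 2) stop("R-hat requires at least 2 chains")
  if (n < 10) stop("R-hat requires at least 10 retained draws per chain")
  out <- apply(x, 2, function(par) {
    ch <- matrix(par, nrow = n, ncol = m)
    W <- mean(apply(ch, 2, stats::var))
    B_over_n <- stats::var(colMeans(ch))
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  names(out) <- dimnames(x)[[2]]
  out
}

#' Posterior inclusion probabilities and model-averaged coefficients
#'
#' For every selectable coefficient, reports the posterior mean of its
#' inclusion indicator (`w`), the model-averaged coefficient `E[w * alpha]`
#' (an average over the visited model space, zero contribution when
#' excluded), its SD and central credible interval, and the conditional
#' posterior mean `E[alpha | w = 1]`.
#'
#' @param fit A `siteuse_fit`.
#' @param level Credible-interval level (default 0.95).
#' @return Data frame, one row per selectable coefficient; the conditional
#'   mean is `NA` (with column `conditional_defined = FALSE`) when the
#'   indicator was never 1 in any draw.
#' @export
model_average_coefficients <- function(fit, level = 0.95) {
  dm <- draw_matrix(fit)
  terms <- c(grep("^alpha\\[", fit$parameters, value = TRUE),
             grep("^beta\\[", fit$parameters, value = TRUE))
  a <- (1 - level) / 2
  rows <- lapply(terms, function(tm) {
    wname <- if (startsWith(tm, "alpha[")) sub("^alpha", "w", tm) else
      sub("^beta", "w_beta", tm)
    co <- dm[, tm]
    w <- if (wname %in% colnames(dm)) dm[, wname] else rep(1, nrow(dm))
    eff <- w * co
    cond_ok <- any(w == 1)
    data.frame(term = sub("^(alpha|beta)\\[(.*)\\]$", "\\2", tm),
               parameter = tm,
               w = mean(w),
               mean_averaged = mean(eff),
               sd_averaged = stats::sd(eff),
               ci_low = unname(stats::quantile(eff, a)),
               ci_high = unname(stats::quantile(eff, 1 - a)),
               mean_conditional = if (cond_ok) mean(co[w == 1]) else NA_real_,
               conditional_defined = cond_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!out$conditional_defined)) {
    warning("indicator never 1 for: ",
            paste(out$term[!out$conditional_defined], collapse = ", "),
            "; conditional mean undefined")
  }
  rownames(out) <- NULL
  out
}

#' Posterior of the number of sites used
#'
#' Summarises the per-draw total of the latent use states,
#' \eqn{\sum_i Z_i}, over all surveyed sites. Its lower bound is the
#' number of sites with at least one detection (those `Z` are pinned at 1).
#'
#' @param fit A `siteuse_fit`.
#' @param level Credible-interval level.
#' @return List with `mean`, `sd`, `ci` (length 2), `min`, `max`.
#' @export
estimate_sites_used <- function(fit, level = 0.95) {
  z <- draw_matrix(fit)[, "Zsum"]
  a <- (1 - level) / 2
  list(mean = mean(z), sd = stats::sd(z),
       ci = unname(stats::quantile(z, c(a, 1 - a))),
       min = min(z), max = max(z))
}

#' Predicted site-use curve along one covariate
#'
#' Marginal prediction on the probability scale: for each standardized grid
#' value `z`, \eqn{\psi(z) = logit^{-1}(\mu + w_c\alpha_c z)} with all other
#' covariates at their mean (0 on the z-scale). The mean curve uses all
#' retained draws; the uncertainty band is the pointwise spread of a random
#' posterior subsample of `n_curve_draws` iterations.
#'
#' @param fit A `siteuse_fit`.
#' @param covariate Covariate name (a column of the fitted design).
#' @param grid Standardized grid; default 51 points over the observed range.
#' @param n_curve_draws Size of the posterior subsample for the band
#'   (default 200).
#' @param level Band level (default 0.95).
#' @param seed Seed for the subsample.
#' @return Data frame of class `siteuse_curve`: `z`, `psi` (posterior mean),
#'   `lower`, `upper`, and `x` on the natural scale when standardization
#'   constants are available.
#' @export
predict_site_use_curve <- function(fit, covariate, grid = NULL,
                                   n_curve_draws = 200, level = 0.95,
                                   seed = NULL) {
  X <- fit$data$X
  if (!covariate %in% colnames(X)) {
    stop("unknown covariate: ", covariate, " (have: ",
         paste(colnames(X), collapse = ", "), ")")
  }
  if (is.null(grid)) {
    r <- range(X[, covariate])
    grid <- seq(r[1], r[2], length.out = 51)
  }
  dm <- draw_matrix(fit)
  base <- if (fit$config$random_intercept) dm[, "mu"] else dm[, "alpha0"]
  aname <- paste0("alpha[", covariate, "]")
  wname <- paste0("w[", covariate, "]")
  eff <- dm[, aname] * (if (wname %in% colnames(dm)) dm[, wname] else 1)
  curves <- stats::plogis(outer(base, rep(1, length(grid))) +
                          outer(eff, grid))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(dm), min(n_curve_draws, nrow(dm)))
  a <- (1 - level) / 2
  band <- apply(curves[idx, , drop = FALSE], 2, stats::quantile,
                probs = c(a, 1 - a))
  out <- data.frame(z = grid, psi = colMeans(curves),
                    lower = band[1, ], upper = band[2, ])
  std <- fit$data$standardization
  if (!is.null(std) && covariate %in% names(std$center)) {
    out$x <- grid * std$scale[[covariate]] + std$center[[covariate]]
  }
  class(out) <- c("siteuse_curve", "data.frame")
  attr(out, "covariate") <- covariate
  out
}

#' @export
predict.siteuse_fit <- function(object, covariate, ...) {
  predict_site_use_curve(object, covariate, ...)
}

#' @export
coef.siteuse_fit <- function(object, ...) {
  ma <- model_average_coefficients(object)
  stats::setNames(ma$mean_averaged, ma$parameter)
}

#' @export
print.siteuse_fit <- function(x, ...) {
  S <- length(x$data$d)
  cat("Bayesian site-use model fit\n")
  cat("  sites:", S, "| areas:", length(x$data$area_levels),
      "| covariates:", ncol(x$data$X), "\n")
  cat("  chains:", x$settings$chains, "x", x$settings$iterations,
      "iterations (burn-in", x$settings$burn_in, ", thin",
      x$settings$thin, ")\n")
  rh <- x$rhat[setdiff(names(x$rhat), "Zsum")]
  rh <- rh[is.finite(rh)]
  if (length(rh) > 0) {
    cat("  max R-hat:", round(max(rh), 4),
        if (max(rh) < 1.1) "(converged at the < 1.1 rule)" else
          "(WARNING: >= 1.1, chains have not converged)", "\n")
  }
  cat("Use summary() for posterior summaries.\n")
  invisible(x)
}

#' Posterior summary table
#'
#' A publication-style summary: for selectable coefficients the conditional
#' posterior mean, SD and central credible interval (draws with the
#' coefficient included) together with the inclusion probability `w`;
#' plain posterior summaries for `mu`, `tau`, `beta0`, the area intercepts
#' and the number of sites used.
#'
#' @param object A `siteuse_fit`.
#' @param level Credible level (default 0.95).
#' @param ... Unused.
#' @return Data frame of class `summary.siteuse_fit` with columns
#'   `parameter`, `mean`, `sd`, `ci_low`, `ci_high`, `w`, `rhat`.
#' @export
summary.siteuse_fit <- function(object, level = 0.95, ...) {
  dm <- draw_matrix(object)
  a <- (1 - level) / 2
  plain <- function(par) {
    v <- dm[, par]
    data.frame(parameter = par, mean = mean(v), sd = stats::sd(v),
               ci_low = unname(stats::quantile(v, a)),
               ci_high = unname(stats::quantile(v, 1 - a)),
               w = NA_real_, stringsAsFactors = FALSE)
  }
  sel <- function(par, wpar) {
    v <- dm[, par]; w <- dm[, wpar]
    keep <- w == 1
    if (!any(keep)) {
      out <- data.frame(parameter = par, mean = NA_real_, sd = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        w = mean(w), stringsAsFactors = FALSE)
      return(out)
    }
    data.frame(parameter = par, mean = mean(v[keep]), sd = stats::sd(v[keep]),
               ci_low = unname(stats::quantile(v[keep], a)),
               ci_high = unname(stats::quantile(v[keep], 1 - a)),
               w = mean(w), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (par in grep("^alpha\\[", object$parameters, value = TRUE)) {
    rows[[par]] <- sel(par, sub("^alpha", "w", par))
  }
  for (par in grep("^(a\\[|alpha0|mu$|tau$|beta0)", object$parameters,
                   value = TRUE)) {
    rows[[par]] <- plain(par)
  }
  for (par in grep("^beta\\[", object$parameters, value = TRUE)) {
    rows[[par]] <- sel(par, sub("^beta", "w_beta", par))
  }
  rows[["Zsum"]] <- plain("Zsum")
  rows[["Zsum"]]$parameter <- "n_sites_used"
  out <- do.call(rbind, rows)
  rh <- object$rhat
  out$rhat <- rh[match(rownames(out), names(rh))]
  rownames(out) <- NULL
  class(out) <- c("summary.siteuse_fit", "data.frame")
  out
}

#' @export
print.summary.siteuse_fit <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.siteuse_fit <- function(x, covariates = colnames(x$data$X), ...) {
  if (length(covariates) == 0) stop("fit has no covariates to plot")
  old <- graphics::par(mfrow = c(ceiling(length(covariates) / 2),
                                 min(2, length(covariates))))
  on.exit(graphics::par(old))
  for (cv in covariates) plot(predict_site_use_curve(x, cv), ...)
  invisible(x)
}

#' @export
plot.siteuse_curve <- function(x, ...) {
  cv <- attr(x, "covariate")
  graphics::plot(x$z, x$psi, type = "n", ylim = c(0, 1),
                 xlab = paste(cv, "(standardized)"),
                 ylab = "Probability of site use", ...)
  graphics::polygon(c(x$z, rev(x$z)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$z, x$psi, lwd = 2)
  invisible(x)
}
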