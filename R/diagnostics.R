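#' Site-level site-use residuals
#'
#' Residuals for spatial-autocorrelation checking: the naive site-use
#' indicator (1 if the species was ever detected at the station, else 0)
#' minus the posterior mean probability of site use \eqn{\psi_i}. Comparing
#' the correlogram of residuals from a pooled (no random intercept) fit
#' against one from the area random-intercept fit shows how much spatial
#' structure the grouping absorbs.
#'
#' @param fit A `siteuse_fit` (pooled or random-intercept; the model kind
#'   is whatever was fitted).
#' @param coords Data frame with `station_id`, `x`, `y` for the fitted
#'   sites (a `station_table` works). Must cover exactly the fitted sites.
#' @param max_draws Posterior draws used for the \eqn{\psi} mean (subsampled
#'   for speed; default 2000).
#' @return Data frame with `station_id`, `x`, `y`, `residual`, `psi_hat`,
#'   `naive_use`.
#' @export
site_residuals <- function(fit, coords, max_draws = 2000) {
  sites <- fit$data$sites
  if (is.null(sites)) sites <- coords$station_id
  idx <- match(sites, coords$station_id)
  if (anyNA(idx)) {
    stop("coords missing station(s): ",
         paste(sites[is.na(idx)], collapse = ", "))
  }
  psi <- posterior_psi_mean(fit, max_draws = max_draws)
  naive <- as.numeric(fit$data$d > 0)
  data.frame(station_id = sites,
             x = coords$x[idx], y = coords$y[idx],
             residual = naive - psi, psi_hat = psi, naive_use = naive,
             stringsAsFactors = FALSE)
}

# posterior mean of psi_i from the retained draws (optionally subsampled)
posterior_psi_mean <- function(fit, max_draws = 2000) {
  dm <- draw_matrix(fit)
  if (nrow(dm) > max_draws) {
    dm <- dm[round(seq(1, nrow(dm), length.out = max_draws)), , drop = FALSE]
  }
  X <- fit$data$X
  C <- ncol(X)
  if (fit$config$random_intercept) {
    acols <- paste0("a[", fit$data$area_levels, "]")
    eta <- dm[, acols, drop = FALSE][, fit$data$area_idx, drop = FALSE]
  } else {
    eta <- matrix(dm[, "alpha0"], nrow = nrow(dm),
                  ncol = length(fit$data$area_idx))
  }
  if (C > 0) {
    eff <- dm[, paste0("alpha[", colnames(X), "]"), drop = FALSE] *
      dm[, paste0("w[", colnames(X), "]"), drop = FALSE]
    eta <- eta + eff %*% t(X)
  }
  colMeans(stats::plogis(eta))
}

#' Distance-binned residual correlogram with bootstrap band
#'
#' Nonparametric correlogram: station pairs are grouped into equal-width
#' distance bins and, within each bin, the Pearson correlation of the
#' paired residuals is computed (each unordered pair enters in both
#' orientations, making the estimator symmetric). A pointwise 95% band is
#' obtained by bootstrap resampling of stations.
#'
#' @param residuals Data frame with `x`, `y`, `residual` (see
#'   [site_residuals()]).
#' @param n_bins Number of equal-width distance bins (default 10).
#' @param max_distance Largest pair distance considered, metres; default
#'   half the maximum observed pair distance.
#' @param n_boot Bootstrap resamples for the band (default 200).
#' @param min_pairs Bins with fewer pairs than this are reported `NA`
#'   (default 5).
#' @param level Band level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return Data frame of class `siteuse_correlogram`: `bin_mid_km`,
#'   `correlation`, `lower`, `upper`, `n_pairs`.
#' @export
distance_correlogram <- function(residuals, n_bins = 10, max_distance = NULL,
                                 n_boot = 200, min_pairs = 5, level = 0.95,
                                 seed = NULL) {
  r <- residuals$residual
  S <- length(r)
  if (S < 2) stop("need at least 2 stations")
  dmat <- as.matrix(stats::dist(cbind(residuals$x, residuals$y)))
  if (is.null(max_distance)) max_distance <- max(dmat) / 2
  edges <- seq(0, max_distance, length.out = n_bins + 1)
  base <- bin_correlations(r, dmat, edges, min_pairs)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = n_bins)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(S, S, replace = TRUE)
    boot[b, ] <- bin_correlations(r[idx], dmat[idx, idx, drop = FALSE],
                                  edges, min_pairs, drop_self = TRUE)$correlation
  }
  a <- (1 - level) / 2
  qs <- apply(boot, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 10) return(c(NA_real_, NA_real_))
    stats::quantile(col, c(a, 1 - a))
  })
  out <- data.frame(bin_mid_km = (utils::head(edges, -1) + diff(edges) / 2) / 1000,
                    correlation = base$correlation,
                    lower = qs[1, ], upper = qs[2, ],
                    n_pairs = base$n_pairs)
  class(out) <- c("siteuse_correlogram", "data.frame")
  out
}

# within-bin symmetric Pearson correlation of residual pairs
bin_correlations <- function(r, dmat, edges, min_pairs, drop_self = FALSE) {
  S <- length(r)
  ut <- upper.tri(dmat)
  if (drop_self) ut <- ut & dmat > 0   # bootstrap duplicates of one station
  dv <- dmat[ut]
  ij <- which(ut, arr.ind = TRUE)
  bin <- findInterval(dv, edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[dv == 0] <- 1L
  n_bins <- length(edges) - 1
  corr <- rep(NA_real_, n_bins)
  npairs <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    sel <- bin == k
    npairs[k] <- sum(sel)
    if (npairs[k] < min_pairs) next
    u <- c(r[ij[sel, 1]], r[ij[sel, 2]])
    v <- c(r[ij[sel, 2]], r[ij[sel, 1]])
    if (stats::sd(u) == 0 || stats::sd(v) == 0) next
    corr[k] <- stats::cor(u, v)
  }
  list(correlation = corr, n_pairs = npairs)
}

#' @export
plot.siteuse_correlogram <- function(x, ...) {
  graphics::plot(x$bin_mid_km, x$correlation, type = "b", pch = 16,
                 ylim = range(c(x$lower, x$upper, 0), na.rm = TRUE),
                 xlab = "Distance between paired stations (km)",
                 ylab = "Residual correlation", ...)
  graphics::arrows(x$bin_mid_km, x$lower, x$bin_mid_km, x$upper,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
residuals.siteuse_fit <- function(object, coords, ...) {
  site_residuals(object, coords, ...)
}
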