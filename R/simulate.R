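#' Generating parameter set for a synthetic survey
#'
#' The truth object used by the synthetic-landscape generator and by the
#' recovery harness. Defaults describe a landscape where human pressure
#' (livestock, proximity to households) suppresses site use while prey and
#' river distance are inert, detection is modest and trail type is inert.
#'
#' @param mu Mean of the area random intercepts (logit scale).
#' @param tau Between-area SD of the random intercepts.
#' @param alpha Named site-use slopes on the standardized covariates.
#' @param beta0 Detection intercept (logit scale).
#' @param beta_trail Named trail contrasts (vs the reference level).
#' @param area_effects Area intercepts; drawn from `Normal(mu, tau^2)` when
#'   omitted.
#' @param n_areas Number of sampling areas.
#' @param seed Seed used to draw `area_effects` (stored for reproducibility).
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(mu = -0.4, tau = 1,
                            alpha = c(livestock = -2, dist_river = 0,
                                      dist_household = 2, cpue = 0),
                            beta0 = -1.6,
                            beta_trail = c(NT = 0, RD = 0),
                            area_effects = NULL, n_areas = 11, seed = 1) {
  if (is.null(area_effects)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    area_effects <- stats::rnorm(n_areas, mu, tau)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(list(mu = mu, tau = tau, alpha = alpha, beta0 = beta0,
                 beta_trail = beta_trail, area_effects = area_effects,
                 n_areas = n_areas, seed = seed),
            class = "synthetic_truth")
}

#' Simulate a clustered camera-trap station layout
#'
#' Places sampling-area centroids at least `area_spacing` apart and fills
#' each area with stations at least `min_spacing` apart (rejection
#' sampling). The default design mirrors a 127-station, 11-area survey
#' split 76/16/35 across a national park, a wildlife management area and
#' village lands, with one large long-running park area.
#'
#' @param n_areas Number of areas.
#' @param stations_per_area Integer vector of stations per area.
#' @param zones Zone label per area.
#' @param min_spacing Minimum within-area station spacing, metres.
#' @param area_spacing Minimum distance between area centroids, metres.
#' @param trail_probs Sampling probabilities of trail types per station.
#' @param area_extent Side length of the square each area's stations are
#'   drawn in; default scales with the number of stations. Setting it
#'   smaller than the packing allows triggers an error.
#' @param max_tries Rejection attempts per station before giving up.
#' @param seed Optional seed.
#' @return A `station_table` (no active windows yet; the detection
#'   simulator attaches them).
#' @export
simulate_stations <- function(n_areas = 11,
                              stations_per_area = c(9, 9, 42, 8, 8, 8, 8,
                                                    9, 9, 9, 8),
                              zones = c(rep("national_park", 5), rep("wma", 2),
                                        rep("village_land", 4)),
                              min_spacing = 1500, area_spacing = 15000,
                              trail_probs = c(AT = 0.7, NT = 0.15, RD = 0.15),
                              area_extent = NULL, max_tries = 500,
                              seed = NULL) {
  stopifnot(length(stations_per_area) == n_areas, length(zones) == n_areas)
  if (!is.null(seed)) set.seed(seed)
  ngrid <- ceiling(sqrt(n_areas))
  cent <- cbind(x = ((seq_len(n_areas) - 1) %% ngrid),
                y = ((seq_len(n_areas) - 1) %/% ngrid)) * area_spacing * 1.4
  cent <- cent + matrix(stats::runif(2 * n_areas, -0.1, 0.1) * area_spacing,
                        ncol = 2)
  rows <- list()
  sid <- 0
  for (g in seq_len(n_areas)) {
    n_g <- stations_per_area[g]
    L <- area_extent %||% (max(4, ceiling(2.2 * sqrt(n_g))) * min_spacing)
    pts <- matrix(NA_real_, nrow = n_g, ncol = 2)
    placed <- 0
    tries <- 0
    while (placed < n_g) {
      cand <- cent[g, ] + stats::runif(2, -L / 2, L / 2)
      ok <- placed == 0 ||
        min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        min_spacing
      if (ok) {
        placed <- placed + 1
        pts[placed, ] <- cand
        tries <- 0
      } else {
        tries <- tries + 1
        if (tries > max_tries) {
          stop("cannot pack ", n_g, " stations at spacing ", min_spacing,
               " m into an area of extent ", L,
               " m; increase area_extent or reduce min_spacing")
        }
      }
    }
    ids <- sprintf("st%03d", sid + seq_len(n_g))
    sid <- sid + n_g
    rows[[g]] <- data.frame(
      station_id = ids, x = pts[, 1], y = pts[, 2],
      area = sprintf("area%02d", g), zone = zones[g],
      trail_type = sample(names(trail_probs), n_g, replace = TRUE,
                          prob = trail_probs),
      stringsAsFactors = FALSE)
  }
  as_station_table(do.call(rbind, rows))
}

#' Simulate zone-structured site covariates
#'
#' Draws unstandardized covariates with the gradients the landscape is
#' assumed to carry: livestock concentrated in village lands, prey biomass
#' (CPUE) highest in the park, households near village lands, and river
#' distance taken from a synthetic river polyline crossing the park side of
#' the landscape. `strength = 0` collapses every zone to the common
#' log-scale mean, making the zone distributions exchangeable.
#'
#' @param stations A `station_table`.
#' @param strength Gradient strength in `[0, 1]` scaling the log-scale zone
#'   contrasts (default 1).
#' @param livestock_mu Zone means of the negative-binomial livestock counts.
#' @param livestock_size Negative-binomial size (dispersion) parameter.
#' @param cpue_meanlog,cpue_sdlog Zone log-normal parameters for CPUE
#'   (kg/100 trap-days).
#' @param household_meanlog,household_sdlog Zone log-normal parameters for
#'   distance to the nearest household (m).
#' @param river Two-column matrix of river vertices; a default wavy
#'   west-east polyline through the park zone is built when omitted.
#' @param seed Optional seed.
#' @return An unstandardized `covariate_table`; the river vertices are
#'   attached as attribute `"river"`.
#' @export
simulate_covariates <- function(stations, strength = 1,
                                livestock_mu = c(national_park = 0.2,
                                                 wma = 4, village_land = 80),
                                livestock_size = 0.5,
                                cpue_meanlog = c(national_park = log(300),
                                                 wma = log(150),
                                                 village_land = log(15)),
                                cpue_sdlog = 0.6,
                                household_meanlog = c(national_park = log(15000),
                                                      wma = log(8000),
                                                      village_land = log(1500)),
                                household_sdlog = 0.5,
                                river = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zone <- stations$zone
  shrink <- function(logpar) {
    m <- mean(logpar)
    stats::setNames(m + strength * (logpar - m), names(logpar))
  }
  lmu <- exp(shrink(log(livestock_mu)))[zone]
  cml <- shrink(cpue_meanlog)[zone]
  hml <- shrink(household_meanlog)[zone]
  livestock <- stats::rnbinom(nrow(stations), size = livestock_size, mu = lmu)
  cpue <- stats::rlnorm(nrow(stations), meanlog = cml, sdlog = cpue_sdlog)
  dist_household <- stats::rlnorm(nrow(stations), meanlog = hml,
                                  sdlog = household_sdlog)
  if (is.null(river)) {
    park <- stations[stations$zone == "national_park", , drop = FALSE]
    yr <- if (nrow(park) > 0) mean(park$y) else mean(stations$y)
    xs <- seq(min(stations$x) - 10000, max(stations$x) + 10000, by = 250)
    river <- cbind(x = xs, y = yr + 3000 * sin(xs / 20000))
  }
  dist_river <- nearest_feature_distance(stations[, c("x", "y")], river)
  out <- covariate_table(stations$station_id, livestock, dist_river,
                         dist_household, cpue)
  attr(out, "river") <- river
  out
}

#' Simulate detection data from the site-use model
#'
#' The generative mirror of [fit_site_use()]: standardizes the covariates,
#' forms \eqn{logit(\psi_i) = a_{area(i)} + \sum_c \alpha_c x_{ic}}, draws
#' latent use `Z_i ~ Bern(psi_i)` and occasion-level detections `y_ij ~
#' Bern(Z_i p_i)` on occasions with effort, and emits record-level
#' timestamps consistent with `y` (events within an occupied cell are
#' placed on a 6-minute lattice, so the 5-minute independence filter is a
#' no-op and the ingest path is exactly invertible).
#'
#' @param stations A `station_table` from [simulate_stations()].
#' @param covariates Unstandardized `covariate_table` from
#'   [simulate_covariates()].
#' @param truth A [synthetic_truth()]; `alpha` must name columns of
#'   `covariates` and `area_effects` must match the number of areas.
#' @param J Number of weekly occasions (default 32).
#' @param effort_pattern `"ragged"` (one long-running area, shorter
#'   staggered windows elsewhere, day-level jitter producing partial-effort
#'   occasions) or `"full"` (every station active the whole survey).
#' @param survey_start First day of occasion 1.
#' @param species Focal species label written into the records.
#' @param seed Optional seed.
#' @return List: `history` (`detection_history`), `records`
#'   (timestamped focal-species events), `stations` (with windows
#'   attached), `covariates` (standardized), `truth`, `psi`, `Z`, `p`.
#' @export
simulate_detection_data <- function(stations, covariates, truth, J = 32,
                                    effort_pattern = c("ragged", "full"),
                                    survey_start = as.Date("2015-06-01"),
                                    species = "leopard", seed = NULL) {
  effort_pattern <- match.arg(effort_pattern)
  if (!is.null(seed)) set.seed(seed)
  survey_start <- as.Date(survey_start)
  S <- nrow(stations)
  areas <- sort(unique(stations$area))
  if (length(truth$area_effects) != length(areas)) {
    stop("truth has ", length(truth$area_effects), " area effects but the ",
         "station table has ", length(areas), " areas")
  }
  cn <- names(truth$alpha)
  if (!all(cn %in% names(covariates))) {
    stop("truth$alpha names must be covariate columns; missing: ",
         paste(setdiff(cn, names(covariates)), collapse = ", "))
  }

  # active windows
  end_all <- survey_start + J * 7
  if (effort_pattern == "full") {
    win <- data.frame(station_id = stations$station_id,
                      start = survey_start, end = end_all)
  } else {
    big <- areas[which.max(table(factor(stations$area, levels = areas)))]
    win <- do.call(rbind, lapply(areas, function(a) {
      ids <- stations$station_id[stations$area == a]
      if (a == big) {
        data.frame(station_id = ids, start = survey_start, end = end_all)
      } else {
        starts <- 0:max(0, J - 8)
        w0 <- starts[sample.int(length(starts), 1)]
        lens <- min(4, J - w0):min(20, J - w0)
        len <- lens[sample.int(length(lens), 1)]
        data.frame(station_id = ids,
                   start = survey_start + 7 * w0 +
                     sample(0:3, length(ids), replace = TRUE),
                   end = survey_start + 7 * (w0 + len) -
                     sample(0:3, length(ids), replace = TRUE))
      }
    }))
  }
  stations <- as_station_table(as.data.frame(stations), windows = win)
  effort <- compute_effort(stations, survey_start, n_occasions = J)

  # site-use and detection probabilities
  Xz <- zscore_standardize(covariates, cols = cn)
  X <- as.matrix(as.data.frame(Xz)[, cn, drop = FALSE])
  area_idx <- match(stations$area, areas)
  psi <- stats::plogis(truth$area_effects[area_idx] +
                       as.numeric(X %*% truth$alpha))
  trail_off <- c(0, truth$beta_trail)[match(stations$trail_type,
                                            c("AT", names(truth$beta_trail)))]
  p <- stats::plogis(truth$beta0 + trail_off)
  Z <- stats::rbinom(S, 1, psi)

  y <- matrix(NA_integer_, nrow = S, ncol = J,
              dimnames = dimnames(effort))
  obs <- effort > 0
  y[obs] <- stats::rbinom(sum(obs), 1, (Z * p)[row(effort)[obs]])

  # record-level timestamps for every detection cell
  recs <- list()
  occ_start <- as.numeric(survey_start) + (seq_len(J) - 1) * 7
  wkey <- split(seq_len(nrow(win)), win$station_id)
  for (cell in which(y == 1)) {
    i <- row(y)[cell]; j <- col(y)[cell]
    sid <- stations$station_id[i]
    w <- win[wkey[[sid]], , drop = FALSE]
    ws <- as.numeric(w$start); we <- as.numeric(w$end)
    lo <- max(ws[1], occ_start[j]); hi <- min(we[1], occ_start[j] + 7)
    n_slot <- (hi - lo) * 240                       # 6-minute lattice
    n_ev <- 1 + stats::rpois(1, 0.7)
    slots <- sample.int(n_slot, min(n_ev, n_slot))
    ts <- as.POSIXct(lo * 86400, origin = "1970-01-01", tz = "UTC") +
      (slots - 1) * 360 + stats::runif(length(slots), 0, 60)
    recs[[length(recs) + 1]] <- data.frame(station_id = sid,
                                           species = species,
                                           timestamp = ts,
                                           stringsAsFactors = FALSE)
  }
  records <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(station_id = character(0), species = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"))
  records <- records[order(records$station_id, records$species,
                           records$timestamp), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("detection_records", "data.frame")

  history <- build_detection_history(records, stations, survey_start,
                                     n_occasions = J, effort = effort)

  list(history = history, records = records, stations = stations,
       covariates = Xz, truth = truth, psi = psi, Z = Z, p = p)
}

#' Recovery report over replicated simulation-fit pairs
#'
#' Given fits to data simulated at known truth, reports per parameter the
#' bias, RMSE and credible-interval coverage of the posterior, and the mean
#' posterior inclusion probability split by whether the generating effect
#' was zero. Selectable coefficients are assessed on the model-averaged
#' (effective, `w * alpha`) scale.
#'
#' @param fits List of `siteuse_fit` objects.
#' @param truths List of matching [synthetic_truth()] objects (recycled if
#'   length 1).
#' @param level Credible level for coverage (default 0.95).
#' @return List of class `recovery_report`: `parameters` (data frame with
#'   `parameter`, `truth`, `bias`, `rmse`, `coverage`) and `inclusion`
#'   (data frame with `covariate`, `true_value`, `mean_w`).
#' @export
evaluate_recovery <- function(fits, truths, level = 0.95) {
  if (length(truths) == 1) truths <- rep(truths, length(fits))
  if (length(fits) != length(truths)) {
    stop("fits and truths must be paired (equal length)")
  }
  a <- (1 - level) / 2
  per_rep <- lapply(seq_along(fits), function(r) {
    fit <- fits[[r]]; tr <- truths[[r]]
    dm <- draw_matrix(fit)
    entry <- function(name, v, true) {
      data.frame(parameter = name, truth = true, est = mean(v),
                 lo = unname(stats::quantile(v, a)),
                 hi = unname(stats::quantile(v, 1 - a)),
                 stringsAsFactors = FALSE)
    }
    rows <- list(entry("mu", dm[, "mu"], tr$mu),
                 entry("tau", dm[, "tau"], tr$tau),
                 entry("beta0", dm[, "beta0"], tr$beta0))
    wrows <- list()
    for (cn in names(tr$alpha)) {
      eff <- dm[, paste0("alpha[", cn, "]")] * dm[, paste0("w[", cn, "]")]
      rows[[length(rows) + 1]] <- entry(paste0("alpha[", cn, "]"), eff,
                                        tr$alpha[[cn]])
      wrows[[length(wrows) + 1]] <- data.frame(
        covariate = cn, true_value = tr$alpha[[cn]],
        w = mean(dm[, paste0("w[", cn, "]")]), stringsAsFactors = FALSE)
    }
    for (kn in names(tr$beta_trail)) {
      bn <- paste0("beta[", kn, "]")
      if (!bn %in% colnames(dm)) next
      wn <- paste0("w_beta[", kn, "]")
      eff <- dm[, bn] * (if (wn %in% colnames(dm)) dm[, wn] else 1)
      rows[[length(rows) + 1]] <- entry(bn, eff, tr$beta_trail[[kn]])
    }
    list(par = do.call(rbind, rows), w = do.call(rbind, wrows))
  })
  par_all <- do.call(rbind, lapply(per_rep, `[[`, "par"))
  w_all <- do.call(rbind, lapply(per_rep, `[[`, "w"))
  pars <- unique(par_all$parameter)
  params <- do.call(rbind, lapply(pars, function(p) {
    s <- par_all[par_all$parameter == p, , drop = FALSE]
    data.frame(parameter = p, truth = mean(s$truth),
               bias = mean(s$est - s$truth),
               rmse = sqrt(mean((s$est - s$truth)^2)),
               coverage = mean(s$lo <= s$truth & s$truth <= s$hi),
               stringsAsFactors = FALSE)
  }))
  incl <- do.call(rbind, lapply(unique(w_all$covariate), function(cn) {
    s <- w_all[w_all$covariate == cn, , drop = FALSE]
    data.frame(covariate = cn, true_value = mean(s$true_value),
               mean_w = mean(s$w), stringsAsFactors = FALSE)
  }))
  structure(list(parameters = params, inclusion = incl,
                 n_replicates = length(fits)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat("Recovery over", x$n_replicates, "replicates\n")
  p <- x$parameters
  p[-1] <- lapply(p[-1], round, digits)
  print.data.frame(p, row.names = FALSE)
  cat("\nInclusion probabilities:\n")
  i <- x$inclusion
  i[-1] <- lapply(i[-1], round, digits)
  print.data.frame(i, row.names = FALSE)
  invisible(x)
}
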