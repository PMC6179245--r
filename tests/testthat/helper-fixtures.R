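# Shared fixtures: tiny record/station tables built in code, and a
# hand-constructed fit-shaped object for testing summary machinery
# independently of the sampler.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_records <- function(station_id, species, timestamp) {
  out <- data.frame(station_id = station_id, species = species,
                    timestamp = ts_utc(timestamp), stringsAsFactors = FALSE)
  class(out) <- c("detection_records", "data.frame")
  out
}

# three stations, two areas, one zone each, single active windows
tiny_stations <- function() {
  as_station_table(data.frame(
    station_id = c("s1", "s2", "s3"),
    x = c(0, 2000, 4000), y = c(0, 0, 0),
    area = c("A", "A", "B"),
    zone = c("national_park", "national_park", "wma"),
    trail_type = c("AT", "NT", "RD"),
    active_start = as.Date("2015-06-01"),
    active_end = as.Date("2015-06-29"),   # 28 days = 4 full occasions
    stringsAsFactors = FALSE))
}

# a fit-shaped object with draws chosen by hand (single chain)
fake_fit <- function(draws, X = NULL, area_idx = NULL,
                     area_levels = "(Intercept)", random_intercept = FALSE,
                     d = NULL, n = NULL, trail_levels = "(ref)",
                     standardization = NULL) {
  stopifnot(is.matrix(draws), !is.null(colnames(draws)))
  arr <- array(draws, dim = c(nrow(draws), ncol(draws), 1),
               dimnames = list(NULL, colnames(draws), NULL))
  if (is.null(X)) X <- matrix(0, nrow = max(length(d), 1), ncol = 0)
  structure(list(
    draws = arr, parameters = colnames(draws),
    data = list(d = d, n = n, X = X,
                area_idx = area_idx %||% rep(1L, nrow(X)),
                area_levels = area_levels, trail_idx = rep(1L, nrow(X)),
                trail_levels = trail_levels,
                sites = if (!is.null(d)) sprintf("s%02d", seq_along(d)),
                standardization = standardization),
    config = site_use_config(random_intercept = random_intercept),
    settings = mcmc_settings(chains = 1, iterations = nrow(draws) + 1,
                             burn_in = 0, thin = 1)),
    class = "siteuse_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick test-scale MCMC settings
fast_mcmc <- function(seed, iterations = 8000, burn_in = 2000, thin = 5,
                      chains = 3) {
  mcmc_settings(chains, iterations, burn_in, thin, seed = seed)
}
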