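#' Default prey body-mass table
#'
#' Field-guide average adult body masses (kg) for the five primary prey
#' species entering the catch-per-unit-effort prey-availability index. Edit
#' or replace to suit other assemblages.
#'
#' @return Data frame with columns `species`, `mean_mass` (kg).
#' @export
default_prey_masses <- function() {
  data.frame(species = c("bushbuck", "common_duiker", "greater_kudu",
                         "impala", "warthog"),
             mean_mass = c(43, 19, 200, 53, 75),
             stringsAsFactors = FALSE)
}

#' Catch-per-unit-effort prey-availability index
#'
#' For every station, multiplies the number of independent events of each
#' prey species by that species' average body mass, sums over species,
#' divides by the station's total sampling effort (trap-days) and scales to
#' kilograms per 100 trap-days:
#' \deqn{CPUE_i = 100 \sum_s N_{is} m_s / E_i.}
#'
#' @param prey_records Independence-filtered records of the prey species.
#' @param mass_table Data frame `species`, `mean_mass` (kg); see
#'   [default_prey_masses()].
#' @param effort Named numeric vector of total trap-days per station (e.g.
#'   `rowSums(compute_effort(...))`). Its names define the output stations.
#'
#' @return Named numeric vector of CPUE (kg per 100 trap-days) per station.
#' @export
compute_cpue <- function(prey_records, mass_table, effort) {
  if (is.null(names(effort))) stop("effort must be named by station_id")
  rec <- prey_records[prey_records$species %in% mass_table$species, ,
                      drop = FALSE]
  orphan <- setdiff(unique(rec$station_id), names(effort))
  if (length(orphan) > 0) {
    stop("prey records at station(s) without effort: ",
         paste(orphan, collapse = ", "))
  }
  zero_eff <- names(effort)[effort <= 0]
  if (any(rec$station_id %in% zero_eff)) {
    stop("station(s) with prey records but zero effort: ",
         paste(intersect(unique(rec$station_id), zero_eff), collapse = ", "))
  }
  mass <- mass_table$mean_mass[match(rec$species, mass_table$species)]
  biomass <- tapply(mass, factor(rec$station_id, levels = names(effort)), sum)
  biomass[is.na(biomass)] <- 0
  cpue <- 100 * as.numeric(biomass) / as.numeric(effort)
  cpue[effort <= 0] <- 0
  stats::setNames(cpue, names(effort))
}

#' Pooled livestock presence counts
#'
#' Counts independent livestock events per station, filtering each livestock
#' species separately at the independence window and then pooling.
#'
#' @param livestock_records Raw (unfiltered) records of the livestock
#'   species; filtering is applied per species here.
#' @param stations A `station_table` (or character vector of station ids).
#' @param species Livestock species pooled (default cattle, goat, donkey).
#' @param window_minutes Independence window, minutes.
#'
#' @return Named integer vector of independent livestock events per station.
#' @export
compute_livestock_presence <- function(livestock_records, stations,
                                       species = c("cattle", "goat", "donkey"),
                                       window_minutes = 5) {
  sites <- if (is.data.frame(stations)) stations$station_id else stations
  rec <- livestock_records[livestock_records$species %in% species, ,
                           drop = FALSE]
  rec <- filter_independent(rec, window_minutes)
  cnt <- table(factor(rec$station_id, levels = sites))
  stats::setNames(as.integer(cnt), sites)
}

#' Assemble the site-level covariate table
#'
#' @param station_id Character vector of stations (row order of the model).
#' @param livestock,dist_river,dist_household,cpue Numeric covariate vectors
#'   aligned with `station_id` (metres for distances, kg/100 trap-days for
#'   CPUE).
#' @return Data frame of class `covariate_table` (unstandardized).
#' @export
covariate_table <- function(station_id, livestock, dist_river,
                            dist_household, cpue) {
  out <- data.frame(station_id = as.character(station_id),
                    livestock = livestock, dist_river = dist_river,
                    dist_household = dist_household, cpue = cpue,
                    stringsAsFactors = FALSE)
  attr(out, "standardized") <- FALSE
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Z-score standardization with stored constants
#'
#' Centres and scales each covariate column to sample mean 0 and sample SD 1
#' (n-1 denominator). The original means and SDs are stored so prediction
#' curves can be drawn on the natural scale.
#'
#' @param x A `covariate_table` or plain data frame.
#' @param cols Columns to standardize; default all numeric columns except
#'   `station_id`.
#' @return The standardized table, attributes `center` and `scale` holding
#'   the constants, `standardized = TRUE`.
#' @export
zscore_standardize <- function(x, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "station_id")
  }
  ctr <- numeric(0); scl <- numeric(0)
  for (cc in cols) {
    v <- x[[cc]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize constant column: ", cc)
    }
    m <- mean(v)
    x[[cc]] <- (v - m) / s
    ctr[cc] <- m; scl[cc] <- s
  }
  attr(x, "center") <- ctr
  attr(x, "scale") <- scl
  attr(x, "standardized") <- TRUE
  x
}

#' Invert a z-score standardization
#' @param x A table returned by [zscore_standardize()].
#' @return The table on its original scale.
#' @export
unstandardize <- function(x) {
  ctr <- attr(x, "center"); scl <- attr(x, "scale")
  if (is.null(ctr)) stop("no standardization constants attached")
  for (cc in names(ctr)) x[[cc]] <- x[[cc]] * scl[cc] + ctr[cc]
  attr(x, "center") <- NULL; attr(x, "scale") <- NULL
  attr(x, "standardized") <- FALSE
  x
}

#' Pairwise-correlation and VIF collinearity screen
#'
#' Computes the full pairwise Pearson correlation matrix and, for each
#' covariate, the variance inflation factor \eqn{VIF_c = 1/(1-R^2_c)} from an
#' ordinary least-squares regression of covariate `c` on all the others.
#' Covariates pass the screen when all their pairwise `|r|` are below
#' `r_max` and their VIF is below `vif_max`.
#'
#' @param x Standardized covariate table (or numeric matrix/data frame).
#' @param cols Columns screened; default all numeric columns but
#'   `station_id`.
#' @param r_max Pairwise Pearson threshold (default 0.7).
#' @param vif_max VIF threshold (default 3).
#' @return List of class `collinearity_screen`: `pearson` (matrix), `vif`
#'   (named vector, `Inf` for perfectly collinear columns), `pass` (named
#'   logical), and the thresholds.
#' @export
collinearity_screen <- function(x, cols = NULL, r_max = 0.7, vif_max = 3) {
  if (is.null(cols)) {
    cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "station_id")
  }
  m <- as.matrix(as.data.frame(x)[, cols, drop = FALSE])
  if (ncol(m) < 2) stop("need at least two covariates to screen")
  if (nrow(m) <= ncol(m) + 1) stop("need n > number of covariates + 1")
  r <- stats::cor(m)
  vif <- stats::setNames(numeric(ncol(m)), cols)
  for (k in seq_len(ncol(m))) {
    yk <- m[, k]
    Xk <- m[, -k, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Xk), yk)
    sse <- sum(fit$residuals^2)
    sst <- sum((yk - mean(yk))^2)
    r2 <- 1 - sse / sst
    vif[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  off <- abs(r); diag(off) <- 0
  pass <- apply(off < r_max, 1, all) & (vif < vif_max)
  structure(list(pearson = r, vif = vif, pass = pass,
                 r_max = r_max, vif_max = vif_max),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("Collinearity screen (|r| <", x$r_max, ", VIF <", x$vif_max, ")\n")
  cat("Pairwise Pearson correlations:\n")
  print(round(x$pearson, 3))
  cat("VIF:\n")
  print(round(x$vif, 3))
  cat(if (all(x$pass)) "All covariates pass.\n" else
    paste("Failing:", paste(names(x$pass)[!x$pass], collapse = ", "), "\n"))
  invisible(x)
}
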