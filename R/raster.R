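#' Euclidean distance-to-feature raster
#'
#' Builds a regular grid over a bounding box and fills each cell with the
#' planar Euclidean distance (metres) from the cell centre to the nearest
#' feature point. Line features (rivers, roads) are represented by their
#' (densified) vertices.
#'
#' @param features Two-column matrix or data frame of feature coordinates
#'   (`x`, `y`), metres, in the same planar CRS as the stations.
#' @param bbox Numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @param cell_size Cell edge length in metres (default 500).
#'
#' @return An object of class `distance_raster`: list with `xll`, `yll`,
#'   `cell_size`, `ncol`, `nrow` and `values`, an `nrow x ncol` matrix whose
#'   `[r, c]` entry is the cell with centre
#'   `(xll + (c-1/2) cell, yll + (r-1/2) cell)` (row 1 at the bottom).
#' @export
distance_raster <- function(features, bbox, cell_size = 500) {
  features <- as.matrix(as.data.frame(features)[, 1:2])
  if (nrow(features) == 0) stop("empty feature set")
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("bbox must be c(xmin, ymin, xmax, ymax) with positive extent")
  }
  nc <- ceiling((bbox[3] - bbox[1]) / cell_size)
  nr <- ceiling((bbox[4] - bbox[2]) / cell_size)
  cx <- bbox[1] + (seq_len(nc) - 0.5) * cell_size
  cy <- bbox[2] + (seq_len(nr) - 0.5) * cell_size
  vals <- matrix(0, nrow = nr, ncol = nc)
  for (r in seq_len(nr)) {
    dx <- outer(features[, 1], cx, "-")          # nfeat x ncol
    dy <- features[, 2] - cy[r]
    vals[r, ] <- sqrt(apply(dx^2 + dy^2, 2, min))
  }
  structure(list(xll = bbox[1], yll = bbox[2], cell_size = cell_size,
                 ncol = nc, nrow = nr, values = vals),
            class = "distance_raster")
}

#' Nearest-feature distance at arbitrary points
#'
#' Exact (non-rasterized) Euclidean distance from each query point to the
#' nearest feature point.
#'
#' @inheritParams distance_raster
#' @param points Two-column matrix/data frame of query coordinates.
#' @return Numeric vector of distances (metres).
#' @export
nearest_feature_distance <- function(points, features) {
  points <- as.matrix(as.data.frame(points)[, 1:2])
  features <- as.matrix(as.data.frame(features)[, 1:2])
  if (nrow(features) == 0) stop("empty feature set")
  vapply(seq_len(nrow(points)), function(i) {
    sqrt(min((features[, 1] - points[i, 1])^2 +
             (features[, 2] - points[i, 2])^2))
  }, numeric(1))
}

#' Sample a raster at station locations
#'
#' Returns the value of the cell *containing* each station (no
#' interpolation). A station exactly on a cell edge is assigned to the
#' lower-index cell.
#'
#' @param raster A `distance_raster`.
#' @param stations `station_table` or data frame with `x`, `y` (and
#'   optionally `station_id` used to name the result).
#' @return Numeric vector of cell values per station.
#' @export
sample_raster_at_stations <- function(raster, stations) {
  x <- stations$x; y <- stations$y
  cs <- raster$cell_size
  col <- ceiling((x - raster$xll) / cs)
  col[x == raster$xll] <- 1L
  row <- ceiling((y - raster$yll) / cs)
  row[y == raster$yll] <- 1L
  bad <- col < 1 | col > raster$ncol | row < 1 | row > raster$nrow
  if (any(bad)) {
    ids <- if (!is.null(stations$station_id)) stations$station_id[bad] else
      which(bad)
    stop("station(s) outside raster bounds: ", paste(ids, collapse = ", "))
  }
  v <- raster$values[cbind(row, col)]
  if (!is.null(stations$station_id)) names(v) <- stations$station_id
  v
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by rows of values, top row first.
#'
#' @param raster A `distance_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", raster$ncol),
               paste("nrows", raster$nrow),
               paste("xllcorner", format(raster$xll, scientific = FALSE)),
               paste("yllcorner", format(raster$yll, scientific = FALSE)),
               paste("cellsize", format(raster$cell_size, scientific = FALSE)),
               "NODATA_value -9999"), con)
  for (r in rev(seq_len(raster$nrow))) {
    writeLines(paste(raster$values[r, ], collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path Path to the text grid.
#' @return A `distance_raster`-shaped object (values need not be distances).
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nc <- hdr$ncols; nr <- hdr$nrows
  vals <- matrix(scan(text = ln[i:length(ln)], quiet = TRUE),
                 nrow = nr, ncol = nc, byrow = TRUE)
  vals <- vals[rev(seq_len(nr)), , drop = FALSE]   # store row 1 at bottom
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  structure(list(xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cell_size = hdr$cellsize, ncol = nc, nrow = nr,
                 values = vals),
            class = "distance_raster")
}
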