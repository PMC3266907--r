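# Occurrence records, ESRI ASCII SST grids, extraction and per-species
# thermal summaries (including the maximum thermal tolerance range).

new_sst_raster <- function(nrows, ncols, cellsize, xll, yll, nodata,
                           min, mean, max) {
  stopifnot(all(dim(min) == c(nrows, ncols)),
            all(dim(mean) == c(nrows, ncols)),
            all(dim(max) == c(nrows, ncols)))
  valid <- !is.na(min) & !is.na(mean) & !is.na(max)
  bad <- valid & (min > mean | mean > max)
  if (any(bad)) {
    stop("invalid SST cell(s): min <= mean <= max violated at ",
         sum(bad), " cell(s)", call. = FALSE)
  }
  structure(list(nrows = nrows, ncols = ncols, cellsize = cellsize,
                 xll = xll, yll = yll, nodata = nodata,
                 min = min, mean = mean, max = max),
            class = "sst_raster")
}

raster_cell_centers <- function(raster) {
  lat_c <- raster$yll + (rev(seq_len(raster$nrows)) - 0.5) * raster$cellsize
  lon_c <- raster$xll + (seq_len(raster$ncols) - 0.5) * raster$cellsize
  list(lat = matrix(lat_c, raster$nrows, raster$ncols),
       lon = matrix(lon_c, raster$nrows, raster$ncols))
}

parse_asc <- function(file) {
  if (!file.exists(file)) stop("grid file not found: ", file, call. = FALSE)
  lines <- readLines(file, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII header of ", file, " lacks ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  if (is.null(hdr$xllcorner) || is.null(hdr$yllcorner)) {
    stop("ESRI ASCII header of ", file, " lacks the lower-left corner",
         call. = FALSE)
  }
  if (is.null(hdr$nodata_value)) hdr$nodata_value <- -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("grid ", file, ": expected ", hdr$nrows * hdr$ncols,
         " values, found ", length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  list(hdr = hdr, m = m)
}

#' Read min/mean/max SST layers from ESRI ASCII grids
#'
#' The three layers must share an identical grid (dimensions, cell size,
#' origin). Values are cell-center registered with row 1 the northernmost
#' row; nodata cells (land) become `NA`. A valid cell violating
#' `min <= mean <= max` is an error.
#'
#' @param min_file,mean_file,max_file paths to the three `.asc` layers.
#' @return an object of class `sst_raster` with grid metadata and three
#'   matrices `min`, `mean`, `max` (deg C).
#' @export
read_ascii_grid <- function(min_file, mean_file, max_file) {
  g <- lapply(c(min_file, mean_file, max_file), parse_asc)
  h1 <- g[[1L]]$hdr
  for (k in 2:3) {
    h <- g[[k]]$hdr
    same <- isTRUE(all.equal(
      c(h1$ncols, h1$nrows, h1$xllcorner, h1$yllcorner, h1$cellsize),
      c(h$ncols, h$nrows, h$xllcorner, h$yllcorner, h$cellsize),
      tolerance = 1e-9))
    if (!same) stop("grid headers differ across SST layers", call. = FALSE)
  }
  new_sst_raster(nrows = h1$nrows, ncols = h1$ncols, cellsize = h1$cellsize,
                 xll = h1$xllcorner, yll = h1$yllcorner,
                 nodata = h1$nodata_value,
                 min = g[[1L]]$m, mean = g[[2L]]$m, max = g[[3L]]$m)
}

#' Write an SST raster as three ESRI ASCII grids
#'
#' @param raster an `sst_raster`.
#' @param min_file,mean_file,max_file output paths.
#' @export
write_ascii_grid <- function(raster, min_file, mean_file, max_file) {
  stopifnot(inherits(raster, "sst_raster"))
  write1 <- function(m, file) {
    hdr <- c(
      paste("ncols", raster$ncols),
      paste("nrows", raster$nrows),
      paste("xllcorner", format(raster$xll, digits = 10)),
      paste("yllcorner", format(raster$yll, digits = 10)),
      paste("cellsize", format(raster$cellsize, digits = 10)),
      paste("NODATA_value", format(raster$nodata, digits = 10))
    )
    m[is.na(m)] <- raster$nodata
    body <- apply(m, 1L, function(r)
      paste(formatC(r, format = "fg", digits = 6), collapse = " "))
    writeLines(c(hdr, body), file)
  }
  write1(raster$min, min_file)
  write1(raster$mean, mean_file)
  write1(raster$max, max_file)
  invisible(NULL)
}

#' Read occurrence records from CSV
#'
#' Expects a header with at least `species`, `lat`, `lon`; an optional
#' `provenance` column defaults to `"literature"` with a warning when
#' absent. Rows with coordinates outside `[-90, 90]` x `[-180, 180]` are
#' rejected with their line numbers.
#'
#' @param file path to the CSV.
#' @return data.frame `species`, `lat`, `lon`, `provenance`.
#' @export
read_occurrences <- function(file) {
  if (!file.exists(file)) stop("occurrence file not found: ", file,
                               call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("occurrence CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"provenance" %in% names(df)) {
    warning("no provenance column: defaulting to 'literature'")
    df$provenance <- "literature"
  }
  for (col in c("lat", "lon")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]])
    if (any(bad)) {
      stop("unparseable ", col, " at line(s): ",
           paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  out_of_range <- is.na(df$lat) | is.na(df$lon) |
    abs(df$lat) > 90 | abs(df$lon) > 180
  if (any(out_of_range)) {
    stop("out-of-range coordinates at line(s): ",
         paste(which(out_of_range) + 1L, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$species) | is.na(df$species))) {
    stop("empty species id at line(s): ",
         paste(which(!nzchar(df$species) | is.na(df$species)) + 1L,
               collapse = ", "), call. = FALSE)
  }
  df[, c("species", "lat", "lon", "provenance")]
}

#' Extract SST values at a point
#'
#' Returns the min/mean/max SST of the cell containing the point. If that
#' cell is nodata (a coastal record falling on a land cell of the marine
#' grid), the nearest valid cell by center distance within `radius` cells
#' (Chebyshev neighbourhood) is used, ties broken in row-major order; beyond
#' the radius an error is raised, as for a point outside the grid.
#'
#' @param raster an `sst_raster`.
#' @param lat,lon point coordinates in decimal degrees.
#' @param radius search radius in cells (default 2).
#' @return named numeric vector `c(min, mean, max)` in deg C.
#' @export
extract_sst <- function(raster, lat, lon, radius = 2L) {
  stopifnot(inherits(raster, "sst_raster"))
  cs <- raster$cellsize
  col <- floor((lon - raster$xll) / cs) + 1L
  row_fb <- floor((lat - raster$yll) / cs) + 1L
  row <- raster$nrows - row_fb + 1L
  if (col < 1L || col > raster$ncols || row < 1L || row > raster$nrows) {
    stop(sprintf("point (%.4f, %.4f) outside grid", lat, lon), call. = FALSE)
  }
  if (!is.na(raster$min[row, col])) {
    return(c(min = raster$min[row, col], mean = raster$mean[row, col],
             max = raster$max[row, col]))
  }
  rows <- max(1L, row - radius):min(raster$nrows, row + radius)
  cols <- max(1L, col - radius):min(raster$ncols, col + radius)
  best <- NULL
  best_d <- Inf
  for (r in rows) {
    for (ccol in cols) {
      if (is.na(raster$min[r, ccol])) next
      cen_lat <- raster$yll + (raster$nrows - r + 0.5) * cs
      cen_lon <- raster$xll + (ccol - 0.5) * cs
      dd <- (cen_lat - lat)^2 + (cen_lon - lon)^2
      if (dd < best_d - 1e-12) {  # strict: ties keep row-major first
        best_d <- dd
        best <- c(r, ccol)
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no valid SST cell within %d cells of point (%.4f, %.4f)",
      radius, lat, lon), call. = FALSE)
  }
  c(min = raster$min[best[1L], best[2L]],
    mean = raster$mean[best[1L], best[2L]],
    max = raster$max[best[1L], best[2L]])
}

#' Per-species thermal and range summaries
#'
#' For each species: record count, latitudinal and longitudinal range (raw
#' max minus min span; see `circular_lon`), the means over records of the
#' per-record min/mean/max SST, and the maximum thermal tolerance range --
#' the largest per-record maximum SST minus the smallest per-record minimum
#' SST, which is never smaller than the difference of the means. Records
#' whose extraction fails (outside grid, or no valid cell within the search
#' radius) are dropped with a warning; a species losing all its records is
#' omitted with a warning.
#'
#' @param records occurrence data.frame (see [read_occurrences()]).
#' @param raster an `sst_raster`.
#' @param radius nodata search radius in cells (see [extract_sst()]).
#' @param circular_lon if `TRUE`, the longitudinal range is the minimal
#'   covering arc on the circle instead of the raw span on [-180, 180].
#' @return data.frame of class `species_thermal_summary` with columns
#'   `species`, `n`, `lat_range`, `lon_range`, `max_C`, `mean_C`, `min_C`,
#'   `max_range_C`.
#' @export
summarize_species <- function(records, raster, radius = 2L,
                              circular_lon = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("species", "lat", "lon") %in% names(records)))
  ext <- matrix(NA_real_, nrow(records), 3L,
                dimnames = list(NULL, c("min", "mean", "max")))
  failed <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- tryCatch(extract_sst(raster, records$lat[i], records$lon[i],
                              radius = radius),
                  error = function(e) NULL)
    if (is.null(v)) failed[i] <- TRUE else ext[i, ] <- v
  }
  if (any(failed)) {
    warning(sum(failed), " record(s) dropped: no SST value obtainable")
  }
  keep <- !failed
  species <- unique(records$species)
  rows <- list()
  for (s in species) {
    sel <- keep & records$species == s
    if (!any(sel)) {
      warning("species ", s, " omitted: all records failed extraction")
      next
    }
    lat <- records$lat[sel]
    lon <- records$lon[sel]
    lon_range <- if (circular_lon) min_arc(lon) else max(lon) - min(lon)
    rows[[length(rows) + 1L]] <- data.frame(
      species = s, n = sum(sel),
      lat_range = max(lat) - min(lat),
      lon_range = lon_range,
      max_C = mean(ext[sel, "max"]),
      mean_C = mean(ext[sel, "mean"]),
      min_C = mean(ext[sel, "min"]),
      max_range_C = max(ext[sel, "max"]) - min(ext[sel, "min"])
    )
  }
  if (!length(rows)) stop("no species with usable records", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_thermal_summary", class(out))
  out
}

# minimal covering arc (degrees) of a set of longitudes on the circle
min_arc <- function(lon) {
  lon <- sort(lon %% 360)
  if (length(lon) == 1L) return(0)
  gaps <- diff(c(lon, lon[1L] + 360))
  360 - max(gaps)
}
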