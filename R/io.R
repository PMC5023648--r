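#' Read and write elevation grids as ESRI ASCII rasters
#'
#' The ESRI ASCII grid is the plain-text raster dialect: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of cell values, northernmost row first. One file holds
#' one layer; climate layers are written as sibling files.
#'
#' @param grid An `elevation_grid`.
#' @param path Output file path.
#' @param layer Which layer to write: `"elev"`, `"mat"` or `"map"`.
#' @return `write_esri_ascii()` returns `path` invisibly;
#'   `read_esri_ascii()` returns an `elevation_grid` (elevation layer only).
#' @export
write_esri_ascii <- function(grid, path, layer = c("elev", "mat", "map")) {
  stopifnot(inherits(grid, "elevation_grid"))
  layer <- match.arg(layer)
  m <- grid[[layer]]
  if (is.null(m)) stop_invalid("grid has no '%s' layer", layer)
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", sqrt(grid$cell_area)),
    "NODATA_value -9999"
  )
  rows <- apply(m, 1, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @param domain Elevation domain `(min, max)` to attach; defaults to the
#'   data range.
#' @export
read_esri_ascii <- function(path, domain = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, ignore.case = TRUE, value = TRUE)
    if (!length(ln)) stop_invalid("malformed ESRI ASCII header: missing %s", key)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols")
  nr <- val("nrows")
  cellsize <- val("cellsize")
  nodata <- val("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop_invalid("expected %d cell values, found %d", nr * nc, length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (is.null(domain)) domain <- range(m, na.rm = TRUE)
  structure(
    list(elev = m, cell_area = cellsize^2, domain = as.numeric(domain),
         mat = NULL, map = NULL),
    class = "elevation_grid"
  )
}

#' Read and write species checklists as CSV
#'
#' Column layout: `species,genus,family,lifeform,elev_min,elev_max` with
#' elevations in metres (written to 0.1 m).
#'
#' @param checklist A `checklist` data frame.
#' @param path File path.
#' @return `write_checklist_csv()` returns `path` invisibly;
#'   `read_checklist_csv()` returns a validated `checklist`.
#' @export
write_checklist_csv <- function(checklist, path) {
  out <- as.data.frame(checklist)
  out$elev_min <- round(out$elev_min, 1)
  out$elev_max <- round(out$elev_max, 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_checklist_csv
#' @param domain Optional `(min, max)` domain for validation.
#' @export
read_checklist_csv <- function(path, domain = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_checklist(df, domain = domain)
  class(df) <- c("checklist", "data.frame")
  attr(df, "domain") <- domain
  df
}

#' Write a band scheme as CSV
#'
#' Columns: `index,kind,lower,upper,mid,width_m,cell_count,area_km2,
#' mat_mean,map_mean`.
#'
#' @param scheme A `band_scheme`.
#' @param path File path.
#' @export
write_band_scheme_csv <- function(scheme, path) {
  stopifnot(inherits(scheme, "band_scheme"))
  out <- data.frame(
    index = scheme$index, kind = attr(scheme, "kind"),
    lower = scheme$lower, upper = scheme$upper, mid = scheme$mid,
    width_m = scheme$width_m, cell_count = scheme$cell_count,
    area_km2 = scheme$area_km2, mat_mean = scheme$mat_mean,
    map_mean = scheme$map_mean
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
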