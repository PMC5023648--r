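#' Altitudinal band schemes
#'
#' A band scheme is an ordered set of contiguous elevation intervals tiling
#' the analysis domain. Intervals are half-open `[lower, upper)` with the top
#' band closed, so every elevation maps to exactly one band. Two kinds exist:
#' equal-elevation (fixed width, e.g. 37 bands of 100 m) and equal-area
#' (boundaries chosen so each band holds the same number of DEM cells).
#'
#' @name band_scheme
#' @keywords internal
NULL

new_band_scheme <- function(df, kind, domain, cell_area = NA_real_,
                            assignment = NULL, n_outside = 0L) {
  df$index <- seq_len(nrow(df))
  df$mid <- (df$lower + df$upper) / 2
  df$width_m <- df$upper - df$lower
  stopifnot(all(df$width_m > 0), !is.unsorted(df$mid, strictly = TRUE))
  structure(df,
            class = c("band_scheme", "data.frame"),
            kind = kind, domain = as.numeric(domain), cell_area = cell_area,
            assignment = assignment, n_outside = n_outside)
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> %s: %d bands tiling [%g, %g] m\n",
              attr(x, "kind"), nrow(x), attr(x, "domain")[1], attr(x, "domain")[2]))
  NextMethod()
}

#' Build an equal-elevation band scheme
#'
#' Divides `[domain_min, domain_max]` into bands of fixed `width`. The span
#' must be an exact multiple of the width; a partial top band would silently
#' change band areas, so it is an error instead.
#'
#' @param domain_min,domain_max Domain limits in metres.
#' @param width Band width in metres.
#' @return A `band_scheme` of kind `"equal_elevation"` with `n = span/width`
#'   bands; areas and climate summaries are filled in by
#'   [assign_band_areas()] and [summarize_band_climate()].
#' @examples
#' sch <- make_equal_elevation_bands(1350, 5050, 100)
#' nrow(sch)  # 37
#' @export
make_equal_elevation_bands <- function(domain_min, domain_max, width) {
  check_number(domain_min, "domain_min")
  check_number(domain_max, "domain_max")
  check_number(width, "width")
  if (domain_max <= domain_min) stop_invalid("domain_max must exceed domain_min")
  if (width <= 0) stop_invalid("width must be > 0")
  span <- domain_max - domain_min
  k <- span / width
  if (abs(k - round(k)) > 1e-9) {
    stop_invalid(paste0(
      "domain span %g m is not divisible by band width %g m; ",
      "adjust the domain (e.g. to [%g, %g]) so bands tile it exactly"),
      span, width, domain_min, domain_min + floor(k) * width)
  }
  k <- as.integer(round(k))
  df <- data.frame(
    lower = domain_min + (seq_len(k) - 1) * width,
    upper = domain_min + seq_len(k) * width,
    cell_count = NA_integer_, area_km2 = NA_real_,
    mat_mean = NA_real_, map_mean = NA_real_
  )
  new_band_scheme(df, "equal_elevation", c(domain_min, domain_max))
}

# DEM cells in raster row-major order (the order the jitter rule is defined in)
cells_row_major <- function(grid, layer = "elev") {
  as.vector(t(grid[[layer]]))
}

# Band index per cell; NA for cells outside the scheme's domain. Equal-area
# schemes carry their rank-split membership; interval lookup covers the rest.
band_assignment <- function(scheme, grid) {
  stored <- attr(scheme, "assignment")
  elev <- cells_row_major(grid)
  if (!is.null(stored)) {
    if (length(stored) != length(elev)) {
      stop_invalid("scheme was built from a grid with %d cells, got %d",
                   length(stored), length(elev))
    }
    return(stored)
  }
  breaks <- c(scheme$lower, scheme$upper[nrow(scheme)])
  idx <- findInterval(elev, breaks, rightmost.closed = TRUE)
  idx[idx < 1L | idx > nrow(scheme)] <- NA_integer_
  idx
}

#' Attach per-band cell counts and areas from a DEM
#'
#' Band area is planimetric: cell area times the number of DEM cells whose
#' elevation falls in the band. Cells outside the scheme's domain are
#' excluded from every band and their count is recorded in the
#' `n_outside` attribute rather than silently dropped.
#'
#' @param scheme A `band_scheme`.
#' @param grid An `elevation_grid`.
#' @return The scheme with `cell_count` and `area_km2` populated.
#' @export
assign_band_areas <- function(scheme, grid) {
  stopifnot(inherits(scheme, "band_scheme"), inherits(grid, "elevation_grid"))
  if (length(grid$elev) == 0) stop_invalid("empty elevation grid")
  idx <- band_assignment(scheme, grid)
  counts <- tabulate(idx, nbins = nrow(scheme))
  scheme$cell_count <- as.integer(counts)
  scheme$area_km2 <- counts * grid$cell_area / 1e6
  attr(scheme, "cell_area") <- grid$cell_area
  attr(scheme, "n_outside") <- sum(is.na(idx))
  scheme
}

#' Build an equal-area band scheme from a DEM
#'
#' Implements the jitter-and-rank construction: each integer cell elevation
#' gets an independent uniform `U(-0.5, +0.5)` perturbation (breaking ties
#' without changing which band a cell plausibly belongs to), the jittered
#' values are sorted, and the cells are cut into `n_bands` contiguous rank
#' groups whose sizes differ by at most one (remainder cells go to the
#' lowest-index bands). Band boundaries are midpoints between the two
#' jittered values that straddle each cut, clamped to the domain at the ends,
#' so band widths vary inversely with the hypsographic density while every
#' band holds (almost) the same area.
#'
#' @param grid An `elevation_grid`.
#' @param n_bands Number of bands.
#' @param seed Seed for the jitter (one uniform per cell in raster row-major
#'   order).
#' @return A `band_scheme` of kind `"equal_area"` with cell counts, areas,
#'   widths and mids populated.
#' @export
make_equal_area_bands <- function(grid, n_bands, seed) {
  stopifnot(inherits(grid, "elevation_grid"))
  elev <- cells_row_major(grid)
  n <- length(elev)
  if (n_bands < 1) stop_invalid("n_bands must be >= 1")
  if (n_bands > n) stop_invalid("n_bands (%d) exceeds the cell count (%d)", n_bands, n)
  z <- elev + with_seed(seed, stats::runif(n, -0.5, 0.5))
  ord <- order(z)
  zs <- z[ord]
  base <- n %/% n_bands
  sizes <- rep.int(base, n_bands)
  extra <- n %% n_bands
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  cuts <- (zs[ends[-n_bands]] + zs[ends[-n_bands] + 1L]) / 2
  lower <- c(grid$domain[1], cuts)
  upper <- c(cuts, grid$domain[2])
  assignment <- integer(n)
  assignment[ord] <- rep.int(seq_len(n_bands), sizes)
  df <- data.frame(
    lower = lower, upper = upper,
    cell_count = as.integer(sizes),
    area_km2 = sizes * grid$cell_area / 1e6,
    mat_mean = NA_real_, map_mean = NA_real_
  )
  new_band_scheme(df, "equal_area", grid$domain, cell_area = grid$cell_area,
                  assignment = assignment)
}

#' Summarize climate layers per band
#'
#' Arithmetic mean of MAT and MAP over the cells assigned to each band;
#' bands with no cells get `NA`.
#'
#' @param scheme A `band_scheme`.
#' @param grid An `elevation_grid` with climate layers attached.
#' @return The scheme with `mat_mean` and `map_mean` populated.
#' @export
summarize_band_climate <- function(scheme, grid) {
  stopifnot(inherits(scheme, "band_scheme"), inherits(grid, "elevation_grid"))
  if (is.null(grid$mat) || is.null(grid$map)) {
    stop_invalid("grid has no climate layers; call generate_climate() first")
  }
  idx <- band_assignment(scheme, grid)
  mean_by <- function(vals) {
    out <- rep(NA_real_, nrow(scheme))
    m <- tapply(vals[!is.na(idx)], idx[!is.na(idx)], mean)
    out[as.integer(names(m))] <- as.numeric(m)
    out
  }
  scheme$mat_mean <- mean_by(cells_row_major(grid, "mat"))
  scheme$map_mean <- mean_by(cells_row_major(grid, "map"))
  scheme
}
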