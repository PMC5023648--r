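#' Parameters for the synthetic mountain generator
#'
#' Bundles the knobs that control the synthetic digital elevation model (DEM)
#' and its climate layers. The defaults emulate a large subtropical massif:
#' a 1350--5050 m domain whose band-area profile (hypsography) is hump-shaped
#' with a maximum near 2700 m, mean annual temperature (MAT) falling linearly
#' with elevation, and mean annual precipitation (MAP) following a
#' rise--fall--rise piecewise profile with its minimum high on the mountain.
#'
#' @param domain_min_elev,domain_max_elev Domain limits in metres.
#' @param grid_shape Integer vector `(rows, cols)` of the DEM.
#' @param cell_area Planimetric cell area in square metres (default 900,
#'   i.e. a 30 m x 30 m DEM cell).
#' @param hump_peak_elev Elevation (m) at which band area is maximal.
#' @param sd_below,sd_above Spread (m) of the hypsographic density below and
#'   above `hump_peak_elev`; together they set the skew of the area profile.
#' @param mat_at_base MAT (deg C) at `domain_min_elev`.
#' @param lapse_rate Temperature lapse rate in deg C per metre (>= 0; MAT
#'   decreases with elevation; 0 gives a constant-MAT degenerate mountain).
#' @param map_profile Data frame with columns `elev` (m, increasing) and
#'   `map` (mm) giving piecewise-linear MAP breakpoints.
#' @param mat_noise_sd,map_noise_sd Standard deviation of optional zero-mean
#'   Gaussian cell noise added to MAT (deg C) and MAP (mm). Default 0.
#' @param seed Integer seed; all randomness is reproducible from it.
#'
#' @return An object of class `mountain_params`.
#' @seealso [generate_elevation_grid()], [generate_climate()]
#' @export
mountain_params <- function(domain_min_elev = 1350,
                            domain_max_elev = 5050,
                            grid_shape = c(100L, 100L),
                            cell_area = 900,
                            hump_peak_elev = 2700,
                            sd_below = 450,
                            sd_above = 750,
                            mat_at_base = 16,
                            lapse_rate = 0.006,
                            map_profile = data.frame(
                              elev = c(1350, 1900, 4200, 5050),
                              map = c(1000, 1200, 912, 1000)
                            ),
                            mat_noise_sd = 0,
                            map_noise_sd = 0,
                            seed = 1L) {
  check_number(domain_min_elev, "domain_min_elev")
  check_number(domain_max_elev, "domain_max_elev")
  if (domain_min_elev >= domain_max_elev) {
    stop_invalid("degenerate domain: domain_min_elev (%g) >= domain_max_elev (%g)",
                 domain_min_elev, domain_max_elev)
  }
  if (length(grid_shape) != 2L || any(grid_shape < 1)) {
    stop_invalid("grid_shape must be two positive integers")
  }
  if (hump_peak_elev <= domain_min_elev || hump_peak_elev >= domain_max_elev) {
    stop_invalid("hump_peak_elev must lie strictly inside the domain")
  }
  if (lapse_rate < 0) stop_invalid("lapse_rate must be >= 0")
  if (sd_below <= 0 || sd_above <= 0) stop_invalid("hypsographic spreads must be > 0")
  if (!is.data.frame(map_profile) ||
      !all(c("elev", "map") %in% names(map_profile)) ||
      is.unsorted(map_profile$elev, strictly = TRUE)) {
    stop_invalid("map_profile must be a data frame with strictly increasing `elev` and `map` columns")
  }
  structure(
    list(
      domain_min_elev = domain_min_elev, domain_max_elev = domain_max_elev,
      grid_shape = as.integer(grid_shape), cell_area = cell_area,
      hump_peak_elev = hump_peak_elev, sd_below = sd_below, sd_above = sd_above,
      mat_at_base = mat_at_base, lapse_rate = lapse_rate,
      map_profile = map_profile,
      mat_noise_sd = mat_noise_sd, map_noise_sd = map_noise_sd,
      seed = as.integer(seed)
    ),
    class = "mountain_params"
  )
}

# CDF / quantile of a two-piece (split) normal with mode `mu`, lower spread
# `s1`, upper spread `s2`. The split normal is the simplest unimodal skew
# family whose mode is a direct parameter, which is all the hypsography needs.
ptwopiece <- function(q, mu, s1, s2) {
  w1 <- s1 / (s1 + s2)
  ifelse(q < mu,
         2 * w1 * stats::pnorm((q - mu) / s1),
         w1 + 2 * (1 - w1) * (stats::pnorm((q - mu) / s2) - 0.5))
}

qtwopiece <- function(p, mu, s1, s2) {
  w1 <- s1 / (s1 + s2)
  out <- numeric(length(p))
  lo <- p < w1
  out[lo] <- mu + s1 * stats::qnorm(p[lo] / (2 * w1))
  out[!lo] <- mu + s2 * stats::qnorm((p[!lo] - w1) / (2 * (1 - w1)) + 0.5)
  out
}

#' Generate a synthetic elevation grid with hump-shaped hypsography
#'
#' Cell elevations are placed at stratified quantiles (midpoint probabilities
#' `(i - 0.5)/n`) of a split-normal hypsographic density truncated to the
#' domain, rounded to integer metres (the convention the equal-area jitter
#' rule assumes), and spatially permuted by the seed. Stratification makes the
#' realized per-band cell-count histogram match the target density -- unimodal
#' with its mode in the band containing `hump_peak_elev` -- for any grid size,
#' while the spatial arrangement stays random.
#'
#' @param params A [mountain_params()] object.
#' @return An object of class `elevation_grid`: a list with the integer
#'   elevation `matrix`, `cell_area` (m^2), `domain` and (after
#'   [generate_climate()]) `mat`/`map` layers.
#' @export
generate_elevation_grid <- function(params) {
  stopifnot(inherits(params, "mountain_params"))
  n <- prod(params$grid_shape)
  a <- params$domain_min_elev
  b <- params$domain_max_elev
  fa <- ptwopiece(a, params$hump_peak_elev, params$sd_below, params$sd_above)
  fb <- ptwopiece(b, params$hump_peak_elev, params$sd_below, params$sd_above)
  p <- fa + ((seq_len(n) - 0.5) / n) * (fb - fa)
  elev <- qtwopiece(p, params$hump_peak_elev, params$sd_below, params$sd_above)
  elev <- pmin(pmax(round(elev), a), b)
  elev <- with_seed(params$seed, elev[sample.int(n)])
  grid <- matrix(as.integer(elev), nrow = params$grid_shape[1],
                 ncol = params$grid_shape[2], byrow = TRUE)
  structure(
    list(elev = grid, cell_area = params$cell_area, domain = c(a, b),
         mat = NULL, map = NULL),
    class = "elevation_grid"
  )
}

#' Attach synthetic climate layers to an elevation grid
#'
#' MAT is a linear lapse from the domain base,
#' `MAT = mat_at_base - lapse_rate * (elev - domain_min_elev)`, and MAP is the
#' piecewise-linear profile evaluated at each cell's elevation; both get
#' optional zero-mean Gaussian cell noise.
#'
#' @param grid An `elevation_grid`.
#' @param params The [mountain_params()] used (or to be used) for the grid.
#' @param seed Seed for the climate noise; defaults to `params$seed + 1L` so
#'   the noise stream is distinct from (but reproducible with) the grid's.
#' @return The grid with `mat` and `map` matrices attached.
#' @export
generate_climate <- function(grid, params, seed = params$seed + 1L) {
  stopifnot(inherits(params, "mountain_params"))
  if (!inherits(grid, "elevation_grid") || is.null(grid$elev)) {
    stop_invalid("`grid` must be an elevation_grid with an elevation layer")
  }
  elev <- grid$elev
  mat <- params$mat_at_base - params$lapse_rate * (elev - params$domain_min_elev)
  map <- matrix(
    stats::approx(params$map_profile$elev, params$map_profile$map,
                  xout = as.vector(elev), rule = 2)$y,
    nrow = nrow(elev)
  )
  if (params$mat_noise_sd > 0 || params$map_noise_sd > 0) {
    noise <- with_seed(seed, list(
      mat = stats::rnorm(length(elev), 0, params$mat_noise_sd),
      map = stats::rnorm(length(elev), 0, params$map_noise_sd)
    ))
    mat <- mat + matrix(noise$mat, nrow = nrow(elev))
    map <- map + matrix(noise$map, nrow = nrow(elev))
  }
  grid$mat <- mat
  grid$map <- map
  grid
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells (%.0f m2 each), domain [%g, %g] m\n",
              nrow(x$elev), ncol(x$elev), x$cell_area, x$domain[1], x$domain[2]))
  cat(sprintf("  elevation range: %d-%d m; climate layers: %s\n",
              min(x$elev), max(x$elev),
              if (is.null(x$mat)) "none" else "MAT, MAP"))
  invisible(x)
}

#' Parameters for the synthetic species checklist generator
#'
#' Defaults emulate a rich subtropical montane flora: 2028 species in about
#' 625 genera and 136 families, two thirds herbaceous, with elevational range
#' sizes mixing narrow (< 150 m), intermediate (150--500 m) and wide
#' (> 500 m) species in proportions 830:554:644 and about 35 % of species
#' known from a single elevation record (range size zero).
#'
#' @param n_species Number of species to generate.
#' @param group_proportions Length-3 fractions (summing to 1) of species in
#'   range-size Groups I (< 150 m), II (150--500 m) and III (> 500 m).
#' @param lifeform_proportions Length-3 fractions for tree, shrub, herb.
#' @param single_record_fraction Fraction of all species with
#'   `elev_min == elev_max`; these are a subset of Group I, so the value must
#'   not exceed `group_proportions[1]`.
#' @param species_per_genus,genera_per_family Mean sizes of the nested
#'   taxonomic levels.
#' @param richness_profile Relative density of elevation used to place range
#'   midpoints: `"unimodal"` (default) is a Gaussian bump peaking at 40 % of
#'   the domain span -- the mid-elevation zone where montane floras
#'   concentrate -- with spread a quarter of the span; `"uniform"` places
#'   midpoints uniformly over each species' feasible interval; or supply any
#'   non-negative function of elevation.
#' @param seed Integer seed.
#' @return An object of class `checklist_params`.
#' @export
checklist_params <- function(n_species = 2028,
                             group_proportions = c(830, 554, 644) / 2028,
                             lifeform_proportions = c(290, 392, 1346) / 2028,
                             single_record_fraction = 717 / 2028,
                             species_per_genus = 2028 / 625,
                             genera_per_family = 625 / 136,
                             richness_profile = "unimodal",
                             seed = 1L) {
  if (n_species < 0) stop_invalid("n_species must be >= 0")
  for (nm in c("group_proportions", "lifeform_proportions")) {
    p <- get(nm)
    if (length(p) != 3L || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      stop_invalid("`%s` must be three fractions in [0, 1] summing to 1", nm)
    }
  }
  if (single_record_fraction < 0 ||
      single_record_fraction > group_proportions[1] + 1e-12) {
    stop_invalid("single_record_fraction must lie in [0, group_proportions[1]]")
  }
  if (species_per_genus < 1 || genera_per_family < 1) {
    stop_invalid("mean taxon sizes must be >= 1")
  }
  if (!is.function(richness_profile) &&
      !identical(richness_profile, "unimodal") &&
      !identical(richness_profile, "uniform")) {
    stop_invalid("richness_profile must be 'unimodal', 'uniform' or a function")
  }
  structure(
    list(n_species = as.integer(n_species),
         group_proportions = group_proportions,
         lifeform_proportions = lifeform_proportions,
         single_record_fraction = single_record_fraction,
         species_per_genus = species_per_genus,
         genera_per_family = genera_per_family,
         richness_profile = richness_profile,
         seed = as.integer(seed)),
    class = "checklist_params"
  )
}

#' Generate a synthetic species checklist
#'
#' Each species gets a range-size group (multinomial in the requested
#' proportions), a range size uniform within its group's limits (Group I
#' `[0, 150)`, Group II `[150, 500]`, Group III `(500, span]`), a range
#' midpoint uniform over the positions where the whole range fits in the
#' domain, a life form, and nested genus/family labels (each genus belongs to
#' exactly one family). A fixed fraction of species are single-record
#' (`elev_min == elev_max`), drawn from Group I.
#'
#' @param params A [checklist_params()] object.
#' @param domain Numeric `(min, max)` elevation domain in metres.
#' @return A `checklist`: a data frame with columns
#'   `species, genus, family, lifeform, elev_min, elev_max`.
#' @export
generate_checklist <- function(params, domain) {
  stopifnot(inherits(params, "checklist_params"))
  if (length(domain) != 2L || domain[2] <= domain[1]) {
    stop_invalid("`domain` must be (min, max) with max > min")
  }
  span <- domain[2] - domain[1]
  if (params$group_proportions[2] > 0 && span < 150) {
    stop_invalid("domain span %.1f m cannot hold Group II ranges (>= 150 m)", span)
  }
  if (params$group_proportions[3] > 0 && span <= 500) {
    stop_invalid("domain span %.1f m cannot hold Group III ranges (> 500 m)", span)
  }
  n <- params$n_species
  empty <- data.frame(species = character(), genus = character(),
                      family = character(), lifeform = character(),
                      elev_min = numeric(), elev_max = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("checklist", "data.frame")
  attr(empty, "domain") <- as.numeric(domain)
  if (n == 0L) return(empty)

  out <- with_seed(params$seed, {
    grp <- sample.int(3L, n, replace = TRUE, prob = params$group_proportions)
    r <- numeric(n)
    # single-record species are the zero-range subset of Group I
    p_sr <- if (params$group_proportions[1] > 0) {
      min(1, params$single_record_fraction / params$group_proportions[1])
    } else 0
    i1 <- which(grp == 1L)
    sr <- rep(FALSE, n)
    sr[i1] <- stats::runif(length(i1)) < p_sr
    r[i1] <- ifelse(sr[i1], 0, stats::runif(length(i1), 0, 150))
    r[grp == 2L] <- stats::runif(sum(grp == 2L), 150, 500)
    r[grp == 3L] <- stats::runif(sum(grp == 3L), 500, span)

    lo <- domain[1] + r / 2
    hi <- domain[2] - r / 2
    f <- params$richness_profile
    if (identical(f, "unimodal")) {
      f <- local({
        peak <- domain[1] + 0.4 * span
        sdv <- 0.25 * span
        function(e) exp(-((e - peak)^2) / (2 * sdv^2))
      })
    }
    if (identical(f, "uniform")) {
      m <- stats::runif(n, lo, hi)
    } else {
      # rejection sampling against the profile's maximum over the domain
      fmax <- max(f(seq(domain[1], domain[2], length.out = 512)))
      m <- numeric(n)
      todo <- seq_len(n)
      while (length(todo) > 0) {
        cand <- stats::runif(length(todo), lo[todo], hi[todo])
        keep <- stats::runif(length(todo)) < f(cand) / fmax
        m[todo[keep]] <- cand[keep]
        todo <- todo[!keep]
      }
    }
    lifeform <- sample(c("tree", "shrub", "herb"), n, replace = TRUE,
                       prob = params$lifeform_proportions)
    n_gen <- max(1L, round(n / params$species_per_genus))
    n_fam <- max(1L, round(n_gen / params$genera_per_family))
    genus_id <- sample.int(n_gen, n, replace = TRUE)
    family_of_genus <- sample.int(n_fam, n_gen, replace = TRUE)
    data.frame(
      species = sprintf("sp%04d", seq_len(n)),
      genus = sprintf("g%04d", genus_id),
      family = sprintf("f%03d", family_of_genus[genus_id]),
      lifeform = lifeform,
      elev_min = m - r / 2,
      elev_max = m + r / 2,
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("checklist", "data.frame")
  attr(out, "domain") <- as.numeric(domain)
  out
}

# Structural validation shared by the richness counters.
validate_checklist <- function(checklist, domain = attr(checklist, "domain")) {
  req <- c("species", "genus", "family", "lifeform", "elev_min", "elev_max")
  if (!all(req %in% names(checklist))) {
    stop_invalid("checklist is missing columns: %s",
                 paste(setdiff(req, names(checklist)), collapse = ", "))
  }
  bad <- checklist$elev_min > checklist$elev_max
  if (any(bad)) {
    stop_invalid("elev_min > elev_max for species %s",
                 paste(checklist$species[bad], collapse = ", "))
  }
  if (!all(checklist$lifeform %in% c("tree", "shrub", "herb"))) {
    stop_invalid("lifeform must be one of tree/shrub/herb")
  }
  dup <- unique(checklist$species[duplicated(checklist$species)])
  if (length(dup)) {
    for (sp in dup) {
      rows <- checklist[checklist$species == sp, c("elev_min", "elev_max")]
      if (nrow(unique(rows)) > 1) {
        stop_invalid("duplicate species_id '%s' with conflicting ranges", sp)
      }
    }
  }
  if (!is.null(domain)) {
    out <- checklist$elev_min < domain[1] | checklist$elev_max > domain[2]
    if (any(out)) {
      stop_invalid("species outside the domain [%g, %g]: %s", domain[1], domain[2],
                   paste(checklist$species[out], collapse = ", "))
    }
  }
  invisible(checklist)
}
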