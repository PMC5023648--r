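#' Richness variables counted per band
#'
#' Nine taxon-richness variables are counted for every band: species (`S`),
#' genus (`G`) and family (`F`) richness; species richness of trees (`TS`),
#' shrubs (`SS`) and herbs (`HS`); and species richness of the three
#' elevational range-size groups (`IS`, `IIS`, `IIIS`).
#'
#' @format A character vector of the nine column names.
#' @export
richness_variables <- c("S", "G", "F", "TS", "SS", "HS", "IS", "IIS", "IIIS")

# First and last band index intersected by each closed range [emin, emax].
# Bands are half-open [lower, upper) with the top band closed; a closed
# species range touching only a band's *lower* bound is counted there
# (conservative presence), touching only an upper bound is not.
presence_range <- function(elev_min, elev_max, scheme) {
  dom <- attr(scheme, "domain")
  out <- elev_min < dom[1] | elev_max > dom[2]
  if (any(out)) {
    stop_invalid("elevational range outside the domain [%g, %g] at index %s",
                 dom[1], dom[2], paste(which(out), collapse = ", "))
  }
  breaks <- c(scheme$lower, scheme$upper[nrow(scheme)])
  first <- findInterval(elev_min, breaks, rightmost.closed = TRUE)
  last <- findInterval(elev_max, scheme$lower)
  list(first = first, last = last)
}

#' Interpolate a species range onto a band scheme
#'
#' A species is taken to occur continuously between its recorded minimum and
#' maximum elevations, so it is present in every band whose interval
#' intersects the closed range `[elev_min, elev_max]`.
#'
#' @param record A one-row data frame (or list) with `elev_min`, `elev_max`
#'   and optionally `species` (used in error messages).
#' @param scheme A `band_scheme`.
#' @return Integer vector of band indices; always a contiguous run.
#' @examples
#' sch <- make_equal_elevation_bands(1350, 5050, 100)
#' interpolate_presence(list(elev_min = 1500, elev_max = 1720), sch)  # 2 3 4
#' @export
interpolate_presence <- function(record, scheme) {
  stopifnot(inherits(scheme, "band_scheme"))
  pr <- tryCatch(
    presence_range(record$elev_min, record$elev_max, scheme),
    error = function(e) {
      id <- if (!is.null(record$species)) record$species else "<unnamed>"
      stop_invalid("species '%s': %s", id, conditionMessage(e))
    }
  )
  seq.int(pr$first, pr$last)
}

#' Classify a species range size into Groups I-III
#'
#' Group I: range size < 150 m; Group II: 150--500 m inclusive at both
#' endpoints; Group III: > 500 m.
#'
#' @param record A data frame with `elev_min` and `elev_max` columns (any
#'   number of rows), or a numeric vector of range sizes in metres.
#' @param thresholds Increasing pair of group limits in metres
#'   (default `c(150, 500)`). The lower limit is exclusive for Group I
#'   (`< 150`), both limits are inclusive for Group II (`150--500`), and the
#'   upper is exclusive for Group III (`> 500`).
#' @return Factor with levels `I`, `II`, `III`.
#' @export
range_size_group <- function(record, thresholds = c(150, 500)) {
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2]) {
    stop_invalid("thresholds must be an increasing pair")
  }
  r <- if (is.numeric(record)) record else record$elev_max - record$elev_min
  if (any(r < 0)) stop_invalid("negative range size")
  factor(ifelse(r < thresholds[1], "I", ifelse(r <= thresholds[2], "II", "III")),
         levels = c("I", "II", "III"))
}

#' Count the nine richness variables per band
#'
#' Interpolates every species' range onto the scheme and counts, per band,
#' distinct species, genera and families, species per life form, and species
#' per range-size group. Running the same operation on an equal-area scheme
#' yields method-2 area-corrected richness: the counting code is identical,
#' only the band scheme differs.
#'
#' @param checklist A `checklist` data frame.
#' @param scheme A `band_scheme`.
#' @param thresholds Range-size group limits passed to [range_size_group()].
#' @return A `richness_table`: data frame with `band`, `mid` and the nine
#'   columns in [richness_variables].
#' @export
richness_table <- function(checklist, scheme, thresholds = c(150, 500)) {
  stopifnot(inherits(scheme, "band_scheme"))
  validate_checklist(checklist, domain = attr(scheme, "domain"))
  nb <- nrow(scheme)
  out <- data.frame(band = seq_len(nb), mid = scheme$mid)
  for (v in richness_variables) out[[v]] <- 0L
  if (nrow(checklist) > 0) {
    pr <- presence_range(checklist$elev_min, checklist$elev_max, scheme)
    grp <- range_size_group(checklist, thresholds)
    for (b in seq_len(nb)) {
      in_band <- pr$first <= b & pr$last >= b
      out$S[b] <- sum(in_band)
      out$G[b] <- length(unique(checklist$genus[in_band]))
      out$F[b] <- length(unique(checklist$family[in_band]))
      out$TS[b] <- sum(in_band & checklist$lifeform == "tree")
      out$SS[b] <- sum(in_band & checklist$lifeform == "shrub")
      out$HS[b] <- sum(in_band & checklist$lifeform == "herb")
      out$IS[b] <- sum(in_band & grp == "I")
      out$IIS[b] <- sum(in_band & grp == "II")
      out$IIIS[b] <- sum(in_band & grp == "III")
    }
  }
  structure(out, class = c("richness_table", "data.frame"),
            kind = attr(scheme, "kind"))
}

#' Species recorded in a single band
#'
#' Returns the checklist subset whose interpolated presence covers exactly
#' one band; counting richness on this subset involves no interpolation, so
#' it serves as a check that interpolation is not manufacturing the
#' mid-elevation richness peak.
#'
#' @param checklist A `checklist` data frame.
#' @param scheme A `band_scheme` (normally the equal-elevation scheme).
#' @return The filtered checklist.
#' @export
single_band_subset <- function(checklist, scheme) {
  stopifnot(inherits(scheme, "band_scheme"))
  validate_checklist(checklist, domain = attr(scheme, "domain"))
  if (nrow(checklist) == 0) return(checklist)
  pr <- presence_range(checklist$elev_min, checklist$elev_max, scheme)
  checklist[pr$first == pr$last, , drop = FALSE]
}
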