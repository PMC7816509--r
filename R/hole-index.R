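# WHO hole-size banding, hole geometry, and the proportionate hole index
# (PHI) used to quantify the physical integrity of field-retrieved nets.

WHO_BAND_LABELS <- c("size1", "size2", "size3", "size4")

# Assumed hole diameters per WHO band (cm); size 4 uses the conventional
# 30 cm stand-in for "larger than a head".
WHO_ASSUMED_DIAMETER_CM <- c(size1 = 1.25, size2 = 6, size3 = 17.5,
                             size4 = 30)

#' WHO hole-size bands
#'
#' The four WHO hole-size bands used in net physical-integrity surveys, with
#' their recorded diameter ranges, assumed diameters and radii, hole areas,
#' and hole-index weights. Weights are the exact squared radius ratios to the
#' size-1 hole, rounded to integers: 1, 23, 196, 576 (196 and 576 are the
#' perfect squares 14^2 and 24^2; 23 rounds from 23.04).
#'
#' @param pi_value value of pi used for the reported hole areas. The default
#'   3.142 reproduces the conventionally printed areas (28.28, 240.56,
#'   706.95 cm^2); pass `base::pi` for exact areas. Weights never depend on
#'   `pi_value`.
#' @return a data frame with one row per band: `band`, `description`,
#'   `diameter_range_cm`, `assumed_diameter_cm`, `radius_cm`, `area_cm2`,
#'   `weight`.
#' @examples
#' who_hole_bands()
#' @export
who_hole_bands <- function(pi_value = 3.142) {
  if (!is.numeric(pi_value) || length(pi_value) != 1 || pi_value <= 0) {
    stop("pi_value must be a single positive number", call. = FALSE)
  }
  r <- WHO_ASSUMED_DIAMETER_CM / 2
  data.frame(
    band = WHO_BAND_LABELS,
    description = c("smaller than a thumb",
                    "larger than a thumb but smaller than a fist",
                    "larger than a fist but smaller than a head",
                    "larger than a head"),
    diameter_range_cm = c("0.5-2", ">2-10", ">10-25", ">25"),
    assumed_diameter_cm = unname(WHO_ASSUMED_DIAMETER_CM),
    radius_cm = unname(r),
    area_cm2 = unname(pi_value * r^2),
    weight = unname(round((r / r[["size1"]])^2)),
    stringsAsFactors = FALSE
  )
}

#' Classify a hole diameter into a WHO size band
#'
#' Bands: 0.5--2 cm is size 1; over 2 up to 10 cm size 2; over 10 up to
#' 25 cm size 3; over 25 cm size 4. Holes under the 0.5 cm recording
#' threshold are not classified and raise an error.
#'
#' @param diameter_cm hole diameter(s) in cm; each must be >= 0.5.
#' @return character vector of band labels (`"size1"` ... `"size4"`).
#' @examples
#' classify_hole(c(1.25, 10, 26))
#' @export
classify_hole <- function(diameter_cm) {
  if (any(!is.finite(diameter_cm))) {
    stop("hole diameters must be finite numbers", call. = FALSE)
  }
  if (any(diameter_cm < 0.5)) {
    stop("hole diameter below the 0.5 cm recording threshold: ",
         paste(diameter_cm[diameter_cm < 0.5], collapse = ", "),
         call. = FALSE)
  }
  WHO_BAND_LABELS[findInterval(diameter_cm, c(2, 10, 25),
                               left.open = TRUE) + 1L]
}

#' @rdname who_hole_bands
#' @param band band label(s): `"size1"` ... `"size4"`.
#' @export
band_area <- function(band, pi_value = 3.142) {
  bands <- who_hole_bands(pi_value)
  idx <- match(band, bands$band)
  if (anyNA(idx)) {
    stop("unknown band label: ",
         paste(band[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  bands$area_cm2[idx]
}

#' @rdname who_hole_bands
#' @export
band_weight <- function(band) {
  bands <- who_hole_bands()
  idx <- match(band, bands$band)
  if (anyNA(idx)) {
    stop("unknown band label: ",
         paste(band[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  bands$weight[idx]
}

as_census <- function(census) {
  if (is.data.frame(census)) {
    cols <- paste0("N", 1:4)
    if (!all(cols %in% names(census))) {
      stop("census data frame needs columns N1, N2, N3, N4", call. = FALSE)
    }
    census <- as.matrix(census[, cols])
  } else if (is.null(dim(census))) {
    if (length(census) != 4) {
      stop("a census is four counts (N1, N2, N3, N4)", call. = FALSE)
    }
    census <- matrix(census, nrow = 1,
                     dimnames = list(NULL, paste0("N", 1:4)))
  }
  if (any(!is.finite(census)) || any(census < 0) ||
      any(census != round(census))) {
    stop("hole counts must be non-negative integers", call. = FALSE)
  }
  census
}

#' Proportionate hole index
#'
#' The WHO hole index of a hole census: the weighted sum of hole counts in
#' the four size bands, `H = 1*N1 + 23*N2 + 196*N3 + 576*N4`, with weights
#' proportional to hole area.
#'
#' @param census either a numeric vector of four counts `(N1, N2, N3, N4)`
#'   or a data frame with columns `N1`..`N4` (one row per net).
#' @return `hole_index()` returns the numeric hole index (one value per
#'   census row); `hole_index_contributions()` returns the per-band weighted
#'   counts as a matrix with columns `N1`..`N4`.
#' @examples
#' hole_index(c(2, 1, 0, 0))  # 25
#' hole_index(c(0, 0, 1, 1))  # 772
#' @export
hole_index <- function(census) {
  unname(rowSums(hole_index_contributions(census)))
}

#' @rdname hole_index
#' @export
hole_index_contributions <- function(census) {
  census <- as_census(census)
  sweep(census, 2, who_hole_bands()$weight, `*`)
}

#' Census from raw hole diameters
#'
#' Tabulates measured hole diameters into the four WHO size-band counts.
#'
#' @param diameters_cm hole diameters in cm (each >= 0.5); may be empty.
#' @return named integer vector `(N1, N2, N3, N4)`.
#' @export
census_from_diameters <- function(diameters_cm) {
  counts <- integer(4)
  names(counts) <- paste0("N", 1:4)
  if (length(diameters_cm)) {
    tab <- table(factor(classify_hole(diameters_cm),
                        levels = WHO_BAND_LABELS))
    counts[] <- as.integer(tab)
  }
  counts
}

field_record_index <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame of field survey records",
         call. = FALSE)
  }
  if (all(paste0("N", 1:4) %in% names(records))) {
    hole_index(records)
  } else if ("hole_diameters_cm" %in% names(records)) {
    vapply(records$hole_diameters_cm,
           function(d) hole_index(census_from_diameters(d)),
           numeric(1))
  } else {
    stop("field records need either columns N1..N4 or hole_diameters_cm",
         call. = FALSE)
  }
}

#' Summarise hole indices by group
#'
#' Computes the per-net hole index for each field record (classifying raw
#' diameters if the census is not pre-tabulated) and the arithmetic mean
#' hole index per group — typically per brand, the level at which
#' lab-versus-field comparisons are made.
#'
#' @param records a field survey data frame as returned by
#'   [read_field_records()] or [generate_field_phi()].
#' @param group_by name of the grouping column (default `"brand"`).
#' @return a data frame of class `phi_report`: group value, `n_nets`,
#'   `mean_hole_index`.
#' @export
phi_summary <- function(records, group_by = "brand") {
  hi <- field_record_index(records)
  if (!group_by %in% names(records)) {
    stop("grouping column not found: ", group_by, call. = FALSE)
  }
  g <- as.character(records[[group_by]])
  if (anyNA(g) || any(!nzchar(g))) {
    stop("empty group value in column ", group_by, call. = FALSE)
  }
  groups <- unique(g)
  out <- data.frame(
    group = groups,
    n_nets = vapply(groups, function(k) sum(g == k), integer(1)),
    mean_hole_index = vapply(groups, function(k) mean(hi[g == k]),
                             numeric(1)),
    stringsAsFactors = FALSE
  )
  names(out)[1] <- group_by
  rownames(out) <- NULL
  class(out) <- c("phi_report", "data.frame")
  out
}
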