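# Validated readers and writers for lab textile-test records and field
# hole-census records. CSV dialect: UTF-8, comma-separated, one header row,
# dot decimal separator. The reader never silently coerces: every schema
# violation is reported with the offending row and field.

LAB_COLUMNS <- c("net_id", "brand", "bursting_kpa", "snag_n",
                 "abrasion_rubs", "end_hole_mm", "secondary_damage")
FIELD_BASE_COLUMNS <- c("net_id", "brand", "months_in_use")
FIELD_CENSUS_COLUMNS <- paste0("N", 1:4)

read_raw_table <- function(path, format) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    strip.white = TRUE, fileEncoding = "UTF-8")
  } else {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0) x <- data.frame()
    as.data.frame(lapply(x, as.character), check.names = FALSE,
                  stringsAsFactors = FALSE)
  }
}

parse_numeric_field <- function(x, field, row, integer = FALSE,
                                positive = FALSE, min = NULL) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v)
  if (any(bad)) {
    stop("row ", row[bad][1], ", field ", field,
         ": not a number ('", x[bad][1], "')", call. = FALSE)
  }
  if (integer && any(v != round(v))) {
    i <- which(v != round(v))[1]
    stop("row ", row[i], ", field ", field, ": must be an integer ('",
         x[i], "')", call. = FALSE)
  }
  if (positive && any(v <= 0)) {
    i <- which(v <= 0)[1]
    stop("row ", row[i], ", field ", field, ": must be > 0 ('",
         x[i], "')", call. = FALSE)
  }
  if (!is.null(min) && any(v < min)) {
    i <- which(v < min)[1]
    stop("row ", row[i], ", field ", field, ": must be >= ", min, " ('",
         x[i], "')", call. = FALSE)
  }
  v
}

check_columns <- function(raw, required, what) {
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Read laboratory textile-test records
#'
#' Reads one summary record per net product: mean bursting strength (kPa),
#' mean snag strength (N), abrasion endurance (rubs), and the
#' hole-enlargement outcome (final hole size in mm plus secondary-damage
#' type). Expected columns: `net_id, brand, bursting_kpa, snag_n,
#' abrasion_rubs, end_hole_mm, secondary_damage`. Secondary-damage labels are
#' case-insensitive; `"tearing+laddering"` and `"tearing+unravelling"` both
#' map to the single `tearing_combined` category. Replicate aggregation is
#' the caller's job: the reader accepts exactly one summary value per net.
#'
#' @param path path to the input file.
#' @param format `"csv"` or `"json"` (an array of objects with the same
#'   field names).
#' @return a data frame of class `lab_panel`, one validated row per record,
#'   input order preserved.
#' @export
read_lab_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  raw <- read_raw_table(path, format)
  check_columns(raw, LAB_COLUMNS, "lab record file")
  n <- nrow(raw)
  if (n == 0) {
    out <- data.frame(net_id = character(), brand = character(),
                      bursting_kpa = numeric(), snag_n = numeric(),
                      abrasion_rubs = integer(), end_hole_mm = numeric(),
                      secondary_damage = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("lab_panel", "data.frame")
    return(out)
  }
  rows <- seq_len(n)
  damage <- normalise_secondary_damage(raw$secondary_damage)
  bad <- !(damage %in% SECONDARY_DAMAGE_LEVELS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("row ", i, ", field secondary_damage: unknown label '",
         raw$secondary_damage[i], "'", call. = FALSE)
  }
  out <- data.frame(
    net_id = raw$net_id,
    brand = raw$brand,
    bursting_kpa = parse_numeric_field(raw$bursting_kpa, "bursting_kpa",
                                       rows, positive = TRUE),
    snag_n = parse_numeric_field(raw$snag_n, "snag_n", rows,
                                 positive = TRUE),
    abrasion_rubs = parse_numeric_field(raw$abrasion_rubs, "abrasion_rubs",
                                        rows, integer = TRUE, min = 0),
    end_hole_mm = parse_numeric_field(raw$end_hole_mm, "end_hole_mm", rows,
                                      min = 0),
    secondary_damage = damage,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lab_panel", "data.frame")
  out
}

#' Read field hole-survey records
#'
#' Reads per-net field physical-integrity records: either pre-tabulated WHO
#' band counts (columns `N1, N2, N3, N4`) or raw hole diameters in cm
#' (column `hole_diameters_cm`, semicolon-separated, e.g. `"1.25;10"`), plus
#' `net_id`, `brand`, `months_in_use`. Exactly one of the two hole encodings
#' must be present. Raw diameters are kept unclassified (see
#' [classify_hole()] and [phi_summary()]); each must be at or above the WHO
#' 0.5 cm recording threshold.
#'
#' @inheritParams read_lab_records
#' @return a data frame of class `field_survey`, one validated row per net.
#'   Diameter lists are returned in a list-column `hole_diameters_cm`.
#' @export
read_field_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  raw <- read_raw_table(path, format)
  check_columns(raw, FIELD_BASE_COLUMNS, "field record file")
  has_census <- any(FIELD_CENSUS_COLUMNS %in% names(raw))
  has_diam <- "hole_diameters_cm" %in% names(raw)
  if (has_census && has_diam) {
    stop("field record file has both band counts (N1..N4) and raw ",
         "diameters (hole_diameters_cm); provide exactly one encoding",
         call. = FALSE)
  }
  if (!has_census && !has_diam) {
    stop("field record file needs either columns N1..N4 or ",
         "hole_diameters_cm", call. = FALSE)
  }
  if (has_census) check_columns(raw, FIELD_CENSUS_COLUMNS, "field record file")
  n <- nrow(raw)
  rows <- seq_len(n)
  out <- data.frame(
    net_id = as.character(raw$net_id),
    brand = as.character(raw$brand),
    months_in_use = if (n) parse_numeric_field(raw$months_in_use,
                                               "months_in_use", rows,
                                               min = 0) else numeric(),
    stringsAsFactors = FALSE
  )
  if (has_census) {
    for (col in FIELD_CENSUS_COLUMNS) {
      out[[col]] <- as.integer(parse_numeric_field(raw[[col]], col, rows,
                                                   integer = TRUE, min = 0))
    }
  } else {
    out$hole_diameters_cm <- lapply(rows, function(i) {
      s <- trimws(raw$hole_diameters_cm[i])
      if (!nzchar(s)) return(numeric())
      parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
      d <- suppressWarnings(as.numeric(parts))
      if (anyNA(d)) {
        stop("row ", i, ", field hole_diameters_cm: not a number ('",
             parts[which(is.na(d))[1]], "')", call. = FALSE)
      }
      if (any(d < 0.5)) {
        stop("row ", i, ", field hole_diameters_cm: diameter below the ",
             "0.5 cm recording threshold (", min(d), ")", call. = FALSE)
      }
      d
    })
  }
  class(out) <- c("field_survey", "data.frame")
  out
}

round_report <- function(results) {
  out <- as.data.frame(results)
  if (inherits(results, "rd_report")) {
    # RD scores are reported to one decimal place.
    for (col in c("bursting", "snag", "abrasion", "hole_enlargement",
                  "total")) {
      if (col %in% names(out)) out[[col]] <- round(out[[col]], 1)
    }
    out <- out[order(out$method, out$net_id), , drop = FALSE]
  } else if (inherits(results, "phi_report")) {
    # hole indices are reported to the nearest integer.
    out$mean_hole_index <- round(out$mean_hole_index)
    out <- out[order(out[[1]]), , drop = FALSE]
  }
  # record collections (lab_panel, field_survey) pass through at full
  # precision and input order so that write-then-read round-trips exactly
  if ("hole_diameters_cm" %in% names(out)) {
    out$hole_diameters_cm <- vapply(
      out$hole_diameters_cm,
      function(d) paste(vapply(d, format, character(1), digits = 15),
                        collapse = ";"),
      character(1))
  }
  rownames(out) <- NULL
  out
}

#' Write a scoring or PHI report
#'
#' Writes an [score_panel()] RD report or a [phi_summary()] PHI report to
#' CSV or JSON with deterministic formatting: stable row ordering, RD scores
#' rounded to one decimal place, hole indices to the nearest integer.
#' Writing the same results twice yields byte-identical files.
#'
#' @param results a non-empty report data frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  if (!dir.exists(dirname(path))) {
    stop("cannot write report: directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  out <- round_report(results)
  if (format == "csv") {
    # Fixed decimal rendering keeps output byte-stable across platforms.
    printable <- out
    for (col in names(printable)) {
      if (inherits(results, "rd_report") &&
          col %in% c("bursting", "snag", "abrasion", "hole_enlargement",
                     "total")) {
        printable[[col]] <- sprintf("%.1f", printable[[col]])
      }
    }
    utils::write.csv(printable, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
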