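# Resistance-to-damage (RD) scoring: Method 1 (proximity to aspirational
# values) and Method 2 (KPI score matrix with secondary-damage penalty).

#' Aspirational performance values
#'
#' Reference levels that a net meeting the aspirational resistance-to-damage
#' target would attain: bursting strength 700 kPa, snag strength 200 N,
#' abrasion resistance 400 rubs, and the maximum hole-enlargement score 100
#' (end hole under 5 mm with no secondary damage). These are the
#' denominators of the Method 1 score and the top tiers of the Method 2
#' score matrix.
#'
#' @param bursting_kpa aspirational mean bursting strength in kPa.
#' @param snag_n aspirational mean snag strength in N.
#' @param abrasion_rubs aspirational abrasion endurance in rubs.
#' @param hole_score_max maximum hole-enlargement resistance score.
#' @return an object of class `aspirational_values`.
#' @examples
#' aspirational_values()
#' aspirational_values(bursting_kpa = 500)
#' @export
aspirational_values <- function(bursting_kpa = 700, snag_n = 200,
                                abrasion_rubs = 400, hole_score_max = 100) {
  vals <- c(bursting_kpa = bursting_kpa, snag_n = snag_n,
            abrasion_rubs = abrasion_rubs, hole_score_max = hole_score_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all aspirational values must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "aspirational_values")
}

#' @export
print.aspirational_values <- function(x, ...) {
  cat("Aspirational values: bursting", x$bursting_kpa, "kPa; snag",
      x$snag_n, "N; abrasion", x$abrasion_rubs, "rubs; hole score max",
      x$hole_score_max, "\n")
  invisible(x)
}

# Secondary-damage categories, in increasing order of severity.
SECONDARY_DAMAGE_LEVELS <- c("none", "laddering", "unravelling",
                             "tearing_combined")

# End-hole-size bands: <=5 mm, (5, 20] mm, >20 mm.
hole_band <- function(end_hole_mm) {
  if (any(!is.finite(end_hole_mm)) || any(end_hole_mm < 0)) {
    stop("end hole size must be finite and non-negative", call. = FALSE)
  }
  findInterval(end_hole_mm, c(5, 20), left.open = TRUE) + 1L
}

#' Method 1 hole-enlargement score table
#'
#' The hole-enlargement resistance score used by Method 1 is the product of a
#' base score for the end-hole-size band (100 for <= 5 mm, 80 for 6--20 mm,
#' 40 for >= 21 mm) and a multiplier for the secondary-damage type (none 1.0,
#' laddering 0.8, unravelling 0.5, tearing combined with laddering or
#' unravelling 0.4). The product reproduces every cell of the published
#' 4 x 3 score table.
#'
#' @param base numeric(3), base score per end-size band.
#' @param multiplier named numeric(4), multiplier per secondary-damage type.
#' @return an object of class `hole_score_table`.
#' @examples
#' tab <- hole_score_table()
#' hole_enlargement_score_m1(10, "laddering", tab) # 64
#' @export
hole_score_table <- function(base = c(100, 80, 40),
                             multiplier = c(none = 1.0, laddering = 0.8,
                                            unravelling = 0.5,
                                            tearing_combined = 0.4)) {
  stopifnot(length(base) == 3, all(base > 0),
            identical(sort(names(multiplier)),
                      sort(SECONDARY_DAMAGE_LEVELS)),
            all(multiplier > 0), all(multiplier <= 1))
  structure(list(base = base, multiplier = multiplier[SECONDARY_DAMAGE_LEVELS]),
            class = "hole_score_table")
}

#' Hole-enlargement resistance score (Method 1)
#'
#' Looks up the Method 1 hole-enlargement score for an end hole size and
#' secondary-damage type, as base(band) x multiplier(damage type).
#'
#' @param end_hole_mm final hole size after the enlargement test, in mm.
#' @param secondary_damage one of `"none"`, `"laddering"`, `"unravelling"`,
#'   `"tearing_combined"`. Vectorised together with `end_hole_mm`.
#' @param table a [hole_score_table()].
#' @return numeric score in (0, 100].
#' @export
hole_enlargement_score_m1 <- function(end_hole_mm, secondary_damage,
                                      table = hole_score_table()) {
  secondary_damage <- match_secondary_damage(secondary_damage)
  band <- hole_band(end_hole_mm)
  unname(table$base[band] * table$multiplier[secondary_damage])
}

match_secondary_damage <- function(x) {
  x <- normalise_secondary_damage(as.character(x))
  bad <- !(x %in% SECONDARY_DAMAGE_LEVELS)
  if (any(bad)) {
    stop("unknown secondary-damage label: ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(SECONDARY_DAMAGE_LEVELS, collapse = ", "),
         ")", call. = FALSE)
  }
  x
}

# Case-insensitive; "tearing+laddering" / "tearing+unravelling" (and spelled
# out "tearing combined with ...") collapse to the single tearing_combined
# category.
normalise_secondary_damage <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("[ +]+", "_", y)
  y[grepl("^tearing", y)] <- "tearing_combined"
  y
}

#' Score matrix for Method 2 (KPI) scoring
#'
#' The tiered score matrix: for each numeric parameter an ordered set of
#' lower tier edges with the score awarded from that edge up to the next one
#' (values below the first edge take the minimum score 1), plus the
#' hole-enlargement scores per end-size band and the secondary-damage
#' penalties. Defaults reproduce the published matrix: bursting and snag
#' have 11 tiers scored 1, 2.5, 5, ..., 25 (bursting edges every 50 kPa from
#' 250 to 700; snag every 20 N from 20 to 200); abrasion has 9 tiers scored
#' 1, 3, 6, 9, 13, 16, 19, 22, 25 with lower edges 25, 75, 125, 175, 250,
#' 300, 350, 400. The penalty score is
#' `penalty(damage) * hole_score / 100`.
#'
#' @param bursting,snag,abrasion data frames with columns `lower` (tier lower
#'   edge, strictly increasing) and `score` (strictly increasing). The
#'   implicit bottom tier below the first `lower` scores `min(score)` is
#'   included as row one with `lower = 0`.
#' @param hole_scores numeric(3): hole-enlargement score for end-size bands
#'   <= 5 mm, 6--20 mm, >= 21 mm (stored worst-band last).
#' @param penalties named numeric(4): secondary-damage penalty per type.
#' @return an object of class `score_matrix`.
#' @examples
#' m <- default_score_matrix()
#' bin_score(250, "bursting", m)  # 2.5
#' bin_score(59, "snag", m)      # 5
#' @export
score_matrix <- function(bursting, snag, abrasion,
                         hole_scores = c(25, 20, 10),
                         penalties = c(none = 0, laddering = 10,
                                       unravelling = 20,
                                       tearing_combined = 30)) {
  tiers <- list(bursting = bursting, snag = snag, abrasion = abrasion)
  for (p in names(tiers)) {
    t <- tiers[[p]]
    if (!is.data.frame(t) || !all(c("lower", "score") %in% names(t))) {
      stop("tier table for ", p, " needs columns 'lower' and 'score'",
           call. = FALSE)
    }
    if (is.unsorted(t$lower, strictly = TRUE) ||
        is.unsorted(t$score, strictly = TRUE)) {
      stop("tier edges and scores for ", p,
           " must be strictly increasing", call. = FALSE)
    }
    if (t$lower[1] != 0) {
      stop("tier table for ", p,
           " must start at lower = 0 (the below-first-range tier)",
           call. = FALSE)
    }
  }
  stopifnot(length(hole_scores) == 3, all(diff(hole_scores) < 0),
            identical(sort(names(penalties)),
                      sort(SECONDARY_DAMAGE_LEVELS)),
            all(penalties >= 0), penalties[["none"]] == 0)
  structure(c(tiers,
              list(hole_scores = hole_scores,
                   penalties = penalties[SECONDARY_DAMAGE_LEVELS])),
            class = "score_matrix")
}

#' @rdname score_matrix
#' @export
default_score_matrix <- function() {
  eleven <- c(1, seq(2.5, 25, by = 2.5))
  score_matrix(
    bursting = data.frame(lower = c(0, seq(250, 700, by = 50)),
                          score = eleven),
    snag = data.frame(lower = c(0, seq(20, 200, by = 20)),
                      score = eleven),
    abrasion = data.frame(lower = c(0, 25, 75, 125, 175, 250, 300, 350, 400),
                          score = c(1, 3, 6, 9, 13, 16, 19, 22, 25))
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Method 2 score matrix\n")
  for (p in c("bursting", "snag", "abrasion")) {
    cat(sprintf("  %-8s %d tiers, scores %s..%s\n", p, nrow(x[[p]]),
                min(x[[p]]$score), max(x[[p]]$score)))
  }
  cat("  hole scores", paste(x$hole_scores, collapse = "/"),
      "; penalties", paste(x$penalties, collapse = "/"), "\n")
  invisible(x)
}

#' Tiered score lookup
#'
#' Returns the score of the highest tier whose lower edge does not exceed
#' the measured value; values below the first named range take the minimum
#' score.
#'
#' @param value measured value(s) (kPa, N, or rubs); must be >= 0.
#' @param parameter `"bursting"`, `"snag"`, or `"abrasion"`.
#' @param matrix a [score_matrix()].
#' @return numeric score(s).
#' @export
bin_score <- function(value, parameter = c("bursting", "snag", "abrasion"),
                      matrix = default_score_matrix()) {
  parameter <- match.arg(parameter)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("value must be finite and non-negative", call. = FALSE)
  }
  t <- matrix[[parameter]]
  t$score[findInterval(value, t$lower)]
}

#' Method 2 hole-enlargement score and secondary-damage penalty
#'
#' The hole term of the Method 2 total is `sigma_h - rho_h` where `sigma_h`
#' is the banded hole-enlargement score and
#' `rho_h = penalty(damage) * sigma_h / 100`; no secondary damage means no
#' penalty.
#'
#' @inheritParams hole_enlargement_score_m1
#' @param matrix a [score_matrix()].
#' @return a list with components `sigma_h` and `rho_h` (vectorised).
#' @export
penalty_score <- function(end_hole_mm, secondary_damage,
                          matrix = default_score_matrix()) {
  secondary_damage <- match_secondary_damage(secondary_damage)
  sigma_h <- matrix$hole_scores[hole_band(end_hole_mm)]
  rho_h <- unname(matrix$penalties[secondary_damage]) * sigma_h / 100
  list(sigma_h = sigma_h, rho_h = rho_h)
}

as_lab_record <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  needed <- c("bursting_kpa", "snag_n", "abrasion_rubs", "end_hole_mm",
              "secondary_damage")
  missing <- setdiff(needed, names(record))
  if (length(missing)) {
    stop("lab record is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in c("bursting_kpa", "snag_n", "abrasion_rubs")) {
    if (!is.finite(record[[f]]) || record[[f]] <= 0) {
      stop("field ", f, " must be a positive number", call. = FALSE)
    }
  }
  record
}

#' RD by Method 1: proximity to aspirational values
#'
#' Each laboratory value contributes a quarter of the 100-point scale in
#' proportion to its aspirational value, and the hole-enlargement score
#' contributes its quarter directly:
#' `RD = 25 * lambda_B/eta_B + 25 * lambda_S/eta_S + 25 * lambda_A/eta_A +
#' sigma_H / 4`. Totals are not clamped: a net exceeding an aspirational
#' value scores above 100 on that term.
#'
#' @param record a single lab record: a one-row data frame or named list with
#'   fields `bursting_kpa`, `snag_n`, `abrasion_rubs`, `end_hole_mm`,
#'   `secondary_damage` (and optionally `net_id`).
#' @param aspirational an [aspirational_values()] object.
#' @param table a [hole_score_table()].
#' @return an `rd_result` list: `net_id`, `method`, `contributions` (named
#'   numeric: bursting, snag, abrasion, hole_enlargement), `total`.
#' @examples
#' net <- list(net_id = "A", bursting_kpa = 350, snag_n = 100,
#'             abrasion_rubs = 200, end_hole_mm = 3, secondary_damage = "unravelling")
#' rd_method1(net)$total  # 50
#' @export
rd_method1 <- function(record, aspirational = aspirational_values(),
                       table = hole_score_table()) {
  record <- as_lab_record(record)
  if (!inherits(aspirational, "aspirational_values")) {
    aspirational <- do.call(aspirational_values, as.list(aspirational))
  }
  sigma_h <- hole_enlargement_score_m1(record$end_hole_mm,
                                       record$secondary_damage, table)
  contributions <- c(
    bursting = record$bursting_kpa / aspirational$bursting_kpa * 25,
    snag = record$snag_n / aspirational$snag_n * 25,
    abrasion = record$abrasion_rubs / aspirational$abrasion_rubs * 25,
    hole_enlargement = sigma_h / 4
  )
  new_rd_result(record$net_id, "method1", contributions)
}

#' RD by Method 2: KPI score matrix
#'
#' Each numeric parameter is scored by its tier in the score matrix and the
#' hole-enlargement term is the banded score net of the secondary-damage
#' penalty: `RD = sigma_B + sigma_S + sigma_A + (sigma_H - rho_H)`. The
#' maximum attainable total is 100.
#'
#' @inheritParams rd_method1
#' @param matrix a [score_matrix()].
#' @return an `rd_result` list, as for [rd_method1()].
#' @examples
#' net <- list(net_id = "A", bursting_kpa = 700, snag_n = 200,
#'             abrasion_rubs = 400, end_hole_mm = 3, secondary_damage = "none")
#' rd_method2(net)$total  # 100
#' @export
rd_method2 <- function(record, matrix = default_score_matrix()) {
  record <- as_lab_record(record)
  hole <- penalty_score(record$end_hole_mm, record$secondary_damage, matrix)
  contributions <- c(
    bursting = bin_score(record$bursting_kpa, "bursting", matrix),
    snag = bin_score(record$snag_n, "snag", matrix),
    abrasion = bin_score(record$abrasion_rubs, "abrasion", matrix),
    hole_enlargement = hole$sigma_h - hole$rho_h
  )
  new_rd_result(record$net_id, "method2", contributions)
}

new_rd_result <- function(net_id, method, contributions) {
  structure(list(net_id = if (is.null(net_id)) NA_character_ else net_id,
                 method = method,
                 contributions = contributions,
                 total = sum(contributions)),
            class = "rd_result")
}

#' @export
print.rd_result <- function(x, ...) {
  cat(sprintf("RD (%s) for %s: %.1f\n", x$method, x$net_id, x$total))
  print(round(x$contributions, 2))
  invisible(x)
}

#' Score a panel of nets
#'
#' Applies [rd_method1()] and/or [rd_method2()] to every record of a lab
#' panel, preserving input order.
#'
#' @param panel a lab panel data frame as returned by [read_lab_records()] or
#'   [generate_lab_panel()].
#' @param method `"method1"`, `"method2"`, or `"both"`.
#' @param aspirational an [aspirational_values()] object (Method 1).
#' @param table a [hole_score_table()] (Method 1).
#' @param matrix a [score_matrix()] (Method 2).
#' @return a data frame of class `rd_report` with one row per record and
#'   method: `net_id`, `brand`, `method`, the four per-parameter
#'   contributions, and `total`.
#' @export
score_panel <- function(panel, method = c("method1", "method2", "both"),
                        aspirational = aspirational_values(),
                        table = hole_score_table(),
                        matrix = default_score_matrix()) {
  method <- match.arg(method)
  if (!is.data.frame(panel) || nrow(panel) == 0) {
    stop("panel must be a non-empty data frame of lab records", call. = FALSE)
  }
  methods <- if (method == "both") c("method1", "method2") else method
  rows <- list()
  for (m in methods) {
    for (i in seq_len(nrow(panel))) {
      rec <- panel[i, , drop = FALSE]
      res <- if (m == "method1") {
        rd_method1(rec, aspirational, table)
      } else {
        rd_method2(rec, matrix)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        net_id = as.character(res$net_id),
        brand = if ("brand" %in% names(panel)) as.character(rec$brand)
                else NA_character_,
        method = m,
        bursting = res$contributions[["bursting"]],
        snag = res$contributions[["snag"]],
        abrasion = res$contributions[["abrasion"]],
        hole_enlargement = res$contributions[["hole_enlargement"]],
        total = res$total,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rd_report", "data.frame")
  out
}
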