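# Seeded synthetic lab panels and matching field hole-census data with a
# known (linear, decreasing) PHI-versus-RD link, so the full pipeline can be
# exercised and calibrated without external data.

#' Configuration for the synthetic-data generator
#'
#' Describes a panel of net products and the lab-to-field link used to
#' generate matching field data. Defaults emulate the study conditions the
#' scoring method was developed under: a 16-product panel whose laboratory
#' values span the full score-matrix ranges (bursting 100--900 kPa, snag
#' 10--250 N, abrasion 10--450 rubs, uniform draws), hole-enlargement
#' outcomes uniform over the 12 band-by-damage cells, and a decreasing
#' linear link from Method 1 RD to the expected field hole index
#' (`PHI = max(0, intercept + slope * RD) + noise`).
#'
#' @param n_nets number of net products in the panel.
#' @param seed integer seed; the field-noise stream uses `seed + 1` so lab
#'   and field draws are independent but both reproducible.
#' @param bursting,snag,abrasion length-2 ranges (min, max) for the uniform
#'   draws of each lab parameter.
#' @param hole_probs 3 x 4 matrix of probabilities over (end-size band x
#'   secondary-damage type) cells; rows are the bands <= 5 / 6--20 / >= 21 mm,
#'   columns `none, laddering, unravelling, tearing_combined`.
#' @param phi_intercept,phi_slope linear link from Method 1 RD to the
#'   expected hole index; `phi_slope` must be <= 0 (higher RD, fewer holes).
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   expected hole index before discretisation (>= 0).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nets = 16, seed = 1,
                             bursting = c(100, 900),
                             snag = c(10, 250),
                             abrasion = c(10, 450),
                             hole_probs = matrix(1 / 12, 3, 4),
                             phi_intercept = 800, phi_slope = -8,
                             noise_sd = 60) {
  stopifnot(n_nets >= 1, n_nets == round(n_nets),
            length(seed) == 1, is.finite(seed))
  for (rng in list(bursting = bursting, snag = snag, abrasion = abrasion)) {
    if (length(rng) != 2 || rng[1] <= 0 || rng[2] <= rng[1]) {
      stop("each parameter range must be (min, max) with 0 < min < max",
           call. = FALSE)
    }
  }
  hole_probs <- as.matrix(hole_probs)
  if (!all(dim(hole_probs) == c(3, 4)) || any(hole_probs < 0) ||
      abs(sum(hole_probs) - 1) > 1e-8) {
    stop("hole_probs must be a 3 x 4 matrix of probabilities summing to 1",
         call. = FALSE)
  }
  if (phi_slope > 0) {
    stop("phi_slope must be <= 0: the field hole index decreases with RD",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_nets = as.integer(n_nets), seed = as.integer(seed),
                 bursting = bursting, snag = snag, abrasion = abrasion,
                 hole_probs = hole_probs,
                 phi_intercept = phi_intercept, phi_slope = phi_slope,
                 noise_sd = noise_sd),
            class = "synthetic_config")
}

as_synthetic_config <- function(config) {
  if (inherits(config, "synthetic_config")) config
  else do.call(synthetic_config, as.list(config))
}

#' Generate a synthetic laboratory panel
#'
#' Draws `n_nets` textile-test records with parameter values spanning the
#' configured ranges. Reproducible for a fixed seed; the global random state
#' is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return a `lab_panel` data frame (same schema as [read_lab_records()]).
#' @examples
#' panel <- generate_lab_panel(synthetic_config(n_nets = 4, seed = 7))
#' score_panel(panel, "method1")$total
#' @export
generate_lab_panel <- function(config = synthetic_config()) {
  config <- as_synthetic_config(config)
  n <- config$n_nets
  withr::with_seed(config$seed, {
    cell <- sample.int(12, n, replace = TRUE, prob = as.vector(config$hole_probs))
    band <- (cell - 1L) %% 3L + 1L          # row index of hole_probs
    damage <- SECONDARY_DAMAGE_LEVELS[(cell - 1L) %/% 3L + 1L]
    end_mm <- numeric(n)
    end_mm[band == 1L] <- stats::runif(sum(band == 1L), 0.5, 5)
    end_mm[band == 2L] <- stats::runif(sum(band == 2L), 6, 20)
    end_mm[band == 3L] <- stats::runif(sum(band == 3L), 21, 40)
    out <- data.frame(
      net_id = sprintf("net%02d", seq_len(n)),
      brand = sprintf("B%02d", seq_len(n)),
      bursting_kpa = stats::runif(n, config$bursting[1], config$bursting[2]),
      snag_n = stats::runif(n, config$snag[1], config$snag[2]),
      abrasion_rubs = pmax(1L, as.integer(round(
        stats::runif(n, config$abrasion[1], config$abrasion[2])))),
      end_hole_mm = end_mm,
      secondary_damage = damage,
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("lab_panel", "data.frame")
  out
}

#' Decompose a target hole index into a band census
#'
#' Greedy decomposition, largest weight first, remainder in size-1 holes:
#' the resulting census reproduces the (rounded) target index exactly, and
#' small holes dominate the counts as they do in real surveys.
#'
#' @param target_index non-negative target hole index (rounded to the
#'   nearest integer before decomposition).
#' @return named integer vector `(N1, N2, N3, N4)` with
#'   `hole_index(census) == round(max(0, target_index))`.
#' @examples
#' decompose_hole_index(772)  # 0, 0, 1, 1
#' @export
decompose_hole_index <- function(target_index) {
  h <- round(max(0, target_index))
  w <- who_hole_bands()$weight  # 1, 23, 196, 576
  counts <- integer(4)
  for (b in 4:1) {
    counts[b] <- as.integer(h %/% w[b])
    h <- h %% w[b]
  }
  names(counts) <- paste0("N", 1:4)
  counts
}

#' Generate matching synthetic field data
#'
#' For each net in a lab panel, draws a field hole census whose hole index
#' realises `max(0, intercept + slope * RD_method1) + Gaussian noise`
#' (clipped at zero, rounded, and decomposed into band counts via
#' [decompose_hole_index()]). Months in use are drawn uniformly between 12
#' and 36, matching 1--3 years of service. Reproducible for a fixed seed.
#'
#' @param panel a `lab_panel` data frame.
#' @param config a [synthetic_config()].
#' @return a `field_survey` data frame with census columns `N1`..`N4`.
#' @export
generate_field_phi <- function(panel, config = synthetic_config()) {
  config <- as_synthetic_config(config)
  rd <- score_panel(panel, "method1")$total
  n <- length(rd)
  withr::with_seed(config$seed + 1L, {
    target <- pmax(0, config$phi_intercept + config$phi_slope * rd) +
      stats::rnorm(n, 0, config$noise_sd)
    months <- sample(12:36, n, replace = TRUE)
  })
  census <- t(vapply(target, decompose_hole_index, integer(4)))
  out <- data.frame(
    net_id = panel$net_id,
    brand = if ("brand" %in% names(panel)) panel$brand else panel$net_id,
    months_in_use = months,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(census))
  class(out) <- c("field_survey", "data.frame")
  out
}

#' Noise level for a target generating r-squared
#'
#' Given the RD values of a panel and the link slope, returns the Gaussian
#' noise standard deviation at which the linear link's population coefficient
#' of determination equals `r_squared`:
#' `noise_sd = |slope| * sd(rd) * sqrt((1 - r2) / r2)`.
#'
#' @param rd numeric RD values of the panel to be linked.
#' @param slope link slope.
#' @param r_squared target generating r^2 in (0, 1).
#' @return noise standard deviation.
#' @export
noise_sd_for_r2 <- function(rd, slope, r_squared) {
  stopifnot(r_squared > 0, r_squared < 1, length(rd) >= 2)
  abs(slope) * stats::sd(rd) * sqrt((1 - r_squared) / r_squared)
}

#' Write the canonical small fixture files
#'
#' Writes a 3-net lab panel, the matching 3-net field census, and an example
#' configuration file — the small canonical inputs used in the documentation
#' and tests. Content is fixed; re-running produces byte-identical files.
#'
#' @param output_dir writable directory (created if missing).
#' @return character vector of the paths written.
#' @export
make_fixture_suite <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", output_dir, call. = FALSE)
  }
  lab <- file.path(output_dir, "lab3.csv")
  field <- file.path(output_dir, "field3.csv")
  config <- file.path(output_dir, "config-example.json")
  writeLines(c(
    "net_id,brand,bursting_kpa,snag_n,abrasion_rubs,end_hole_mm,secondary_damage",
    "net01,B01,350,100,200,3,none",
    "net02,B02,700,200,400,3,none",
    "net03,B03,250,59,410,10,laddering"
  ), lab)
  writeLines(c(
    "net_id,brand,months_in_use,N1,N2,N3,N4",
    "net01,B01,24,2,1,0,0",
    "net02,B02,24,0,0,0,0",
    "net03,B03,24,0,0,1,1"
  ), field)
  writeLines(c(
    "{",
    "  \"aspirational\": {",
    "    \"bursting_kpa\": 700,",
    "    \"snag_n\": 200,",
    "    \"abrasion_rubs\": 400,",
    "    \"hole_score_max\": 100",
    "  },",
    "  \"pi_value\": 3.142",
    "}"
  ), config)
  invisible(c(lab, field, config))
}
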