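# Force/pressure conversions over a contact area and packaged human-factors
# reference constants (maximal isometric forces, explosive pulling forces,
# adult body weights) used to motivate the aspirational thresholds.

#' Convert a force over a contact area to pressure
#'
#' `pressure [kPa] = force [N] / (area [cm^2] * 1e-4 [m^2/cm^2]) / 1000`.
#' With the standard 7.3 cm^2 burst-test diaphragm this maps the reference
#' human pulling forces onto the bursting-strength scale: 200 N -> ~274 kPa,
#' 308 N -> ~422 kPa, 500 N -> ~685 kPa. Full precision is returned; round
#' only when reporting.
#'
#' @param force_n force in newtons (> 0).
#' @param contact_area_cm2 contact area in cm^2 (> 0).
#' @return pressure in kPa.
#' @examples
#' force_to_pressure(308, 7.3)   # ~421.9 kPa
#' force_to_pressure(308, 1)     # 3080 kPa
#' @export
force_to_pressure <- function(force_n, contact_area_cm2) {
  check_positive(force_n, "force_n")
  check_positive(contact_area_cm2, "contact_area_cm2")
  force_n / (contact_area_cm2 * 1e-4) / 1000
}

#' @rdname force_to_pressure
#' @param pressure_kpa pressure in kPa (> 0).
#' @export
pressure_to_force <- function(pressure_kpa, contact_area_cm2) {
  check_positive(pressure_kpa, "pressure_kpa")
  check_positive(contact_area_cm2, "contact_area_cm2")
  pressure_kpa * 1000 * contact_area_cm2 * 1e-4
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(name, " must be finite and strictly positive", call. = FALSE)
  }
  invisible(x)
}

# Maximal isometric forces (EN 1005-3 style machinery-safety values) and
# explosive pulling forces, N. Isometric rows carry a single force; explosive
# rows carry the min and max of the reported mean-force range.
force_reference_table <- function() {
  iso <- data.frame(
    activity = c("power grip",
                 "arm pulling upwards", "arm pulling downwards",
                 "arm pulling outwards", "arm pulling inwards",
                 "arm pushing with trunk support",
                 "arm pushing without trunk support",
                 "arm pulling with trunk support",
                 "arm pulling without trunk support"),
    kind = "isometric",
    stringsAsFactors = FALSE
  )
  iso <- rbind(
    transform(iso, population = "professional",
              force_min_n = c(250, 50, 75, 55, 75, 275, 62, 225, 55),
              force_max_n = c(250, 50, 75, 55, 75, 275, 62, 225, 55)),
    transform(iso, population = "domestic",
              force_min_n = c(184, 31, 44, 31, 49, 186, 30, 169, 28),
              force_max_n = c(184, 31, 44, 31, 49, 186, 30, 169, 28))
  )
  expl <- data.frame(
    activity = rep(c("underhand pulling", "overhand pulling"), each = 2),
    kind = "explosive",
    population = rep(c("male_21_60", "female_21_60"), times = 2),
    force_min_n = c(145, 85, 99, 78),
    force_max_n = c(185, 123, 308, 260),
    stringsAsFactors = FALSE
  )
  out <- rbind(iso, expl)
  rownames(out) <- NULL
  out
}

#' Human exertable-force reference values
#'
#' Packaged reference table of forces humans can exert: maximal isometric
#' forces per activity for professional and domestic use, and minimum/maximum
#' mean explosive pulling forces for adult males and females aged 21--60
#' (e.g. seated one-arm pulling downwards, professional: 75 N; overhand
#' explosive pulling, male: up to 308 N). These bound the forces a net user
#' can apply and anchor the aspirational snag (200 N) and bursting (700 kPa)
#' thresholds.
#'
#' @param activity optional substring filter on the activity description
#'   (case-insensitive).
#' @param population optional exact filter: `"professional"`, `"domestic"`,
#'   `"male_21_60"`, or `"female_21_60"`.
#' @return a data frame with columns `activity`, `kind` (isometric or
#'   explosive), `population`, `force_min_n`, `force_max_n`.
#' @examples
#' reference_forces("pulling downwards", "professional")
#' reference_forces("overhand")
#' @export
reference_forces <- function(activity = NULL, population = NULL) {
  out <- force_reference_table()
  if (!is.null(activity)) {
    out <- out[grepl(activity, out$activity, ignore.case = TRUE), ,
               drop = FALSE]
  }
  if (!is.null(population)) {
    pops <- unique(force_reference_table()$population)
    if (!population %in% pops) {
      stop("unknown population: ", population, " (expected one of ",
           paste(pops, collapse = ", "), ")", call. = FALSE)
    }
    out <- out[out$population == population, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Mean adult body weights in malaria-endemic countries
#'
#' Packaged mean adult human body weights (kg) for selected malaria-endemic
#' countries and the world average, used to judge how explosive-force values
#' measured on heavier study populations transfer to typical net users.
#'
#' @param country optional substring filter (case-insensitive).
#' @return a data frame with columns `country` and `mean_weight_kg`.
#' @examples
#' body_weights("India")
#' @export
body_weights <- function(country = NULL) {
  out <- data.frame(
    country = c("India", "Ethiopia", "Congo", "Cambodia", "Mozambique",
                "Kenya", "Uganda", "Benin", "Nigeria", "All of World"),
    mean_weight_kg = c(52.9, 53.1, 53.5, 55.7, 56, 56.3, 57, 60.3, 60.7, 62),
    stringsAsFactors = FALSE
  )
  if (!is.null(country)) {
    out <- out[grepl(country, out$country, ignore.case = TRUE), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
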