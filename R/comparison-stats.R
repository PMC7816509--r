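# Association statistics: lab RD versus field PHI, and agreement between
# the two RD scoring methods.

#' Pearson association between two series
#'
#' Coefficient of determination (r^2) of the Pearson correlation between
#' paired observations, with the two-sided p-value from the correlation
#' t-test on n - 2 degrees of freedom, and the ordinary-least-squares line
#' of `y` on `x`. This is the statistic used to relate laboratory
#' resistance-to-damage scores to field hole indices.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each non-constant.
#' @return an object of class `association` with fields `n`, `r`,
#'   `r_squared`, `p_value`, `slope`, `intercept`.
#' @examples
#' a <- pearson_association(1:6, 2 * (1:6) + 1)
#' a$r_squared  # 1
#' @export
pearson_association <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop("association requires at least 3 paired observations (got ", n,
         ")", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  structure(list(n = n,
                 r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("Association (n = %d): r^2 = %.3f, p = %.3g\n",
              x$n, x$r_squared, x$p_value))
  cat(sprintf("  OLS line: y = %.3f + %.3f x\n", x$intercept, x$slope))
  invisible(x)
}

#' Agreement between the two RD scoring methods
#'
#' Scores a lab panel under both Method 1 and Method 2 and measures how well
#' the two totals agree: Pearson r^2 (with p-value and OLS line of Method 2
#' on Method 1) and the Spearman rank correlation. A high rank correlation
#' means the two algorithms order products almost identically even though
#' their scales differ.
#'
#' @inheritParams score_panel
#' @return a list with `scores` (data frame of per-net `method1`/`method2`
#'   totals), `pearson` (an `association`), and `spearman` (rank
#'   correlation).
#' @export
method_agreement <- function(panel, aspirational = aspirational_values(),
                             table = hole_score_table(),
                             matrix = default_score_matrix()) {
  if (!is.data.frame(panel) || nrow(panel) < 3) {
    stop("method agreement requires a panel of at least 3 nets",
         call. = FALSE)
  }
  m1 <- score_panel(panel, "method1", aspirational = aspirational,
                    table = table)
  m2 <- score_panel(panel, "method2", matrix = matrix)
  scores <- data.frame(net_id = m1$net_id, method1 = m1$total,
                       method2 = m2$total, stringsAsFactors = FALSE)
  list(scores = scores,
       pearson = pearson_association(scores$method1, scores$method2),
       spearman = stats::cor(scores$method1, scores$method2,
                             method = "spearman"))
}

#' Lab-versus-field comparison
#'
#' Joins per-brand RD scores (lab) with per-brand mean hole indices (field)
#' and returns their Pearson association. RD totals are averaged per brand
#' when a brand has several products in the lab panel. Non-mechanical damage
#' should be excluded from the field data upstream; no filtering is applied
#' here.
#'
#' @param lab_panel a lab panel data frame.
#' @param field_records a field survey data frame.
#' @param method `"method1"` or `"method2"`.
#' @param ... passed to [score_panel()].
#' @return a list with `pairs` (per-brand RD and mean hole index) and
#'   `association`.
#' @export
compare_lab_field <- function(lab_panel, field_records,
                              method = c("method1", "method2"), ...) {
  method <- match.arg(method)
  rd <- score_panel(lab_panel, method, ...)
  phi <- phi_summary(field_records, group_by = "brand")
  rd_by_brand <- tapply(rd$total, rd$brand, mean)
  unmatched <- setdiff(phi$brand, names(rd_by_brand))
  if (length(unmatched)) {
    stop("field brands with no lab record: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  pairs <- data.frame(brand = phi$brand,
                      rd = unname(rd_by_brand[phi$brand]),
                      mean_hole_index = phi$mean_hole_index,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       association = pearson_association(pairs$rd, pairs$mean_hole_index))
}
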