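# Run configuration: JSON overrides for the aspirational values, the Method 2
# score matrix, and the pi convention used for reported hole areas.

#' Read a run configuration file
#'
#' Parses a JSON configuration mirroring the packaged defaults. Recognised
#' keys (all optional): `aspirational` (object with `bursting_kpa`,
#' `snag_n`, `abrasion_rubs`, `hole_score_max`), `score_matrix` (objects
#' `bursting`/`snag`/`abrasion` with arrays `lower` and `score`, array
#' `hole_scores`, object `penalties`), and `pi_value`. Missing keys fall
#' back to the packaged defaults. An example file ships in
#' `system.file("extdata", "config-example.json", package = "llindur")`.
#'
#' @param path path to a JSON config file, or `NULL` for all defaults.
#' @return a list with elements `aspirational` ([aspirational_values()]),
#'   `matrix` ([score_matrix()]), and `pi_value`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(aspirational = aspirational_values(),
                   matrix = default_score_matrix(),
                   pi_value = 3.142)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$aspirational)) {
    defaults$aspirational <- do.call(aspirational_values,
                                     as.list(cfg$aspirational))
  }
  if (!is.null(cfg$score_matrix)) {
    sm <- cfg$score_matrix
    base <- default_score_matrix()
    tier <- function(p) {
      if (is.null(sm[[p]])) return(base[[p]])
      data.frame(lower = sm[[p]]$lower, score = sm[[p]]$score)
    }
    defaults$matrix <- score_matrix(
      bursting = tier("bursting"), snag = tier("snag"),
      abrasion = tier("abrasion"),
      hole_scores = if (is.null(sm$hole_scores)) base$hole_scores
                    else sm$hole_scores,
      penalties = if (is.null(sm$penalties)) base$penalties
                  else unlist(sm$penalties)
    )
  }
  if (!is.null(cfg$pi_value)) defaults$pi_value <- cfg$pi_value
  defaults
}
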