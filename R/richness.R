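#' First-order jackknife richness estimation
#'
#' Incidence-based estimator of total species richness from presence/absence
#' across sampling units (caves): `S_jack1 = S_obs + Q1 * (n - 1) / n`, where
#' `Q1` is the number of species recorded in exactly one unit. Survey
#' completeness is the ratio of observed to estimated richness.
#'
#' @param S_obs Observed species count.
#' @param Q1 Number of uniques (species in exactly one sampling unit).
#' @param n Number of sampling units.
#' @return `jackknife1()` returns the estimated richness (numeric scalar).
#' @examples
#' jackknife1(32, 21, 105)           # 52.8
#' survey_completeness(32, 52.8)     # ~0.606
#' @rdname jackknife
#' @export
jackknife1 <- function(S_obs, Q1, n) {
  if (n < 1) stop("`n` must be >= 1 sampling unit")
  if (Q1 < 0 || Q1 > S_obs) stop("`Q1` must be in [0, S_obs]")
  S_obs + Q1 * (n - 1) / n
}

#' @param S_jack1 Estimated richness (`>= S_obs`).
#' @return `survey_completeness()` returns `S_obs / S_jack1` in (0, 1].
#' @rdname jackknife
#' @export
survey_completeness <- function(S_obs, S_jack1) {
  if (S_jack1 <= 0) stop("estimated richness must be positive")
  if (S_jack1 < S_obs) stop("estimated richness cannot be below observed")
  S_obs / S_jack1
}

#' Count species with a single occurrence
#'
#' @param occurrences Occurrence table ([read_occurrences()]).
#' @param troglobionts_only If `TRUE` (default) restrict to
#'   subterranean-restricted species.
#' @return Integer count of species recorded in exactly one cave.
#' @export
singleton_count <- function(occurrences, troglobionts_only = TRUE) {
  if (nrow(occurrences) == 0L) stop("occurrence table is empty")
  occ <- if (troglobionts_only) {
    occurrences[occurrences$troglobiont, , drop = FALSE]
  } else occurrences
  if (nrow(occ) == 0L) return(0L)
  caves_per_sp <- tapply(occ$cave_id, occ$species_id,
                         function(z) length(unique(z)))
  sum(caves_per_sp == 1L)
}

#' Richness summary for an assemblage
#'
#' Computes observed richness, singleton count, the first-order jackknife
#' estimate and survey completeness for the (by default troglobiont)
#' assemblage of an occurrence table.
#'
#' @param occurrences Occurrence table ([read_occurrences()]).
#' @param n_units Number of sampling units (caves inventoried); defaults to
#'   the number of distinct caves in the table, but should be the full
#'   inventory size when some caves hold no species of the assemblage.
#' @param troglobionts_only Restrict to troglobionts (default `TRUE`).
#' @return A list with `S_obs`, `Q1`, `n`, `S_jack1`, `completeness`.
#' @export
richness_summary <- function(occurrences, n_units = NULL,
                             troglobionts_only = TRUE) {
  occ <- if (troglobionts_only) {
    occurrences[occurrences$troglobiont, , drop = FALSE]
  } else occurrences
  if (is.null(n_units)) n_units <- length(unique(occurrences$cave_id))
  S_obs <- length(unique(occ$species_id))
  if (S_obs == 0L) {
    return(list(S_obs = 0L, Q1 = 0L, n = n_units, S_jack1 = 0, completeness = NA_real_))
  }
  Q1 <- singleton_count(occurrences, troglobionts_only)
  S_jack1 <- jackknife1(S_obs, Q1, n_units)
  list(S_obs = S_obs, Q1 = as.integer(Q1), n = as.integer(n_units),
       S_jack1 = S_jack1, completeness = survey_completeness(S_obs, S_jack1))
}
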