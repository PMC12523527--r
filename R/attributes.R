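#' Per-cave biodiversity and vulnerability attributes
#'
#' The prioritization framework rates each cave on four raw criteria:
#' \describe{
#'   \item{nTS}{non-troglobite species richness — distinct species recorded
#'     in the cave that are not subterranean-restricted;}
#'   \item{TbS}{troglobite species richness — distinct subterranean-restricted
#'     (troglobiont/stygobiont) species in the cave;}
#'   \item{EnD}{stenoendemic count — troglobiont species whose only known
#'     occurrence in the whole dataset is this cave;}
#'   \item{VuL}{vulnerability — number of distinct anthropogenic impact types
#'     with at least one site within `radius_m` of the cave entrance.}
#' }
#'
#' @param caves Cave table as returned by [read_caves()].
#' @param occurrences Occurrence table as returned by [read_occurrences()].
#' @param impacts Impact site table as returned by [read_impacts()].
#' @param radius_m Buffer radius in meters (default 250).
#' @return A data.frame with columns `cave_id, nTS, TbS, EnD, VuL`, one row
#'   per cave in `caves` order. Caves with no occurrence rows get zero
#'   richness.
#' @examples
#' caves <- data.frame(cave_id = "C1", name = "a", x = 0, y = 0,
#'                     length_m = 50, season = "dry")
#' occ <- data.frame(cave_id = "C1", species_id = c("s1", "t1"),
#'                   troglobiont = c(FALSE, TRUE))
#' imp <- data.frame(impact_type = "mining", x = 100, y = 0)
#' cave_attributes(caves, occ, imp)
#' @export
cave_attributes <- function(caves, occurrences, impacts, radius_m = 250) {
  unknown <- setdiff(unique(occurrences$cave_id), caves$cave_id)
  if (length(unknown)) {
    stop("occurrence rows reference unknown cave_id: ",
         paste(unknown, collapse = ", "))
  }
  ids <- caves$cave_id
  nts <- vapply(ids, function(id) non_troglobite_richness(occurrences, id,
                                                          .checked = FALSE),
                integer(1))
  tbs <- vapply(ids, function(id) troglobite_richness(occurrences, id,
                                                      .checked = FALSE),
                integer(1))
  # per-species cave counts once, then per-cave singleton tallies
  trog <- occurrences[occurrences$troglobiont, , drop = FALSE]
  occ_per_sp <- table(trog$species_id)
  singletons <- names(occ_per_sp)[occ_per_sp == 1L]
  sing_rows <- trog[trog$species_id %in% singletons, , drop = FALSE]
  end_tab <- table(factor(sing_rows$cave_id, levels = ids))
  vul <- vapply(seq_along(ids), function(i) {
    vulnerability_count(caves$x[i], caves$y[i], impacts, radius_m)
  }, integer(1))
  data.frame(cave_id = ids, nTS = as.integer(nts), TbS = as.integer(tbs),
             EnD = as.integer(end_tab), VuL = vul,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-cave attribute queries
#'
#' Building blocks of [cave_attributes()], exposed for interactive use.
#' `non_troglobite_richness()` and `troglobite_richness()` count distinct
#' species with the corresponding flag in one cave; `stenoendemic_count()`
#' counts troglobiont species whose only occurrence in the entire table is
#' the given cave; `vulnerability_count()` counts distinct impact types
#' within the buffer (boundary inclusive).
#'
#' @param occurrences Occurrence table ([read_occurrences()]).
#' @param cave_id Cave identifier; must be present in the occurrence table
#'   (richness of a cave with no records is queried through
#'   [cave_attributes()], which knows the full cave list).
#' @param .checked Internal: skip the cave_id presence check.
#' @return An integer count.
#' @rdname cave_attribute_queries
#' @export
non_troglobite_richness <- function(occurrences, cave_id, .checked = TRUE) {
  if (.checked) .kp_check_cave(occurrences, cave_id)
  rows <- occurrences$cave_id == cave_id & !occurrences$troglobiont
  length(unique(occurrences$species_id[rows]))
}

#' @rdname cave_attribute_queries
#' @export
troglobite_richness <- function(occurrences, cave_id, .checked = TRUE) {
  if (.checked) .kp_check_cave(occurrences, cave_id)
  rows <- occurrences$cave_id == cave_id & occurrences$troglobiont
  length(unique(occurrences$species_id[rows]))
}

#' @rdname cave_attribute_queries
#' @export
stenoendemic_count <- function(occurrences, cave_id, .checked = TRUE) {
  if (.checked) .kp_check_cave(occurrences, cave_id)
  trog <- occurrences[occurrences$troglobiont, , drop = FALSE]
  here <- unique(trog$species_id[trog$cave_id == cave_id])
  if (!length(here)) return(0L)
  caves_per_sp <- tapply(trog$cave_id, trog$species_id,
                         function(z) length(unique(z)))
  sum(caves_per_sp[here] == 1L)
}

#' @param x,y Cave location in planar meters.
#' @param impacts Impact site table ([read_impacts()]).
#' @param radius_m Buffer radius in meters; sites at exactly `radius_m` count.
#' @rdname cave_attribute_queries
#' @export
vulnerability_count <- function(x, y, impacts, radius_m = 250) {
  if (radius_m <= 0) stop("`radius_m` must be > 0")
  if (is.null(impacts) || nrow(impacts) == 0L) return(0L)
  d2 <- (impacts$x - x)^2 + (impacts$y - y)^2
  length(unique(impacts$impact_type[d2 <= radius_m^2]))
}

.kp_check_cave <- function(occurrences, cave_id) {
  if (!cave_id %in% occurrences$cave_id) {
    stop("cave_id not present in occurrence table: ", cave_id)
  }
}
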