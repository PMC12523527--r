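#' Study configuration
#'
#' Bundles every tunable of the prioritization pipeline: the analysis extent
#' and grid resolution, the vulnerability buffer radius, the number of
#' priority classes, the category weight map, and the policy for caves with
#' no stenoendemic species.
#'
#' @param bbox Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in planar
#'   meters. Default covers a 40 x 30 km landscape (1200 km^2).
#' @param ncols,nrows Grid dimensions (columns along x, rows along y).
#'   Defaults 40 x 30 give 1200 cells of 1 km^2 each.
#' @param buffer_radius_m Radius in meters of the impact buffer around each
#'   cave used for the vulnerability criterion. Default 250 m, following the
#'   buffer mandated for Brazilian caves by Decree 6640/2008.
#' @param n_classes Number of priority classes for the natural-breaks
#'   classification of composite cell values. Default 4.
#' @param weights Named numeric vector mapping the four categories to scores.
#'   Must be strictly increasing in the order Low, Average, High, Extreme.
#' @param end_zero_policy How a stenoendemic count of zero is categorized:
#'   `"table_literal"` (default) places it in the Low category; `"zero"`
#'   assigns no category and a score of 0.
#' @param tbs_extreme_min Minimum troglobite richness for the Extreme
#'   category. Default 7.
#' @param seed Optional integer seed recorded in reports for provenance.
#'
#' @return An object of class `study_config` (a validated list).
#' @examples
#' cfg <- study_config()
#' cfg$weights
#' @export
study_config <- function(bbox = c(0, 0, 40000, 30000),
                         ncols = 40, nrows = 30,
                         buffer_radius_m = 250,
                         n_classes = 4,
                         weights = c(Low = 100, Average = 250,
                                     High = 500, Extreme = 1000),
                         end_zero_policy = c("table_literal", "zero"),
                         tbs_extreme_min = 7,
                         seed = NULL) {
  end_zero_policy <- match.arg(end_zero_policy)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || anyNA(bbox) || !all(is.finite(bbox))) {
    stop("`bbox` must be four finite numbers (xmin, ymin, xmax, ymax)")
  }
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("`bbox` must satisfy xmax > xmin and ymax > ymin")
  }
  if (!is.numeric(ncols) || ncols < 1 || ncols != round(ncols) ||
      !is.numeric(nrows) || nrows < 1 || nrows != round(nrows)) {
    stop("`ncols` and `nrows` must be positive integers")
  }
  if (!is.numeric(buffer_radius_m) || buffer_radius_m <= 0) {
    stop("`buffer_radius_m` must be a positive number")
  }
  if (!is.numeric(n_classes) || n_classes < 1 || n_classes != round(n_classes)) {
    stop("`n_classes` must be a positive integer")
  }
  req <- c("Low", "Average", "High", "Extreme")
  if (!all(req %in% names(weights))) {
    stop("`weights` must name all of: ", paste(req, collapse = ", "))
  }
  w <- as.numeric(weights[req])
  if (any(diff(w) <= 0) || any(w <= 0)) {
    stop("`weights` must be strictly increasing from Low to Extreme and positive")
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be coercible to integer")
  }
  structure(
    list(bbox = bbox, ncols = as.integer(ncols), nrows = as.integer(nrows),
         buffer_radius_m = buffer_radius_m, n_classes = as.integer(n_classes),
         weights = stats::setNames(w, req),
         end_zero_policy = end_zero_policy,
         tbs_extreme_min = as.integer(tbs_extreme_min),
         seed = seed),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  extent : [%g, %g] x [%g, %g] m\n",
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  cat(sprintf("  grid   : %d cols x %d rows (%d cells)\n",
              x$ncols, x$nrows, x$ncols * x$nrows))
  cat(sprintf("  buffer : %g m; priority classes: %d\n",
              x$buffer_radius_m, x$n_classes))
  cat(sprintf("  weights: %s\n",
              paste(names(x$weights), x$weights, sep = "=", collapse = ", ")))
  cat(sprintf("  EnD=0 policy: %s; TbS extreme threshold: >=%d\n",
              x$end_zero_policy, x$tbs_extreme_min))
  invisible(x)
}

# category ranks shared across the scoring helpers; "None" means the
# attribute contributes nothing (score 0)
.kp_categories <- c("None", "Low", "Average", "High", "Extreme")

.kp_impact_types <- c("pasture", "agriculture_forestry", "mining",
                      "urbanization", "paved_road")

.kp_seasons <- c("dry", "wet", "unknown")
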