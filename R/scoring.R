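#' Equal-interval class cutpoints on an integer range
#'
#' Splits the closed integer range `[vmin, vmax]` into `k` contiguous classes
#' of (near-)equal width. The inclusive upper bound of class i is
#' `floor(vmin + i * (vmax - vmin) / k)`; class 1 starts at `vmin` and class
#' i at one past the previous upper bound, so the classes partition the
#' integer range with no gaps or overlaps. Applied to the observed
#' non-troglobite richness range 17-93 with k = 4 this yields the bins
#' 17-36, 37-55, 56-74, 75-93.
#'
#' @param vmin,vmax Observed integer minimum and maximum (`vmax > vmin`).
#' @param k Number of classes; requires `vmax - vmin >= k - 1` so every class
#'   contains at least one integer.
#' @return An object of class `class_intervals`: list with `k`, `vmin`,
#'   `vmax` and the inclusive `upper` bounds (length `k`, last equals `vmax`).
#' @examples
#' equal_interval_cutpoints(17, 93, 4)$upper  # 36 55 74 93
#' @export
equal_interval_cutpoints <- function(vmin, vmax, k) {
  if (vmax <= vmin) stop("`vmax` must exceed `vmin`")
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer")
  if (vmax - vmin < k - 1) {
    stop(sprintf("cannot split range [%d, %d] into %d non-empty integer classes",
                 vmin, vmax, k))
  }
  upper <- floor(vmin + seq_len(k) * (vmax - vmin) / k)
  structure(list(k = as.integer(k), vmin = as.integer(vmin),
                 vmax = as.integer(vmax), upper = as.integer(upper)),
            class = "class_intervals")
}

#' @export
print.class_intervals <- function(x, ...) {
  lower <- c(x$vmin, x$upper[-x$k] + 1L)
  cat(sprintf("%d equal-interval classes on [%d, %d]:\n", x$k, x$vmin, x$vmax))
  cat(paste(sprintf("  [%d, %d]", lower, x$upper), collapse = "\n"), "\n")
  invisible(x)
}

#' Attribute categorization rules
#'
#' Maps each raw attribute to one of the categories None, Low, Average,
#' High, Extreme. `categorize_nts()` uses data-driven equal-interval bins on
#' the observed richness range; the other three use fixed integer rules:
#' troglobite richness 0 -> None, 1-2 -> Low, 3-4 -> Average,
#' 5-(extreme_min - 1) -> High, >= extreme_min -> Extreme; stenoendemic count
#' 0 -> Low (or None under the `"zero"` policy), 1 -> Average, 2 -> High,
#' >= 3 -> Extreme; vulnerability 0 -> None, 1 -> Low, 2 -> Average,
#' 3 -> High, 4-5 -> Extreme.
#'
#' @param x Integer attribute value(s); vectorized.
#' @param intervals A `class_intervals` object built from the dataset's
#'   observed non-troglobite richness range (see
#'   [equal_interval_cutpoints()]); values outside the range are an error.
#' @return Character vector of categories.
#' @rdname categorize
#' @export
categorize_nts <- function(x, intervals) {
  stopifnot(inherits(intervals, "class_intervals"))
  if (intervals$k != 4L) stop("nTS categorization expects 4 classes")
  if (any(x < intervals$vmin | x > intervals$vmax)) {
    stop(sprintf("nTS value outside fitted range [%d, %d]; rebuild intervals",
                 intervals$vmin, intervals$vmax))
  }
  idx <- vapply(x, function(v) which(v <= intervals$upper)[1L], integer(1))
  c("Low", "Average", "High", "Extreme")[idx]
}

#' @param extreme_min Troglobite richness threshold for Extreme (default 7).
#' @rdname categorize
#' @export
categorize_tbs <- function(x, extreme_min = 7) {
  if (any(x < 0)) stop("troglobite richness cannot be negative")
  ifelse(x == 0, "None",
  ifelse(x <= 2, "Low",
  ifelse(x <= 4, "Average",
  ifelse(x < extreme_min, "High", "Extreme"))))
}

#' @param policy Policy for a stenoendemic count of zero: `"table_literal"`
#'   (zero maps to Low) or `"zero"` (zero maps to None, scoring 0).
#' @rdname categorize
#' @export
categorize_end <- function(x, policy = c("table_literal", "zero")) {
  policy <- match.arg(policy)
  if (any(x < 0)) stop("stenoendemic count cannot be negative")
  zero_cat <- if (policy == "table_literal") "Low" else "None"
  ifelse(x == 0, zero_cat,
  ifelse(x == 1, "Average",
  ifelse(x == 2, "High", "Extreme")))
}

#' @rdname categorize
#' @export
categorize_vul <- function(x) {
  if (any(x < 0 | x > 5)) stop("vulnerability count must be in [0, 5]")
  ifelse(x == 0, "None",
  ifelse(x == 1, "Low",
  ifelse(x == 2, "Average",
  ifelse(x == 3, "High", "Extreme"))))
}

#' Score of a category
#'
#' @param category Character vector of categories (None/Low/Average/High/
#'   Extreme).
#' @param weights Named category-to-score map; None always scores 0.
#' @return Numeric score vector.
#' @examples
#' weight_of(c("None", "Low", "Extreme"))
#' @export
weight_of <- function(category,
                      weights = c(Low = 100, Average = 250,
                                  High = 500, Extreme = 1000)) {
  full <- c(None = 0, weights[c("Low", "Average", "High", "Extreme")])
  names(full) <- c("None", "Low", "Average", "High", "Extreme")
  bad <- setdiff(unique(category), names(full))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  unname(full[category])
}

#' Categorize and score all caves
#'
#' Applies the four categorization rules and the category weights to a raw
#' attribute table, yielding per-cave scores and their total. Equal-interval
#' bins for non-troglobite richness are recomputed from the dataset's
#' observed range unless `intervals` is supplied.
#'
#' @param attrs Attribute table from [cave_attributes()] (columns `cave_id,
#'   nTS, TbS, EnD, VuL`).
#' @param config A [study_config()] object.
#' @param intervals Optional pre-built `class_intervals` for nTS.
#' @return A data.frame with the raw attributes, a category and score column
#'   per attribute (`nTS_cat`, `nTS_score`, ...), and `total`.
#' @export
score_caves <- function(attrs, config = study_config(), intervals = NULL) {
  stopifnot(all(c("cave_id", "nTS", "TbS", "EnD", "VuL") %in% names(attrs)))
  if (is.null(intervals)) {
    intervals <- equal_interval_cutpoints(min(attrs$nTS), max(attrs$nTS), 4L)
  }
  out <- attrs
  out$nTS_cat <- categorize_nts(attrs$nTS, intervals)
  out$TbS_cat <- categorize_tbs(attrs$TbS, config$tbs_extreme_min)
  out$EnD_cat <- categorize_end(attrs$EnD, config$end_zero_policy)
  out$VuL_cat <- categorize_vul(attrs$VuL)
  out$nTS_score <- weight_of(out$nTS_cat, config$weights)
  out$TbS_score <- weight_of(out$TbS_cat, config$weights)
  out$EnD_score <- weight_of(out$EnD_cat, config$weights)
  out$VuL_score <- weight_of(out$VuL_cat, config$weights)
  out$total <- out$nTS_score + out$TbS_score + out$EnD_score + out$VuL_score
  attr(out, "intervals") <- intervals
  out
}
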