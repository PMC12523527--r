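#' Exact Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification: partitions the sorted values into `k`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations (SSD), by dynamic programming over prefix sums (Fisher's exact
#' algorithm, of which the popular Jenks method is a heuristic). When several
#' partitions attain the minimal SSD, the lexicographically smallest vector
#' of break positions (in sorted order) is returned, making the result
#' deterministic.
#'
#' @param values Numeric vector; must contain at least `k` distinct values.
#' @param k Number of classes.
#' @return An object of class `jenks_breaks`: list with `k`, `breaks` (the
#'   inclusive upper value of each class, ascending; last is `max(values)`),
#'   `ssd` (the minimal total within-class SSD), and `sizes` (class sizes of
#'   the optimal partition of the sorted values).
#' @examples
#' jenks_breaks(c(1, 2, 3, 100, 101, 102), 2)$breaks  # 3 102
#' @export
jenks_breaks <- function(values, k) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain NA")
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer")
  n_distinct <- length(unique(values))
  if (n_distinct < k) {
    stop(sprintf("need at least k=%d distinct values, got %d", k, n_distinct))
  }
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # within-class SSD of x[a..b], O(1) via prefix sums
  ssq <- function(a, b) {
    s <- cs[b + 1L] - cs[a]
    q <- cs2[b + 1L] - cs2[a]
    max(q - s * s / (b - a + 1L), 0)
  }
  if (k == 1L) {
    return(structure(list(k = 1L, breaks = x[n], ssd = ssq(1L, n), sizes = n),
                     class = "jenks_breaks"))
  }
  # suffix DP: S[j, i] = minimal SSD of partitioning x[i..n] into j classes.
  # A forward greedy reconstruction over suffix costs yields the
  # lexicographically smallest optimal break positions.
  S <- matrix(Inf, nrow = k, ncol = n + 1L)
  for (i in 1:n) S[1L, i] <- ssq(i, n)
  if (k >= 2L) {
    for (j in 2:k) {
      # x[i..n] into j classes needs at least j elements
      for (i in 1:(n - j + 1L)) {
        ends <- i:(n - j + 1L)  # last index of the first class
        costs <- vapply(ends, function(e) ssq(i, e), numeric(1)) +
                 S[j - 1L, ends + 1L]
        S[j, i] <- min(costs)
      }
    }
  }
  opt <- S[k, 1L]
  tol <- 1e-9 * max(1, abs(opt))
  pos <- integer(k)  # last sorted index of each class
  start <- 1L
  for (j in 1:(k - 1L)) {
    remaining <- k - j
    ends <- start:(n - remaining)
    prefix <- if (j == 1L) 0 else sum(vapply(seq_len(j - 1L), function(m) {
      a <- if (m == 1L) 1L else pos[m - 1L] + 1L
      ssq(a, pos[m])
    }, numeric(1)))
    for (e in ends) {
      if (prefix + ssq(start, e) + S[remaining, e + 1L] <= opt + tol) {
        pos[j] <- e
        break
      }
    }
    start <- pos[j] + 1L
  }
  pos[k] <- n
  sizes <- diff(c(0L, pos))
  structure(list(k = as.integer(k), breaks = x[pos], ssd = opt,
                 sizes = as.integer(sizes)),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("Fisher-Jenks natural breaks: k=%d, within-class SSD=%g\n",
              x$k, x$ssd))
  cat("  class upper bounds:", paste(signif(x$breaks, 7), collapse = ", "), "\n")
  invisible(x)
}

#' Classify values against natural breaks
#'
#' Assigns each value the lowest class whose upper bound is >= the value, so
#' equal values always share a class.
#'
#' @param values Numeric vector.
#' @param breaks A `jenks_breaks` object (or ascending numeric upper bounds).
#' @return Integer class indices in `1..k`.
#' @export
classify_values <- function(values, breaks) {
  ub <- if (inherits(breaks, "jenks_breaks")) breaks$breaks else breaks
  idx <- vapply(values, function(v) {
    w <- which(v <= ub)
    if (!length(w)) length(ub) else w[1L]
  }, integer(1))
  as.integer(idx)
}

#' Priority classification of occupied grid cells
#'
#' Runs the natural-breaks classifier on the composite conservation values of
#' occupied cells and labels the classes in ascending value order. With the
#' default `k = 4` the labels are `low`, `medium`, `high`, `extreme`.
#'
#' @param pic Named numeric vector of composite values per occupied cell
#'   ([composite_map()]).
#' @param k Number of classes (default 4).
#' @return A named character vector of class labels, same names as `pic`.
#' @export
classify_priority <- function(pic, k = 4) {
  br <- jenks_breaks(pic, k)
  labels <- .kp_priority_labels(k)
  stats::setNames(labels[classify_values(pic, br)], names(pic))
}

.kp_priority_labels <- function(k) {
  if (k == 4L) return(c("low", "medium", "high", "extreme"))
  paste0("class", seq_len(k))
}
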