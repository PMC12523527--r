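#' Build a rectangular analysis grid
#'
#' Tiles the bounding box exactly with `ncols x nrows` cells. Cell (i, j),
#' 0-based from the lower-left corner, spans the half-open rectangle
#' `[xmin + i*w, xmin + (i+1)*w) x [ymin + j*h, ymin + (j+1)*h)`; the outer
#' edge of the last column/row is closed so points on the bbox boundary are
#' always assigned.
#'
#' @param bbox Numeric `c(xmin, ymin, xmax, ymax)` in meters.
#' @param ncols,nrows Positive integer grid dimensions.
#' @return An object of class `karst_grid`.
#' @examples
#' g <- build_grid(c(0, 0, 40000, 30000), 40, 30)
#' g$cell_w * g$cell_h  # 1e6 m^2 = 1 km^2 per cell
#' @export
build_grid <- function(bbox, ncols, nrows) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("degenerate bbox: need xmax > xmin and ymax > ymin")
  }
  if (ncols < 1 || nrows < 1 || ncols != round(ncols) || nrows != round(nrows)) {
    stop("`ncols` and `nrows` must be positive integers")
  }
  structure(
    list(bbox = bbox, ncols = as.integer(ncols), nrows = as.integer(nrows),
         cell_w = (bbox[3] - bbox[1]) / ncols,
         cell_h = (bbox[4] - bbox[2]) / nrows),
    class = "karst_grid"
  )
}

#' @export
print.karst_grid <- function(x, ...) {
  cat(sprintf("karst_grid: %d x %d cells of %g x %g m over [%g, %g] x [%g, %g]\n",
              x$ncols, x$nrows, x$cell_w, x$cell_h,
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Assign points to grid cells
#'
#' @param grid A `karst_grid`.
#' @param x,y Point coordinates in meters.
#' @return A data.frame with 0-based `col`, `row` and a `cell` key
#'   (`"col:row"`). Points outside the bbox are an error.
#' @keywords internal
cell_of <- function(grid, x, y) {
  out <- x < grid$bbox[1] | x > grid$bbox[3] |
         y < grid$bbox[2] | y > grid$bbox[4]
  if (any(out)) stop("point outside grid bbox at index ", which(out)[1])
  col <- pmin(floor((x - grid$bbox[1]) / grid$cell_w), grid$ncols - 1L)
  row <- pmin(floor((y - grid$bbox[2]) / grid$cell_h), grid$nrows - 1L)
  data.frame(col = as.integer(col), row = as.integer(row),
             cell = paste(as.integer(col), as.integer(row), sep = ":"),
             stringsAsFactors = FALSE)
}

#' Map caves to grid cells
#'
#' Each cave is assigned to exactly one cell by the half-open cell
#' convention of [build_grid()].
#'
#' @param grid A `karst_grid`.
#' @param caves Cave table ([read_caves()]).
#' @return A data.frame `cave_id, col, row, cell`.
#' @export
assign_caves <- function(grid, caves) {
  inside <- caves$x >= grid$bbox[1] & caves$x <= grid$bbox[3] &
            caves$y >= grid$bbox[2] & caves$y <= grid$bbox[4]
  if (!all(inside)) {
    stop("cave outside grid bbox: ",
         paste(caves$cave_id[!inside], collapse = ", "))
  }
  cells <- cell_of(grid, caves$x, caves$y)
  cbind(data.frame(cave_id = caves$cave_id, stringsAsFactors = FALSE), cells)
}

#' Aggregate one attribute score layer onto the grid
#'
#' Implements the map-algebra overlay rule: where several caves fall in the
#' same cell, the cell takes the highest score of that attribute among them.
#' Unoccupied cells are absent from the result.
#'
#' @param scores Scored cave table ([score_caves()]).
#' @param mapping Cave-to-cell mapping ([assign_caves()]).
#' @param attribute One of `"nTS"`, `"TbS"`, `"EnD"`, `"VuL"`.
#' @return A named numeric vector: names are `"col:row"` cell keys, values
#'   the per-cell maximum score.
#' @export
aggregate_layer <- function(scores, mapping, attribute = c("nTS", "TbS", "EnD", "VuL")) {
  attribute <- match.arg(attribute)
  col <- paste0(attribute, "_score")
  missing <- setdiff(scores$cave_id, mapping$cave_id)
  if (length(missing)) {
    stop("scored caves not present in cell mapping: ",
         paste(missing, collapse = ", "))
  }
  cell <- mapping$cell[match(scores$cave_id, mapping$cave_id)]
  vapply(split(scores[[col]], cell), max, numeric(1))
}

#' Sum attribute layers into the composite conservation value
#'
#' The composite priority-for-conservation value of a cell is the sum of its
#' four per-attribute maximum scores.
#'
#' @param layers A list of cell-to-score vectors from [aggregate_layer()];
#'   all must cover the same occupied-cell set.
#' @return A named numeric vector of composite values per occupied cell.
#' @export
composite_map <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  keys <- names(layers[[1]])
  for (l in layers[-1]) {
    if (!identical(sort(names(l)), sort(keys))) {
      stop("attribute layers cover different occupied-cell sets")
    }
  }
  out <- Reduce(`+`, lapply(layers, function(l) l[keys]))
  stats::setNames(as.numeric(out), keys)
}
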