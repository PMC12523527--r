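#' Prioritize caves for conservation
#'
#' Runs the complete prioritization on validated input tables: per-cave raw
#' attributes (non-troglobite richness, troglobite richness, stenoendemic
#' count, vulnerability within the buffer), category weights, cave-to-cell
#' assignment, per-attribute maximum aggregation, map-algebra summation into
#' a composite conservation value per occupied cell, natural-breaks priority
#' classification, and a jackknife survey-completeness summary for the
#' troglobiont assemblage.
#'
#' @param caves Cave table ([read_caves()] layout).
#' @param occurrences Occurrence table ([read_occurrences()] layout).
#' @param impacts Impact site table ([read_impacts()] layout).
#' @param config A [study_config()].
#' @return An object of class `karst_priority` with components `caves`,
#'   `attributes`, `scores`, `intervals`, `grid`, `mapping`, `cells` (one row
#'   per occupied cell: `col, row, cell, n_caves, nTS_score, TbS_score,
#'   EnD_score, VuL_score, PiC, class`), `richness` (completeness block) and
#'   `config`.
#' @examples
#' sim <- simulate_karst(karst_sim_params(n_caves = 40), seed = 3)
#' fit <- prioritize(sim$caves, sim$occurrences, sim$impacts)
#' fit
#' @export
prioritize <- function(caves, occurrences, impacts, config = study_config()) {
  attrs <- cave_attributes(caves, occurrences, impacts,
                           radius_m = config$buffer_radius_m)
  scores <- score_caves(attrs, config)
  grid <- build_grid(config$bbox, config$ncols, config$nrows)
  mapping <- assign_caves(grid, caves)
  layers <- lapply(c("nTS", "TbS", "EnD", "VuL"), function(a) {
    aggregate_layer(scores, mapping, a)
  })
  names(layers) <- c("nTS", "TbS", "EnD", "VuL")
  pic <- composite_map(layers)
  classes <- classify_priority(pic, config$n_classes)

  keys <- names(pic)
  split_keys <- strsplit(keys, ":", fixed = TRUE)
  cells <- data.frame(
    col = vapply(split_keys, function(z) as.integer(z[1]), integer(1)),
    row = vapply(split_keys, function(z) as.integer(z[2]), integer(1)),
    cell = keys,
    n_caves = as.integer(table(mapping$cell)[keys]),
    nTS_score = as.numeric(layers$nTS[keys]),
    TbS_score = as.numeric(layers$TbS[keys]),
    EnD_score = as.numeric(layers$EnD[keys]),
    VuL_score = as.numeric(layers$VuL[keys]),
    PiC = as.numeric(pic[keys]),
    class = unname(classes[keys]),
    stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$col, cells$row), , drop = FALSE]
  rownames(cells) <- NULL

  structure(
    list(caves = caves, attributes = attrs, scores = scores,
         intervals = attr(scores, "intervals"),
         grid = grid, mapping = mapping, cells = cells,
         richness = richness_summary(occurrences, n_units = nrow(caves),
                                     troglobionts_only = TRUE),
         dataset_info = list(n_species = length(unique(occurrences$species_id)),
                             n_impacts = nrow(impacts)),
         config = config),
    class = "karst_priority"
  )
}

#' @export
print.karst_priority <- function(x, ...) {
  cat("Cave conservation prioritization\n")
  cat(sprintf("  %d caves on a %d x %d grid; %d occupied cells\n",
              nrow(x$caves), x$grid$ncols, x$grid$nrows, nrow(x$cells)))
  tab <- table(factor(x$cells$class,
                      levels = .kp_priority_labels(x$config$n_classes)))
  cat("  priority classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  r <- x$richness
  if (!is.na(r$completeness)) {
    cat(sprintf("  troglobiont completeness: %d observed / %.1f estimated = %.1f%%\n",
                r$S_obs, r$S_jack1, 100 * r$completeness))
  }
  invisible(x)
}

#' @export
summary.karst_priority <- function(object, ...) {
  rep <- build_report(object)
  cat(summarize_report(rep))
  invisible(rep)
}

#' Plot a priority map
#'
#' Renders the grid as an image with occupied cells shaded by priority class.
#'
#' @param x A `karst_priority` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.karst_priority <- function(x, ...) {
  g <- x$grid
  labels <- .kp_priority_labels(x$config$n_classes)
  z <- matrix(NA_integer_, nrow = g$ncols, ncol = g$nrows)
  z[cbind(x$cells$col + 1L, x$cells$row + 1L)] <-
    match(x$cells$class, labels)
  cols <- grDevices::hcl.colors(length(labels), "YlOrRd", rev = TRUE)
  graphics::image(
    x = g$bbox[1] + (0:g$ncols) * g$cell_w,
    y = g$bbox[2] + (0:g$nrows) * g$cell_h,
    z = z, zlim = c(1, length(labels)), col = cols,
    xlab = "x (m)", ylab = "y (m)",
    main = "Cave conservation priority", useRaster = FALSE, ...)
  graphics::legend("topright", legend = labels, fill = cols, bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Structured run report
#'
#' Collects the dataset summary, per-attribute category counts, occupied-cell
#' count, priority class counts and shares, and the completeness block into a
#' plain list suitable for JSON serialization.
#'
#' @param fit A `karst_priority` object.
#' @return A list (class `karst_report`).
#' @export
build_report <- function(fit) {
  stopifnot(inherits(fit, "karst_priority"))
  s <- fit$scores
  cats <- .kp_categories
  cat_counts <- lapply(c("nTS_cat", "TbS_cat", "EnD_cat", "VuL_cat"),
                       function(cc) as.list(table(factor(s[[cc]], levels = cats))))
  names(cat_counts) <- c("nTS", "TbS", "EnD", "VuL")
  labels <- .kp_priority_labels(fit$config$n_classes)
  ptab <- table(factor(fit$cells$class, levels = labels))
  occupied <- nrow(fit$cells)
  report <- list(
    dataset = list(n_caves = nrow(fit$caves),
                   n_species = fit$dataset_info$n_species,
                   n_impacts = fit$dataset_info$n_impacts,
                   n_occupied_cells = occupied,
                   n_grid_cells = fit$grid$ncols * fit$grid$nrows),
    category_counts = cat_counts,
    priority = list(counts = as.list(ptab),
                    shares = as.list(as.numeric(ptab) / occupied)),
    completeness = fit$richness,
    config = list(bbox = fit$config$bbox, ncols = fit$config$ncols,
                  nrows = fit$config$nrows,
                  buffer_radius_m = fit$config$buffer_radius_m,
                  n_classes = fit$config$n_classes,
                  weights = as.list(fit$config$weights),
                  end_zero_policy = fit$config$end_zero_policy,
                  tbs_extreme_min = fit$config$tbs_extreme_min,
                  seed = fit$config$seed)
  )
  names(report$priority$shares) <- names(ptab)
  class(report) <- c("karst_report", "list")
  report
}

#' Human-readable report text
#'
#' @param report A `karst_report` from [build_report()].
#' @return A single character string (printable with `cat()`).
#' @export
summarize_report <- function(report) {
  lines <- character(0)
  d <- report$dataset
  lines <- c(lines, sprintf("Caves: %d; grid cells: %d; occupied cells: %d",
                            d$n_caves, d$n_grid_cells, d$n_occupied_cells))
  for (a in names(report$category_counts)) {
    cc <- report$category_counts[[a]]
    lines <- c(lines, sprintf("%s categories: %s", a,
                              paste(names(cc), unlist(cc), sep = "=",
                                    collapse = ", ")))
  }
  if (d$n_occupied_cells == 0) {
    lines <- c(lines, "Priority classes: no occupied cells")
  } else {
    pc <- report$priority$counts
    sh <- report$priority$shares
    lines <- c(lines, sprintf(
      "Priority classes: %s",
      paste(sprintf("%s=%d (%d%%)", names(pc), unlist(pc),
                    round(100 * unlist(sh))), collapse = ", ")))
  }
  r <- report$completeness
  if (!is.null(r) && !is.na(r$completeness)) {
    lines <- c(lines, sprintf(
      "Troglobiont completeness: S_obs=%d, Q1=%d, n=%d, S_jack1=%.1f (%.1f%%)",
      r$S_obs, r$Q1, r$n, r$S_jack1, 100 * r$completeness))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Export the priority grid as GeoJSON and CSV
#'
#' Writes one polygon Feature per grid cell with properties `col`, `row`,
#' `occupied`, the four per-attribute scores, `PiC` and `class` (unoccupied
#' cells carry `null` scores and class `"unoccupied"`), plus a CSV twin of
#' the same table.
#'
#' @param fit A `karst_priority` object.
#' @param geojson_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the full per-cell data.frame (all cells, occupied or
#'   not).
#' @export
export_priority <- function(fit, geojson_path = NULL, csv_path = NULL) {
  stopifnot(inherits(fit, "karst_priority"))
  g <- fit$grid
  all_cells <- expand.grid(col = 0:(g$ncols - 1L), row = 0:(g$nrows - 1L))
  all_cells$cell <- paste(all_cells$col, all_cells$row, sep = ":")
  m <- match(all_cells$cell, fit$cells$cell)
  all_cells$occupied <- !is.na(m)
  for (cc in c("nTS_score", "TbS_score", "EnD_score", "VuL_score", "PiC")) {
    all_cells[[cc]] <- fit$cells[[cc]][m]
  }
  all_cells$class <- ifelse(all_cells$occupied, fit$cells$class[m], "unoccupied")

  if (!is.null(csv_path)) {
    .kp_write_csv(all_cells[, c("col", "row", "occupied", "nTS_score",
                                "TbS_score", "EnD_score", "VuL_score",
                                "PiC", "class")], csv_path)
  }
  if (!is.null(geojson_path)) {
    features <- lapply(seq_len(nrow(all_cells)), function(i) {
      col <- all_cells$col[i]; row <- all_cells$row[i]
      x0 <- g$bbox[1] + col * g$cell_w; x1 <- x0 + g$cell_w
      y0 <- g$bbox[2] + row * g$cell_h; y1 <- y0 + g$cell_h
      ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      props <- list(col = col, row = row, occupied = all_cells$occupied[i],
                    nTS_score = all_cells$nTS_score[i],
                    TbS_score = all_cells$TbS_score[i],
                    EnD_score = all_cells$EnD_score[i],
                    VuL_score = all_cells$VuL_score[i],
                    PiC = all_cells$PiC[i],
                    class = all_cells$class[i])
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = props)
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(all_cells)
}

#' Run the pipeline end to end and write all artifacts
#'
#' Loads (or simulates) the three input tables, runs [prioritize()] and
#' writes `attributes.csv`, `scores.csv`, `cells.csv`, `priority.geojson`
#' and `report.json` into `out_dir`. Reruns with identical inputs and seed
#' produce identical artifacts. Any stage failure aborts with the stage name
#' and removes partial outputs.
#'
#' @param caves,occurrences,impacts Paths to input CSVs, or `NULL` to
#'   simulate.
#' @param config A [study_config()].
#' @param simulate_seed Seed for the generator when inputs are `NULL`.
#' @param sim_params Generator parameters when simulating.
#' @param out_dir Output directory (created if absent).
#' @return The `karst_priority` fit, invisibly.
#' @export
run_pipeline <- function(caves = NULL, occurrences = NULL, impacts = NULL,
                         config = study_config(), simulate_seed = NULL,
                         sim_params = karst_sim_params(), out_dir) {
  artifacts <- file.path(out_dir, c("attributes.csv", "scores.csv",
                                    "cells.csv", "priority.geojson",
                                    "report.json"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(artifacts)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(caves)) {
    seed <- if (!is.null(simulate_seed)) simulate_seed else config$seed
    if (is.null(seed)) stop("pipeline stage 'load' failed: no inputs and no seed to simulate with")
    sim <- stage("simulate", simulate_karst(sim_params, seed = seed))
    caves_df <- sim$caves; occ_df <- sim$occurrences; imp_df <- sim$impacts
  } else {
    caves_df <- stage("load", read_caves(caves))
    occ_df <- stage("load", read_occurrences(occurrences))
    imp_df <- stage("load", read_impacts(impacts))
  }
  fit <- stage("prioritize", prioritize(caves_df, occ_df, imp_df, config))
  stage("export", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .kp_write_csv(fit$attributes, artifacts[1])
    .kp_write_csv(fit$scores, artifacts[2])
    export_priority(fit, geojson_path = artifacts[4], csv_path = artifacts[3])
    jsonlite::write_json(unclass(build_report(fit)), artifacts[5],
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  })
  invisible(fit)
}
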