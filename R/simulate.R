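#' Parameters for the synthetic karst generator
#'
#' Defaults emulate an intensively surveyed tropical karst landscape:
#' 105 caves clustered over a 1200 km^2 extent, per-cave non-troglobite
#' richness around 49.2 (SD 17.1, clipped to the 17-93 range), a pool of 32
#' troglobiont species of which 65.6% are single-cave endemics, lognormal
#' cave lengths with mean 102.7 m, and five anthropogenic impact types mixed
#' 54/18/15/7/6 (agriculture-forestry, pasture, mining, urbanization, paved
#' roads) with every cave receiving at least one impact site within the
#' 250 m buffer.
#'
#' @param n_caves Number of caves.
#' @param bbox Study extent in meters.
#' @param cluster_fraction Fraction of caves placed around cluster centers
#'   (karst caves aggregate along limestone outcrops); the rest are uniform.
#' @param n_clusters Number of cluster centers.
#' @param cluster_sd_m Gaussian scatter (m) of clustered caves around their
#'   center.
#' @param length_mean_m Target mean cave length; lengths are lognormal.
#' @param length_sdlog Lognormal sigma of cave length.
#' @param nts_mean,nts_sd,nts_clip Normal mean/SD and clipping range for
#'   per-cave non-troglobite richness.
#' @param n_nontrog_pool Size of the regional non-troglobite species pool.
#' @param n_troglobiont_pool Size of the troglobiont species pool.
#' @param singleton_fraction Fraction of troglobiont species restricted to a
#'   single cave (stenoendemics).
#' @param occupancy_max Maximum number of caves a non-endemic troglobiont
#'   occupies; occupancy is drawn from a truncated power law on
#'   `2..occupancy_max`.
#' @param occupancy_alpha Power-law exponent of the occupancy distribution.
#' @param impact_mix Named probabilities over the five impact types.
#' @param impacts_per_cave_lambda Poisson rate: each cave gets
#'   `1 + rpois(lambda)` impact sites inside its buffer.
#' @param n_background_impacts Impact sites scattered uniformly over the
#'   extent, independent of caves.
#' @param buffer_radius_m Buffer radius used when planting per-cave impacts.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `karst_sim_params`.
#' @export
karst_sim_params <- function(n_caves = 105,
                             bbox = c(0, 0, 40000, 30000),
                             cluster_fraction = 0.7,
                             n_clusters = 18,
                             cluster_sd_m = 700,
                             length_mean_m = 102.7,
                             length_sdlog = 0.9,
                             nts_mean = 49.2,
                             nts_sd = 17.1,
                             nts_clip = c(17, 93),
                             n_nontrog_pool = 1281,
                             n_troglobiont_pool = 32,
                             singleton_fraction = 0.656,
                             occupancy_max = 10,
                             occupancy_alpha = 1.5,
                             impact_mix = c(agriculture_forestry = 0.54,
                                            pasture = 0.18,
                                            mining = 0.15,
                                            urbanization = 0.07,
                                            paved_road = 0.06),
                             impacts_per_cave_lambda = 1,
                             n_background_impacts = 60,
                             buffer_radius_m = 250,
                             seed = 1L) {
  if (n_caves < 1) stop("`n_caves` must be >= 1")
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    stop("`cluster_fraction` must be in [0, 1]")
  }
  if (singleton_fraction < 0 || singleton_fraction > 1) {
    stop("`singleton_fraction` must be in [0, 1]")
  }
  if (abs(sum(impact_mix) - 1) > 1e-8) stop("`impact_mix` must sum to 1")
  if (!all(names(impact_mix) %in% .kp_impact_types)) {
    stop("`impact_mix` names must be impact types: ",
         paste(.kp_impact_types, collapse = ", "))
  }
  n_singletons <- round(singleton_fraction * n_troglobiont_pool)
  # at most 2 stenoendemics per cave, so we need enough caves to host them
  if (n_singletons > 2 * n_caves) {
    stop("infeasible: more planted stenoendemics than 2 per cave allows")
  }
  structure(as.list(environment()), class = "karst_sim_params")
}

#' Generate a synthetic karst dataset
#'
#' Produces internally consistent cave, occurrence and impact tables with the
#' statistical structure the prioritization pipeline assumes, plus a `truth`
#' record of every planted quantity (per-cave richness, stenoendemic counts,
#' singleton total) so downstream computations can be checked exactly.
#' Identical seeds yield identical datasets.
#'
#' @param params A [karst_sim_params()] object.
#' @param seed Integer seed; overrides `params$seed` if given.
#' @return A list of class `karst_sim` with elements `caves`, `occurrences`,
#'   `impacts` (data frames in the reader layouts), `truth` (list: `nTS`,
#'   `TbS`, `EnD` named per cave, `singleton_total`, `trog_occupancy`,
#'   `hotspot`), and `params`.
#' @examples
#' sim <- simulate_karst(karst_sim_params(n_caves = 20), seed = 7)
#' head(sim$caves)
#' @export
simulate_karst <- function(params = karst_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "karst_sim_params"))
  if (is.null(seed)) seed <- params$seed
  set.seed(as.integer(seed))
  p <- params
  n <- p$n_caves
  bb <- p$bbox

  # --- cave locations: Neyman-Scott-like clustering over the extent
  centers_x <- stats::runif(p$n_clusters, bb[1], bb[3])
  centers_y <- stats::runif(p$n_clusters, bb[2], bb[4])
  clustered <- stats::runif(n) < p$cluster_fraction
  parent <- sample.int(p$n_clusters, n, replace = TRUE)
  x <- ifelse(clustered,
              centers_x[parent] + stats::rnorm(n, 0, p$cluster_sd_m),
              stats::runif(n, bb[1], bb[3]))
  y <- ifelse(clustered,
              centers_y[parent] + stats::rnorm(n, 0, p$cluster_sd_m),
              stats::runif(n, bb[2], bb[4]))
  x <- pmin(pmax(x, bb[1]), bb[3])
  y <- pmin(pmax(y, bb[2]), bb[4])

  ids <- sprintf("C%03d", seq_len(n))
  meanlog <- log(p$length_mean_m) - p$length_sdlog^2 / 2
  length_m <- stats::rlnorm(n, meanlog, p$length_sdlog)
  season <- sample(c("dry", "wet"), n, replace = TRUE, prob = c(49, 54))
  caves <- data.frame(cave_id = ids, name = paste("Cave", ids),
                      x = x, y = y, length_m = length_m, season = season,
                      stringsAsFactors = FALSE)

  # --- non-troglobite occurrences: exact per-cave richness draws
  nts <- pmin(pmax(round(stats::rnorm(n, p$nts_mean, p$nts_sd)),
                   p$nts_clip[1]), p$nts_clip[2])
  pool <- sprintf("sp%04d", seq_len(p$n_nontrog_pool))
  pool_w <- stats::rlnorm(p$n_nontrog_pool, 0, 1.2)
  nontrog <- do.call(rbind, lapply(seq_len(n), function(i) {
    sp <- sample(pool, nts[i], prob = pool_w)
    data.frame(cave_id = ids[i], species_id = sp, troglobiont = FALSE,
               stringsAsFactors = FALSE)
  }))

  # --- troglobionts: planted singletons (<= 2 per cave) + power-law
  #     occupancy for the rest, placement weighted by cave length
  n_sing <- round(p$singleton_fraction * p$n_troglobiont_pool)
  trog_ids <- sprintf("tb%02d", seq_len(p$n_troglobiont_pool))
  sing_ids <- trog_ids[seq_len(n_sing)]
  multi_ids <- setdiff(trog_ids, sing_ids)
  lw <- caves$length_m
  end_count <- stats::setNames(integer(n), ids)
  occupancy <- vector("list", p$n_troglobiont_pool)
  names(occupancy) <- trog_ids
  for (sp in sing_ids) {
    eligible <- which(end_count < 2L)
    i <- if (length(eligible) == 1L) eligible else {
      sample(eligible, 1L, prob = lw[eligible])
    }
    end_count[i] <- end_count[i] + 1L
    occupancy[[sp]] <- ids[i]
  }
  occ_sizes_support <- 2:p$occupancy_max
  occ_prob <- occ_sizes_support^(-p$occupancy_alpha)
  for (sp in multi_ids) {
    s <- sample(occ_sizes_support, 1L, prob = occ_prob)
    s <- min(s, n)
    occupancy[[sp]] <- ids[sample.int(n, s, prob = lw)]
  }
  trog <- do.call(rbind, lapply(trog_ids, function(sp) {
    data.frame(cave_id = occupancy[[sp]], species_id = sp, troglobiont = TRUE,
               stringsAsFactors = FALSE)
  }))
  occurrences <- rbind(nontrog, trog)
  rownames(occurrences) <- NULL

  tbs_count <- table(factor(trog$cave_id, levels = ids))

  # --- impacts: every cave gets >= 1 site inside its buffer, plus a
  #     background scatter over the extent
  mix <- p$impact_mix[order(match(names(p$impact_mix), .kp_impact_types))]
  per_cave <- 1L + stats::rpois(n, p$impacts_per_cave_lambda)
  near <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- per_cave[i]
    r <- stats::runif(k, 0, p$buffer_radius_m)
    th <- stats::runif(k, 0, 2 * pi)
    data.frame(impact_type = sample(names(mix), k, replace = TRUE, prob = mix),
               x = caves$x[i] + r * cos(th),
               y = caves$y[i] + r * sin(th),
               stringsAsFactors = FALSE)
  }))
  bg <- if (p$n_background_impacts > 0) {
    data.frame(impact_type = sample(names(mix), p$n_background_impacts,
                                    replace = TRUE, prob = mix),
               x = stats::runif(p$n_background_impacts, bb[1], bb[3]),
               y = stats::runif(p$n_background_impacts, bb[2], bb[4]),
               stringsAsFactors = FALSE)
  } else NULL
  impacts <- rbind(near, bg)
  rownames(impacts) <- NULL

  truth <- list(
    nTS = stats::setNames(as.integer(nts), ids),
    TbS = stats::setNames(as.integer(tbs_count), ids),
    EnD = end_count,
    singleton_total = as.integer(n_sing),
    trog_occupancy = occupancy,
    hotspot = NULL
  )
  structure(list(caves = caves, occurrences = occurrences, impacts = impacts,
                 truth = truth, params = params, seed = as.integer(seed)),
            class = "karst_sim")
}

#' @export
print.karst_sim <- function(x, ...) {
  cat(sprintf("Synthetic karst dataset (seed %d): %d caves, %d occurrence rows, %d impact sites\n",
              x$seed, nrow(x$caves), nrow(x$occurrences), nrow(x$impacts)))
  if (!is.null(x$truth$hotspot)) {
    cat(sprintf("  planted hotspot cave %s in cell (%d, %d)\n",
                x$truth$hotspot$cave_id,
                x$truth$hotspot$cell[1], x$truth$hotspot$cell[2]))
  }
  invisible(x)
}

#' Plant a maximal-profile hotspot cave in a chosen grid cell
#'
#' Adds one cave in the center of the given cell with the profile of a
#' top-priority site: non-troglobite richness equal to the dataset maximum,
#' seven troglobiont species of which exactly two are stenoendemic (new,
#' known only from this cave), and four distinct impact types within the
#' buffer. Under default weights the cave scores
#' (Extreme, Extreme, High, Extreme) = 1000 + 1000 + 500 + 1000 = 3500,
#' the maximum attainable when no cave holds three or more stenoendemics, so
#' its cell must fall in the top priority class — the basis for end-to-end
#' recovery tests.
#'
#' @param sim A `karst_sim` dataset.
#' @param cell Integer vector `c(col, row)`, 0-based.
#' @param config A [study_config()] defining the grid.
#' @return The modified `karst_sim`, with `truth$hotspot` set.
#' @export
plant_hotspot <- function(sim, cell, config = study_config()) {
  stopifnot(inherits(sim, "karst_sim"), length(cell) == 2)
  grid <- build_grid(config$bbox, config$ncols, config$nrows)
  col <- as.integer(cell[1]); row <- as.integer(cell[2])
  if (col < 0 || col >= grid$ncols || row < 0 || row >= grid$nrows) {
    stop(sprintf("cell (%d, %d) outside the %d x %d grid",
                 col, row, grid$ncols, grid$nrows))
  }
  cx <- grid$bbox[1] + (col + 0.5) * grid$cell_w
  cy <- grid$bbox[2] + (row + 0.5) * grid$cell_h
  id <- "HOTSPOT"
  while (id %in% sim$caves$cave_id) id <- paste0(id, "X")

  new_cave <- data.frame(cave_id = id, name = "Planted hotspot cave",
                         x = cx, y = cy,
                         length_m = max(sim$caves$length_m) * 1.2,
                         season = "dry", stringsAsFactors = FALSE)

  # non-troglobite richness at the dataset maximum (deterministic choice of
  # species identities; only the count matters for scoring)
  nts_max <- max(sim$truth$nTS)
  nontrog_sp <- sprintf("sp%04d", seq_len(nts_max))
  # two fresh stenoendemics + five widespread troglobionts (>= 2 caves each,
  # so adding this cave cannot change any existing cave's endemic count)
  widespread <- names(sim$truth$trog_occupancy)[
    vapply(sim$truth$trog_occupancy, length, integer(1)) >= 2L]
  if (length(widespread) < 5L) {
    stop("dataset has fewer than 5 non-endemic troglobionts to borrow")
  }
  trog_sp <- c(paste0(id, "_end1"), paste0(id, "_end2"),
               sort(widespread)[1:5])
  new_occ <- rbind(
    data.frame(cave_id = id, species_id = nontrog_sp, troglobiont = FALSE,
               stringsAsFactors = FALSE),
    data.frame(cave_id = id, species_id = trog_sp, troglobiont = TRUE,
               stringsAsFactors = FALSE)
  )
  d <- config$buffer_radius_m * 0.4
  new_imp <- data.frame(
    impact_type = c("pasture", "agriculture_forestry", "mining", "urbanization"),
    x = cx + c(d, -d, 0, 0), y = cy + c(0, 0, d, -d),
    stringsAsFactors = FALSE)

  sim$caves <- rbind(sim$caves, new_cave)
  sim$occurrences <- rbind(sim$occurrences, new_occ)
  sim$impacts <- rbind(sim$impacts, new_imp)
  sim$truth$nTS[id] <- nts_max
  sim$truth$TbS[id] <- 7L
  sim$truth$EnD[id] <- 2L
  sim$truth$singleton_total <- sim$truth$singleton_total + 2L
  for (sp in trog_sp[1:2]) sim$truth$trog_occupancy[[sp]] <- id
  for (sp in trog_sp[3:7]) {
    sim$truth$trog_occupancy[[sp]] <- c(sim$truth$trog_occupancy[[sp]], id)
  }
  sim$truth$hotspot <- list(cave_id = id, cell = c(col, row))
  sim
}

#' Write a synthetic dataset to a directory
#'
#' Writes `caves.csv`, `occurrences.csv`, `impacts.csv` and `truth.json`.
#'
#' @param sim A `karst_sim` dataset.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_karst_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "karst_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_caves(sim$caves, file.path(dir, "caves.csv"))
  write_occurrences(sim$occurrences, file.path(dir, "occurrences.csv"))
  write_impacts(sim$impacts, file.path(dir, "impacts.csv"))
  truth <- sim$truth
  truth$trog_occupancy <- NULL  # bulky; the tables carry the same information
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
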