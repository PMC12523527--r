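test_that("the default grid tiles the extent into 1200 one-km2 cells", {
  g <- build_grid(c(0, 0, 40000, 30000), 40, 30)
  expect_equal(g$ncols * g$nrows, 1200)
  expect_equal(g$cell_w * g$cell_h, 1e6)
  expect_error(build_grid(c(0, 0, 0, 100), 10, 10), "degenerate")
})

test_that("cave-to-cell assignment follows the half-open convention", {
  g <- build_grid(c(0, 0, 4000, 3000), 4, 3)  # 1000 m cells
  caves <- data.frame(cave_id = c("a", "b", "c", "d"),
                      name = "x",
                      x = c(500, 1000, 4000, 0),
                      y = c(500, 0, 3000, 0),
                      length_m = 10, season = "dry",
                      stringsAsFactors = FALSE)
  m <- assign_caves(g, caves)
  expect_equal(m$col, c(0, 1, 3, 0))  # lower edge belongs to the cell,
  expect_equal(m$row, c(0, 0, 2, 0))  # bbox max corner to the last cell
  outside <- caves; outside$x[1] <- -1
  expect_error(assign_caves(g, outside), "a")
})

test_that("all simulated caves map to exactly one cell each", {
  sim <- simulate_karst(karst_sim_params(), seed = 4)
  g <- build_grid(c(0, 0, 40000, 30000), 40, 30)
  m <- assign_caves(g, sim$caves)
  expect_equal(nrow(m), 105)
  expect_equal(anyDuplicated(m$cave_id), 0)
  expect_true(all(m$col >= 0 & m$col < 40 & m$row >= 0 & m$row < 30))
})

test_that("layer aggregation takes the per-cell maximum score", {
  scores <- data.frame(cave_id = c("a", "b", "c"),
                       nTS_score = c(250, 1000, 500),
                       stringsAsFactors = FALSE)
  mapping <- data.frame(cave_id = c("a", "b", "c"),
                        col = c(0, 0, 1), row = c(0, 0, 0),
                        cell = c("0:0", "0:0", "1:0"),
                        stringsAsFactors = FALSE)
  layer <- aggregate_layer(scores, mapping, "nTS")
  expect_equal(layer[["0:0"]], 1000)  # max of {250, 1000}
  expect_equal(layer[["1:0"]], 500)   # single cave keeps its score
  # adding a cave can never lower a cell's value
  more <- rbind(scores, data.frame(cave_id = "d", nTS_score = 100))
  mapping2 <- rbind(mapping, data.frame(cave_id = "d", col = 0, row = 0,
                                        cell = "0:0"))
  expect_true(all(aggregate_layer(more, mapping2, "nTS")[names(layer)] >= layer))
  expect_error(aggregate_layer(scores, mapping[1:2, ], "nTS"), "c")
})

test_that("the composite map sums layers over a shared occupied-cell set", {
  l <- list(nTS = c("0:0" = 1000, "1:0" = 100),
            TbS = c("0:0" = 1000, "1:0" = 0),
            EnD = c("0:0" = 500, "1:0" = 100),
            VuL = c("0:0" = 1000, "1:0" = 100))
  pic <- composite_map(l)
  expect_equal(pic[["0:0"]], 3500)
  expect_equal(pic[["1:0"]], 300)
  zeros <- lapply(l, function(z) z * 0)
  expect_equal(unname(composite_map(zeros)), c(0, 0))
  bad <- l; names(bad$VuL) <- c("0:0", "2:0")
  expect_error(composite_map(bad), "different occupied-cell sets")
})

test_that("per-attribute maxima make the composite an exact identity", {
  sim <- simulate_karst(karst_sim_params(n_caves = 60), seed = 13)
  fit <- prioritize(sim$caves, sim$occurrences, sim$impacts)
  cells <- fit$cells
  expect_equal(cells$PiC,
               cells$nTS_score + cells$TbS_score + cells$EnD_score +
                 cells$VuL_score)
  # a cell's composite dominates any single attribute score of its caves
  sc <- fit$scores
  m <- fit$mapping
  for (i in seq_len(nrow(cells))) {
    in_cell <- m$cave_id[m$cell == cells$cell[i]]
    sub <- sc[sc$cave_id %in% in_cell, ]
    expect_true(cells$PiC[i] >= max(sub$nTS_score, sub$TbS_score,
                                    sub$EnD_score, sub$VuL_score))
  }
  expect_true(all(cells$PiC >= 0 & cells$PiC <= 4000))
  if (max(fit$attributes$EnD) < 3) expect_true(all(cells$PiC <= 3500))
})

test_that("GeoJSON export round-trips every cell with its properties", {
  sim <- simulate_karst(karst_sim_params(n_caves = 30), seed = 21)
  cfg <- study_config(ncols = 10, nrows = 6)
  fit <- prioritize(sim$caves, sim$occurrences, sim$impacts, cfg)
  gj <- tempfile(fileext = ".geojson")
  cs <- tempfile(fileext = ".csv")
  tab <- export_priority(fit, geojson_path = gj, csv_path = cs)
  expect_equal(nrow(tab), 60)

  parsed <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_equal(parsed$type, "FeatureCollection")
  expect_equal(length(parsed$features), 60)
  f1 <- parsed$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  expect_equal(length(f1$geometry$coordinates[[1]]), 5)  # closed ring
  # properties agree with the exported table, including nulls when unoccupied
  for (i in c(1, 15, 60)) {
    p <- parsed$features[[i]]$properties
    expect_equal(p$col, tab$col[i])
    expect_equal(p$row, tab$row[i])
    expect_equal(p$occupied, tab$occupied[i])
    if (tab$occupied[i]) {
      expect_equal(p$PiC, tab$PiC[i])
      expect_equal(p$class, tab$class[i])
    } else {
      expect_null(p$PiC)
      expect_equal(p$class, "unoccupied")
    }
  }
  occ_csv <- read.csv(cs)
  expect_equal(nrow(occ_csv), 60)
  expect_equal(sum(occ_csv$occupied == "TRUE" | occ_csv$occupied == TRUE),
               nrow(fit$cells))
})
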