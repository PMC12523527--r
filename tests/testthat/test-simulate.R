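test_that("identical seeds reproduce the dataset byte for byte", {
  s1 <- simulate_karst(karst_sim_params(), seed = 42)
  s2 <- simulate_karst(karst_sim_params(), seed = 42)
  expect_identical(s1$caves, s2$caves)
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$impacts, s2$impacts)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_karst_sim(s1, d1); write_karst_sim(s2, d2)
  for (f in c("caves.csv", "occurrences.csv", "impacts.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- simulate_karst(karst_sim_params(), seed = 43)
  expect_false(identical(s1$caves, s3$caves))
})

test_that("generated tables satisfy the loader invariants", {
  sim <- simulate_karst(karst_sim_params(), seed = 8)
  key <- paste(sim$occurrences$cave_id, sim$occurrences$species_id)
  expect_equal(anyDuplicated(key), 0)
  flags <- tapply(sim$occurrences$troglobiont, sim$occurrences$species_id,
                  function(z) length(unique(z)))
  expect_true(all(flags == 1))
  expect_equal(anyDuplicated(sim$caves$cave_id), 0)
  expect_true(all(sim$caves$length_m > 0))
  expect_true(all(sim$impacts$impact_type %in%
                    c("pasture", "agriculture_forestry", "mining",
                      "urbanization", "paved_road")))
  bb <- sim$params$bbox
  expect_true(all(sim$caves$x >= bb[1] & sim$caves$x <= bb[3]))
  expect_true(all(sim$caves$y >= bb[2] & sim$caves$y <= bb[4]))
})

test_that("every cave has at least one impact inside its buffer", {
  for (seed in c(1, 6, 12)) {
    sim <- simulate_karst(karst_sim_params(), seed = seed)
    vul <- vapply(seq_len(nrow(sim$caves)), function(i) {
      vulnerability_count(sim$caves$x[i], sim$caves$y[i], sim$impacts, 250)
    }, integer(1))
    expect_true(all(vul >= 1))
  }
})

test_that("computed attributes equal the generator's planted truth", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_karst(karst_sim_params(), seed = seed)
    attrs <- cave_attributes(sim$caves, sim$occurrences, sim$impacts)
    expect_identical(attrs$nTS, unname(sim$truth$nTS[attrs$cave_id]))
    expect_identical(attrs$TbS, unname(sim$truth$TbS[attrs$cave_id]))
    expect_identical(attrs$EnD, unname(sim$truth$EnD[attrs$cave_id]))
  }
})

test_that("planted stenoendemics never exceed two per cave", {
  sim <- simulate_karst(karst_sim_params(), seed = 19)
  expect_true(all(sim$truth$EnD <= 2))
})

test_that("distributional targets are near the configured values", {
  # light check on a handful of seeds; the full replicate calibration runs
  # in the acceptance suite
  means <- singles <- numeric(5)
  for (seed in 1:5) {
    sim <- simulate_karst(karst_sim_params(), seed = seed)
    means[seed] <- mean(sim$truth$nTS)
    singles[seed] <- sim$truth$singleton_total / sim$params$n_troglobiont_pool
  }
  expect_lt(abs(mean(means) - 49.2), 4)
  expect_lt(abs(mean(singles) - 0.656), 0.1)
  sim <- simulate_karst(karst_sim_params(), seed = 2)
  expect_lt(abs(mean(sim$caves$length_m) - 102.7), 60)
  expect_true(all(sim$truth$nTS >= 17 & sim$truth$nTS <= 93))
})

test_that("infeasible generator parameters are rejected up front", {
  expect_error(karst_sim_params(n_caves = 5, n_troglobiont_pool = 32,
                                singleton_fraction = 1), "infeasible")
  expect_error(karst_sim_params(impact_mix = c(mining = 0.5, pasture = 0.4)),
               "sum to 1")
  expect_error(karst_sim_params(cluster_fraction = 1.5), "cluster_fraction")
})

test_that("a planted hotspot carries the maximal-profile attribute vector", {
  sim <- simulate_karst(karst_sim_params(), seed = 14)
  hs <- plant_hotspot(sim, c(5, 5))
  id <- hs$truth$hotspot$cave_id
  attrs <- cave_attributes(hs$caves, hs$occurrences, hs$impacts)
  row <- attrs[attrs$cave_id == id, ]
  expect_equal(row$nTS, max(attrs$nTS))
  expect_equal(row$TbS, 7L)
  expect_equal(row$EnD, 2L)
  expect_gte(row$VuL, 4)
  sc <- score_caves(attrs)
  srow <- sc[sc$cave_id == id, ]
  expect_equal(unlist(srow[c("nTS_score", "TbS_score", "EnD_score",
                             "VuL_score")], use.names = FALSE),
               c(1000, 1000, 500, 1000))
  expect_equal(srow$total, 3500)
  # other caves' planted truth is untouched
  expect_identical(hs$truth$nTS[sim$caves$cave_id], sim$truth$nTS)
  expect_identical(hs$truth$EnD[sim$caves$cave_id], sim$truth$EnD)
  expect_error(plant_hotspot(sim, c(40, 5)), "outside")
  expect_error(plant_hotspot(sim, c(0, 30)), "outside")
})
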