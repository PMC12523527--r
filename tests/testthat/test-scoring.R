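test_that("equal-interval cutpoints reproduce known bin bounds", {
  expect_equal(equal_interval_cutpoints(17, 93, 4)$upper, c(36L, 55L, 74L, 93L))
  expect_equal(equal_interval_cutpoints(0, 100, 4)$upper, c(25L, 50L, 75L, 100L))
  expect_equal(equal_interval_cutpoints(1, 2, 2)$upper, c(1L, 2L))
  expect_error(equal_interval_cutpoints(5, 5, 2), "exceed")
  expect_error(equal_interval_cutpoints(1, 3, 4), "non-empty")
})

test_that("equal-interval classes partition the integer range exactly", {
  set.seed(7)
  for (rep in 1:60) {
    vmin <- sample(-50:100, 1)
    k <- sample(1:6, 1)
    vmax <- vmin + sample(max(k - 1, 1):200, 1)
    ci <- equal_interval_cutpoints(vmin, vmax, k)
    lower <- c(ci$vmin, ci$upper[-k] + 1L)
    expect_equal(ci$upper[k], vmax)
    expect_true(all(lower <= ci$upper))          # every class non-empty
    covered <- unlist(mapply(seq, lower, ci$upper, SIMPLIFY = FALSE))
    expect_equal(covered, seq(vmin, vmax))       # no gaps, no overlaps
  }
})

test_that("non-troglobite richness categorization follows the fitted bins", {
  ci <- equal_interval_cutpoints(17, 93, 4)
  expect_equal(categorize_nts(49, ci), "Average")
  expect_equal(categorize_nts(93, ci), "Extreme")
  expect_equal(categorize_nts(17, ci), "Low")
  expect_equal(categorize_nts(c(36, 37, 55, 56, 74, 75), ci),
               c("Low", "Average", "Average", "High", "High", "Extreme"))
  expect_error(categorize_nts(94, ci), "outside")
  expect_error(categorize_nts(16, ci), "outside")
})

test_that("troglobite richness categories follow the fixed integer bins", {
  expect_equal(categorize_tbs(c(0, 1, 2, 3, 4, 5, 6, 7, 14)),
               c("None", "Low", "Low", "Average", "Average",
                 "High", "High", "Extreme", "Extreme"))
  expect_equal(categorize_tbs(7, extreme_min = 8), "High")
  expect_error(categorize_tbs(-1))
})

test_that("stenoendemic categories honor the zero policy", {
  expect_equal(categorize_end(c(0, 1, 2, 3, 5)),
               c("Low", "Average", "High", "Extreme", "Extreme"))
  expect_equal(categorize_end(0, policy = "zero"), "None")
  expect_equal(categorize_end(1, policy = "zero"), "Average")
})

test_that("vulnerability categories cover 0..5 impact types", {
  expect_equal(categorize_vul(0:5),
               c("None", "Low", "Average", "High", "Extreme", "Extreme"))
  expect_error(categorize_vul(6))
})

test_that("category weights map as configured and reject unknowns", {
  expect_equal(weight_of(c("None", "Low", "Average", "High", "Extreme")),
               c(0, 100, 250, 500, 1000))
  expect_equal(weight_of("High", weights = c(Low = 1, Average = 2,
                                             High = 3, Extreme = 4)), 3)
  expect_error(weight_of("Huge"), "unknown category")
})

test_that("cave scoring composes the four rules", {
  attrs <- data.frame(cave_id = c("top", "bottom"),
                      nTS = c(93, 17), TbS = c(14, 0),
                      EnD = c(2, 0), VuL = c(4, 1),
                      stringsAsFactors = FALSE)
  ci <- equal_interval_cutpoints(17, 93, 4)
  sc <- score_caves(attrs, study_config(), intervals = ci)
  expect_equal(unlist(sc[1, c("nTS_score", "TbS_score", "EnD_score",
                              "VuL_score")], use.names = FALSE),
               c(1000, 1000, 500, 1000))
  expect_equal(sc$total[1], 3500)
  expect_equal(unlist(sc[2, c("nTS_score", "TbS_score", "EnD_score",
                              "VuL_score")], use.names = FALSE),
               c(100, 0, 100, 100))
  expect_equal(sc$total[2], 300)
})

test_that("scores take only the configured values and totals stay in range", {
  sim <- simulate_karst(karst_sim_params(), seed = 9)
  sc <- score_caves(cave_attributes(sim$caves, sim$occurrences, sim$impacts))
  allowed <- c(0, 100, 250, 500, 1000)
  for (col in c("nTS_score", "TbS_score", "EnD_score", "VuL_score")) {
    expect_true(all(sc[[col]] %in% allowed), info = col)
  }
  expect_true(all(sc$total >= 0 & sc$total <= 4000))
})

test_that("categorization is monotone in each raw attribute", {
  rank_of <- function(cat) match(cat, c("None", "Low", "Average", "High", "Extreme"))
  ci <- equal_interval_cutpoints(0, 100, 4)
  expect_true(all(diff(rank_of(categorize_nts(0:100, ci))) >= 0))
  expect_true(all(diff(rank_of(categorize_tbs(0:20))) >= 0))
  expect_true(all(diff(rank_of(categorize_end(0:6))) >= 0))
  expect_true(all(diff(rank_of(categorize_end(0:6, "zero"))) >= 0))
  expect_true(all(diff(rank_of(categorize_vul(0:5))) >= 0))
})
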