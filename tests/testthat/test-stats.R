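test_that("identical groups give t = 0, p = 1, no stars", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  r <- compare_groups(x, x)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$stars, "ns")
  # order within a group is irrelevant
  r2 <- compare_groups(c(1, 2, 3, 4, 5), c(5, 3, 1, 4, 2))
  expect_equal(r2$t_statistic, 0)
  expect_equal(r2$p_value, 1)
})

test_that("star labels follow the P<0.05 / P<0.01 cutoffs exactly", {
  expect_equal(significance_stars(c(0.2, 0.049, 0.05, 0.009, 0.01, NA)),
               c("ns", "*", "ns", "**", "*", NA))
})

test_that("degenerate zero-variance input is flagged, not fabricated", {
  r <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_true(is.na(r$p_value))
  expect_match(r$flags, "degenerate")
  r2 <- compare_groups(c(2, 2, 2), c(3, 3, 3))
  expect_equal(r2$p_value, 0)
  expect_match(r2$flags, "zero_variance")
  expect_error(compare_groups(1, c(1, 2)), ">= 2")
})

test_that("Student and Welch variants both run and agree on balanced data", {
  set.seed(8)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  rs <- compare_groups(a, b, equal_variance = TRUE)
  rw <- compare_groups(a, b, equal_variance = FALSE)
  expect_equal(rs$t_statistic, rw$t_statistic, tolerance = 1e-12)
  expect_gt(rw$p_value, 0); expect_lt(rw$p_value, 1)
})

test_that("type-I error sits at the nominal 5% level", {
  set.seed(101)
  rej <- mean(replicate(1000, {
    compare_groups(rnorm(15), rnorm(15))$p_value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("batch report compares every metric across condition pairs", {
  set.seed(11)
  metrics <- data.frame(cell_id = 1:30,
                        ratio_membrane = c(rnorm(15, 0.3, 0.05),
                                           rnorm(15, 0.6, 0.05)),
                        percent_contact = rnorm(30, 20, 5))
  cond <- data.frame(cell_id = 1:30,
                     condition = rep(c("control", "hemin"), each = 15))
  rep <- batch_report(metrics, cond)
  expect_equal(nrow(rep$comparisons), 2)
  row <- rep$comparisons[rep$comparisons$metric == "ratio_membrane", ]
  expect_lt(row$p_value, 0.01)
  expect_equal(row$stars, "**")
  expect_equal(row$n_a, 15)
  expect_equal(nrow(rep$descriptives), 4)
  # missing values are dropped and counted
  metrics$ratio_membrane[1] <- NA
  rep2 <- batch_report(metrics, cond)
  r2 <- rep2$comparisons[rep2$comparisons$metric == "ratio_membrane", ]
  expect_equal(r2$n_a, 14)
  expect_equal(r2$dropped_a, 1)
})

test_that("single condition yields descriptives only; labels validated", {
  metrics <- data.frame(cell_id = 1:12, v = rnorm(12))
  cond <- data.frame(cell_id = 1:12, condition = "only")
  rep <- batch_report(metrics, cond)
  expect_equal(nrow(rep$comparisons), 0)
  expect_equal(nrow(rep$descriptives), 1)
  expect_error(batch_report(metrics,
                            data.frame(cell_id = 2:12, condition = "x")),
               "without a condition")
  expect_warning(batch_report(data.frame(cell_id = 1:8, v = rnorm(8)),
                              data.frame(cell_id = 1:8,
                                         condition = rep(c("a", "b"), 4))),
                 "10-40")
})

test_that("a planted membrane-fraction shift is detected at high power", {
  # one real scene pair at planted delta f_m = 0.3, then a Monte-Carlo
  # power check at the empirically measured per-cell spread
  prof_for <- function(fm, seed) {
    params <- list(
      DAPI = list(background = 5, cell_amplitude = 200,
                  membrane_fraction = 0, nucleus_fraction = 1),
      markerA = list(background = 8, cell_amplitude = 50,
                     membrane_fraction = fm, nucleus_fraction = 0.1),
      markerB = list(background = 8, cell_amplitude = 40,
                     membrane_fraction = fm, nucleus_fraction = 0.1))
    sc <- generate_scene(scene_spec(n_cells = 20, seed = seed,
                                    channel_params = params,
                                    noise = list(poisson = TRUE,
                                                 gaussian_sd = 2.5)))
    img <- subtract_background(sc$image)
    compartment_profile(img, truth_segmentation(sc$truth), "markerA")
  }
  a <- prof_for(0.3, 71)$ratio_membrane
  b <- prof_for(0.6, 72)$ratio_membrane
  expect_lt(compare_groups(a, b)$p_value, 0.01)
  sd_cell <- max(sd(a), sd(b))
  set.seed(73)
  power <- mean(replicate(200, {
    compare_groups(rnorm(20, 0.3, sd_cell),
                   rnorm(20, 0.6, sd_cell))$p_value < 0.01
  }))
  expect_gte(power, 0.95)
})

test_that("report bundles are byte-stable for fixed inputs", {
  metrics <- data.frame(cell_id = 1:20, v = sin(1:20))
  cond <- data.frame(cell_id = 1:20,
                     condition = rep(c("a", "b"), each = 10))
  rep <- batch_report(metrics, cond)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_report(rep, d1); write_report(rep, d2)
  for (f in c("report_comparisons.csv", "report.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})
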