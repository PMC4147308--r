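test_that("Manders coefficients on hand-checkable configurations", {
  mask <- matrix(TRUE, 2, 2)
  a <- matrix(c(3, 1, 2, 5), 2, 2)
  # identical nonzero channels overlap fully
  mm <- manders(a, a, mask)
  expect_equal(mm$M1, 1); expect_equal(mm$M2, 1)

  # disjoint supports never co-occur
  b <- matrix(c(0, 0, 0, 0), 2, 2); b[a == 0] <- 4
  a2 <- matrix(c(3, 0, 0, 0), 2, 2); b2 <- matrix(c(0, 2, 2, 0), 2, 2)
  mm2 <- manders(a2, b2, mask)
  expect_equal(mm2$M1, 0); expect_equal(mm2$M2, 0)

  # the 4-pixel worked example: A = (10,10,0,0), B = (5,0,5,0)
  a3 <- matrix(c(10, 10, 0, 0), 2, 2)
  b3 <- matrix(c(5, 0, 5, 0), 2, 2)
  mm3 <- manders(a3, b3, mask)
  expect_equal(mm3$M1, 0.5)  # 10 of A's 20 counts sit where B > 0
  expect_equal(mm3$M2, 0.5)  # 5 of B's 10 counts sit where A > 0
})

test_that("Manders is invariant to per-channel gains and flags zeros", {
  set.seed(3)
  a <- matrix(rpois(64, 5), 8, 8)
  b <- matrix(rpois(64, 5), 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[2:7, 2:7] <- TRUE
  m0 <- manders(a, b, mask)
  m1 <- manders(a * 3.7, b * 0.21, mask)
  expect_equal(m1$M1, m0$M1); expect_equal(m1$M2, m0$M2)
  expect_true(m0$M1 >= 0 && m0$M1 <= 1)

  z <- matrix(0, 8, 8)
  mz <- manders(z, b, mask)
  expect_true(is.na(mz$M1))
  expect_match(paste(mz$flags, collapse = ";"), "zero_A")
  expect_error(manders(a, b, matrix(FALSE, 8, 8)), "empty")
})

test_that("PDM sign identities and covariance identity hold", {
  set.seed(5)
  a <- matrix(runif(400, 0, 10), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:18, 3:18] <- TRUE

  same <- pdm(a, a, mask)
  expect_true(all(same$pdm_map[mask] >= 0))
  expect_equal(same$positive_fraction, mean(a[mask] != mean(a[mask])))

  anti <- pdm(a, max(a) - a, mask)
  expect_true(all(anti$pdm_map[mask] <= 0))

  b <- matrix(runif(400, 0, 10), 20, 20)
  p <- pdm(a, b, mask)
  n <- sum(mask)
  expect_equal(p$mean_pdm,
               stats::cov(a[mask], b[mask]) * (n - 1) / n)
  expect_equal(sum(p$scatter_hist), n)  # scatter mass conservation
  expect_true(all(is.na(p$pdm_map[!mask])))
})

test_that("independent fields give mean PDM within 3 SE of zero", {
  # planted rho = 0, measured over >= 1e4 pixels of one cell's cytoplasm
  # (a region of homogeneous expected intensity, so any covariance would
  # come from the textures, which are independent by construction)
  sc <- generate_scene(scene_spec(n_cells = 1, seed = 43, coloc_rho = 0,
                                  cell_diameter = 140,
                                  cell_shape = "cuboidal"))
  img <- subtract_background(sc$image)
  a <- get_channel(img, "markerA"); b <- get_channel(img, "markerB")
  tr <- sc$truth
  mask <- tr$cell_labels == 1 & tr$membrane_labels != 1 &
    tr$nucleus_labels != 1
  expect_gte(sum(mask), 1e4)
  p <- pdm(a, b, mask)
  vals <- p$pdm_map[mask]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(p$mean_pdm), 3 * se)
})

test_that("nuclear M1 rises with the planted co-localization level", {
  m1 <- vapply(c(0, 0.5, 1), function(rho) {
    sc <- generate_scene(scene_spec(n_cells = 12, seed = 47,
                                    coloc_rho = rho,
                                    noise = list(poisson = FALSE,
                                                 gaussian_sd = 2)))
    img <- subtract_background(sc$image)
    cp <- coloc_profile(img, truth_segmentation(sc$truth),
                        c("markerA", "markerB"), region = "nucleus")
    mean(cp$M1, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(m1) > 0))
})

test_that("condition summaries aggregate profiles faithfully", {
  sc <- make_clean_scene(n_cells = 8, seed = 53)
  img <- subtract_planted_background(sc)
  prof <- compartment_profile(img, truth_segmentation(sc$truth),
                              c("markerA", "markerB"))
  cond <- data.frame(cell_id = 1:8,
                     condition = rep(c("control", "induced"), each = 4))
  s <- nuclear_membrane_shift(prof, cond)
  expect_equal(nrow(s), 4)  # 2 conditions x 2 channels
  # identical planting in both groups -> identical means
  expect_equal(s$mean_ratio_membrane[s$channel == "markerA"][1],
               s$mean_ratio_membrane[s$channel == "markerA"][2])
  expect_warning(
    nuclear_membrane_shift(prof, data.frame(cell_id = 1:8,
                                            condition = "only")),
    "single condition")
})

test_that("a condition planted with higher f_n shows a higher nucleus ratio", {
  prof_for <- function(fn, seed) {
    params <- list(
      DAPI = list(background = 5, cell_amplitude = 200,
                  membrane_fraction = 0, nucleus_fraction = 1),
      markerA = list(background = 8, cell_amplitude = 50,
                     membrane_fraction = 0.3, nucleus_fraction = fn),
      markerB = list(background = 8, cell_amplitude = 40,
                     membrane_fraction = 0.3, nucleus_fraction = fn))
    sc <- generate_scene(scene_spec(n_cells = 10, seed = seed,
                                    channel_params = params))
    img <- subtract_background(sc$image)
    compartment_profile(img, truth_segmentation(sc$truth), "markerA")
  }
  p_ctrl <- prof_for(0.1, 61)
  p_ind <- prof_for(0.45, 62)
  p_ind$cell_id <- p_ind$cell_id + 10
  cond <- data.frame(cell_id = 1:20,
                     condition = rep(c("control", "induced"), each = 10))
  s <- nuclear_membrane_shift(rbind(p_ctrl, p_ind), cond)
  expect_gt(s$mean_ratio_nucleus[s$condition == "induced"][1],
            s$mean_ratio_nucleus[s$condition == "control"][1])
})
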