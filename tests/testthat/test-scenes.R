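test_that("generated scenes satisfy the mask-geometry invariants", {
  sc <- make_clean_scene(n_cells = 8, seed = 3)
  tr <- sc$truth
  for (k in cell_ids(tr$cell_labels)) {
    cm <- tr$cell_labels == k
    mm <- tr$membrane_labels == k
    nm <- tr$nucleus_labels == k
    expect_true(all(cm[mm]))                # membrane inside cell
    expect_true(all(cm[nm]))                # nucleus inside cell
    expect_false(any(mm & nm))              # ring and nucleus disjoint
    expect_gt(sum(nm), 0)
  }
  # disjoint cells and DAPI confined to nuclei + background
  expect_true(all(table(tr$cell_labels[tr$cell_labels > 0]) > 0))
  dapi <- tr$clean$DAPI
  bg <- tr$spec$channel_params$DAPI$background
  expect_true(all(dapi[tr$nucleus_labels == 0] == bg))
  expect_true(all(dapi[tr$nucleus_labels > 0] > bg))
})

test_that("planted compartment fractions are exact on the clean image", {
  sc <- make_clean_scene(n_cells = 6, seed = 7)
  img <- subtract_planted_background(sc)
  seg <- truth_segmentation(sc$truth)
  for (ch in c("markerA", "markerB")) {
    planted <- sc$truth$channels[sc$truth$channels$channel == ch, ]
    prof <- compartment_profile(img, seg, ch)
    expect_equal(prof$ratio_membrane, planted$f_membrane, tolerance = 1e-9)
    expect_equal(prof$ratio_nucleus, planted$f_nucleus, tolerance = 1e-9)
  }
})

test_that("clean marker intensity is conserved at amplitude x area", {
  sc <- make_clean_scene(n_cells = 6, seed = 5)
  img <- subtract_planted_background(sc)
  a <- get_channel(img, "markerA")
  amp <- sc$truth$spec$channel_params$markerA$cell_amplitude
  for (k in cell_ids(sc$truth$cell_labels)) {
    area <- sum(sc$truth$cell_labels == k)
    expect_equal(sum(a[sc$truth$cell_labels == k]), amp * area,
                 tolerance = 0.005)
  }
})

test_that("all-membrane planting puts every marker count in the ring", {
  params <- list(
    DAPI = list(background = 0, cell_amplitude = 200,
                membrane_fraction = 0, nucleus_fraction = 1),
    markerA = list(background = 0, cell_amplitude = 50,
                   membrane_fraction = 1, nucleus_fraction = 0),
    markerB = list(background = 0, cell_amplitude = 50,
                   membrane_fraction = 1, nucleus_fraction = 0)
  )
  sc <- make_clean_scene(n_cells = 4, seed = 9, channel_params = params)
  a <- get_channel(sc$image, "markerA")
  expect_true(all(a[sc$truth$membrane_labels == 0] == 0))
  prof <- compartment_profile(sc$image, truth_segmentation(sc$truth),
                              "markerA")
  expect_equal(prof$ratio_membrane, rep(1, 4), tolerance = 1e-12)
  expect_equal(prof$ratio_nucleus, rep(0, 4), tolerance = 1e-12)
})

test_that("isolated scenes have zero true shared boundary", {
  sc <- make_clean_scene(n_cells = 9, seed = 13)
  expect_true(all(sc$truth$cells$true_shared == 0))
  m <- contact_morphology(truth_segmentation(sc$truth))
  expect_true(all(m$shared_perimeter == 0))
  expect_true(all(m$percent_contact == 0))
})

test_that("a fixed seed fixes the emitted scene bit-for-bit", {
  sp1 <- scene_spec(n_cells = 8, seed = 1,
                    channel_params = NULL, coloc_rho = 0.4,
                    noise = list(poisson = TRUE, gaussian_sd = 2))
  sp2 <- scene_spec(n_cells = 8, seed = 1,
                    channel_params = NULL, coloc_rho = 0.4,
                    noise = list(poisson = TRUE, gaussian_sd = 2))
  s1 <- generate_scene(sp1); s2 <- generate_scene(sp2)
  expect_identical(s1$image$channels, s2$image$channels)
  expect_identical(s1$truth$cells, s2$truth$cells)
  # and a different seed changes the noise realization
  s3 <- generate_scene(scene_spec(n_cells = 8, seed = 2, coloc_rho = 0.4))
  expect_false(identical(s1$image$channels$markerA,
                         s3$image$channels$markerA))
})

test_that("rho = 1 makes the marker channels proportional inside cells", {
  sc <- make_clean_scene(n_cells = 5, seed = 21, coloc_rho = 1)
  img <- subtract_planted_background(sc)
  a <- get_channel(img, "markerA"); b <- get_channel(img, "markerB")
  inside <- sc$truth$cell_labels > 0
  ratio <- b[inside][a[inside] > 0] / a[inside][a[inside] > 0]
  # equal planted fractions for both markers -> one global constant
  expect_lt(diff(range(ratio)), 1e-9)
  expect_true(all(b[inside][a[inside] == 0] == 0))
})

test_that("mean true shared boundary is monotone in the contact target", {
  shared <- vapply(c(0, 0.2, 0.35, 0.5), function(t) {
    sc <- generate_scene(scene_spec(n_cells = 10, seed = 17,
                                    adjacency_mode = "chained",
                                    target_contact_fraction = t))
    mean(sc$truth$cells$true_shared)
  }, numeric(1))
  expect_true(all(diff(shared) >= 0))
  expect_equal(shared[1], 0)
})

test_that("shot-noise variance tracks the clean mean", {
  # 500 replicate renders of a fixed nuclear-stain pixel: var ~ mean
  vals <- vapply(1:500, function(s) {
    sc <- generate_scene(scene_spec(
      n_cells = 1, seed = 1000 + s, cell_diameter = 18,
      image_size = c(34, 34), cell_shape = "cuboidal",
      noise = list(poisson = TRUE, gaussian_sd = 0)))
    ctr <- round(dim(sc$image$channels$DAPI) / 2)
    stopifnot(sc$truth$nucleus_labels[ctr[1], ctr[2]] > 0)
    sc$image$channels$DAPI[ctr[1], ctr[2]]
  }, numeric(1))
  clean_mean <- 200 + 5  # amplitude + background at a nuclear pixel
  expect_lt(abs(var(vals) / clean_mean - 1), 0.10)
})

test_that("invalid specs fail with parameter errors", {
  expect_error(scene_spec(channel_params = list(
    a = list(background = 0, cell_amplitude = 1,
             membrane_fraction = 0.7, nucleus_fraction = 0.5))),
    "> 1")
  expect_error(scene_spec(coloc_rho = 1.5), "coloc_rho")
  expect_error(scene_spec(target_contact_fraction = 1), "contact_fraction")
  expect_error(
    generate_scene(scene_spec(n_cells = 12, image_size = c(40, 40))),
    "placement error")
})
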