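test_that("polygon rasterization follows center sampling", {
  # axis-aligned rectangle (0,0)-(4,3): exactly the 12 pixels whose
  # centers fall inside
  poly <- data.frame(cell_id = 1, x = c(0, 4, 4, 0), y = c(0, 0, 3, 3))
  lab <- load_cell_outlines(poly, dim = c(10, 10))
  expect_equal(sum(lab == 1), 12)
  expect_true(all(lab[1:3, 1:4] == 1))
  expect_true(all(lab[4:10, ] == 0) && all(lab[, 5:10] == 0))

  # a label mask passes through unchanged
  m <- matrix(0L, 6, 6); m[2:3, 2:3] <- 2L
  expect_identical(load_cell_outlines(m), m)
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  # two triangles sharing one edge: disjoint pixel sets, each matching
  # ray-casting rasterization (shared edge slope 7/8 so no pixel center
  # falls exactly on it and the comparison is convention-free)
  tri <- data.frame(
    cell_id = rep(c(1, 2), each = 3),
    x = c(1, 9, 1, 1, 9, 9),
    y = c(1, 8, 8, 1, 1, 8))
  lab <- load_cell_outlines(tri, dim = c(12, 12))
  o1 <- oracle_rasterize(c(1, 9, 1), c(1, 8, 8), c(12, 12))
  o2 <- oracle_rasterize(c(1, 9, 9), c(1, 1, 8), c(12, 12))
  expect_false(any(o1 & o2))
  expect_identical(lab == 1, o1)
  expect_identical(lab == 2, o2)

  # random convex polygons against the oracle
  set.seed(99)
  for (i in 1:5) {
    th <- sort(runif(7, 0, 2 * pi))
    xs <- 10 + 7 * cos(th); ys <- 10 + 7 * sin(th)
    lab <- load_cell_outlines(data.frame(cell_id = 1, x = xs, y = ys),
                              dim = c(20, 20))
    expect_identical(lab == 1, oracle_rasterize(xs, ys, c(20, 20)))
  }
})

test_that("malformed outlines are rejected", {
  bowtie <- data.frame(cell_id = 1, x = c(0, 4, 0, 4), y = c(0, 4, 4, 0))
  expect_error(load_cell_outlines(bowtie, dim = c(8, 8)),
               "self-intersecting")
  overlap <- data.frame(cell_id = rep(1:2, each = 4),
                        x = c(0, 5, 5, 0, 2, 7, 7, 2),
                        y = c(0, 0, 5, 5, 2, 2, 7, 7))
  expect_error(load_cell_outlines(overlap, dim = c(10, 10)), "overlap")
  tiny <- data.frame(cell_id = 1, x = c(0, .2, .2, 0), y = c(0, 0, .2, .2))
  expect_error(load_cell_outlines(tiny, dim = c(10, 10)), "no pixel")
})

test_that("nucleus DAPI rule is strictly greater-than at the threshold", {
  cells <- matrix(0L, 8, 8); cells[2:7, 2:7] <- 1L
  for (v in c(59, 60)) {
    dapi <- matrix(0, 8, 8); dapi[cells == 1] <- v
    expect_warning(nuc <- threshold_nucleus(dapi, cells, threshold = 60),
                   "empty nucleus")
    expect_equal(sum(nuc), 0)
    expect_equal(attr(nuc, "empty_cells"), 1L)
  }
  dapi <- matrix(0, 8, 8); dapi[cells == 1] <- 61
  nuc <- threshold_nucleus(dapi, cells, threshold = 60)
  expect_identical(nuc > 0, cells > 0)
})

test_that("nucleus keeps only the largest connected component", {
  cells <- matrix(0L, 12, 20); cells[2:11, 2:19] <- 1L
  dapi <- matrix(0, 12, 20)
  dapi[3:5, 3:5] <- 200    # 9-pixel component
  dapi[8:9, 15:16] <- 200  # 4-pixel component
  nuc <- threshold_nucleus(dapi, cells, threshold = 60)
  expect_equal(sum(nuc == 1), 9)
  expect_true(all(nuc[3:5, 3:5] == 1))
  # independent component enumeration confirms the sizes
  lab <- oracle_components4(dapi > 60)
  expect_equal(sort(tabulate(lab[lab > 0])), c(4, 9))
})

test_that("membrane ring equals cell minus erosion, cross-checked", {
  cells <- matrix(0L, 14, 14); cells[3:12, 3:12] <- 1L
  ring <- derive_membrane_ring(cells, 1, "box")
  expect_equal(sum(ring == 1), 36)  # 100 - 64

  thin <- matrix(0L, 7, 7); thin[3:5, 3:5] <- 1L
  ring2 <- derive_membrane_ring(thin, 2, "box")
  expect_equal(sum(ring2 == 1), 9)  # whole cell is membrane
  expect_equal(attr(ring2, "thin_cells"), 1L)

  # 8x12 rectangle, disc element radius 2: the ring is every cell pixel
  # whose distance to the nearest background pixel is within the disc
  # brush's reach, cross-checked against a brute-force distance map
  rect <- matrix(0L, 14, 18); rect[4:11, 4:15] <- 1L
  ring3 <- derive_membrane_ring(rect, 2, "disc") == 1
  dmap <- oracle_interior_distance(rect == 1)
  brush <- EBImage::makeBrush(5, "disc")
  reach <- max(sqrt(((row(brush) - 3)^2 + (col(brush) - 3)^2)[brush > 0]))
  oracle_core <- !is.na(dmap) & dmap > reach
  expect_identical(ring3, (rect == 1) & !oracle_core)
})

test_that("ring width is validated", {
  cells <- matrix(0L, 5, 5); cells[2:4, 2:4] <- 1L
  expect_error(derive_membrane_ring(cells, 0), ">= 1")
})

test_that("segmentation invariants hold on derived masks", {
  sc <- generate_scene(scene_spec(n_cells = 8, seed = 31))
  img <- subtract_background(sc$image)
  seg <- segment_cells(img, sc$truth$cell_labels)
  expect_s3_class(seg, "cell_segmentation")  # constructor validates
  expect_identical(validate_segmentation(seg), seg)
  # tampering is caught
  broken <- seg
  out_px <- which(seg$cell_labels == 0)[1]
  broken$membrane_labels[out_px] <- 1L
  expect_error(validate_segmentation(broken), "escapes")
})

test_that("derived nuclei recover the true nuclei (Jaccard >= 0.9)", {
  # DAPI amplitude 200 >= 3x the 60-count threshold, noise sd 10 = 5%
  sc <- generate_scene(scene_spec(n_cells = 8, seed = 41,
                                  noise = list(poisson = FALSE,
                                               gaussian_sd = 10)))
  img <- subtract_background(sc$image)
  seg <- segment_cells(img, sc$truth$cell_labels)
  for (k in cell_ids(seg$cell_labels)) {
    a <- seg$nucleus_labels == k
    b <- sc$truth$nucleus_labels == k
    jacc <- sum(a & b) / sum(a | b)
    expect_gte(jacc, 0.9)
  }
})
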