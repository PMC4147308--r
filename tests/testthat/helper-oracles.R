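# Independent oracles, deliberately implemented with different algorithms
# than the package (ray casting instead of mgcv, recursive labelling
# instead of EBImage, brute-force distance maps instead of erosion).

# even-odd ray casting point-in-polygon
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(xs, ys, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2]))
    out[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5, xs, ys)
  out
}

# 4-connected component enumeration by repeated seed fill
oracle_components4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (p in which(mask & lab == 0L)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    nr <- nrow(mask)
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1L) %% nr + 1L; c <- (q - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, rr + (cc - 1L) * nr)
        }
      }
    }
  }
  lab
}

# per-pixel Euclidean distance to the nearest background pixel (or image
# border), by exhaustive search; used to cross-check erosion rings
oracle_interior_distance <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(NA_real_, nr, nc)
  for (p in which(mask)) {
    r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
    dist_bg <- if (nrow(bg)) min(sqrt((bg[, 1] - r)^2 + (bg[, 2] - c)^2)) else Inf
    d[p] <- min(dist_bg, r, c, nr + 1 - r, nc + 1 - c)
  }
  d
}

# small clean fixture scene shared across tests
make_clean_scene <- function(n_cells = 6, seed = 11, ...) {
  generate_scene(scene_spec(n_cells = n_cells, seed = seed,
                            noise = list(poisson = FALSE, gaussian_sd = 0),
                            ...),
                 clean = TRUE)
}

# subtract the exact planted backgrounds (clean-image oracle path)
subtract_planted_background <- function(scene) {
  p <- scene$truth$spec$channel_params
  vals <- vapply(p, function(x) x$background, numeric(1))
  subtract_background(scene$image, "fixed", vals)
}
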