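## Morphology and cell-cell contact statistics.
##
## Digital perimeters are convention-dependent; the conventions here are:
##  - "chain": Moore-traced 8-connected boundary chain, diagonal steps
##    weighted sqrt(2). A 10x10 square measures 36 (the 36 boundary pixels
##    traversed in unit steps), a single pixel measures 4 by convention.
##    The chain overestimates smooth boundaries by ~5.5% on average
##    (direction-averaging bias of the (1, sqrt2) weights).
##  - "crofton": 4-direction Crofton formula, nearly unbiased on smooth
##    convex shapes (disks within ~1-3%), underestimates polygons with
##    axis-aligned edges.
## Shared perimeter is always measured on the chain (Crofton is undefined
## on a boundary subset), so percent contact is a chain/chain ratio and
## the chain bias cancels.

# clockwise Moore neighborhood, starting north
.moore <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# 8-connected flood fill reachability from the first pixel; masks are
# per-cell crops so a simple queue is fast enough
is_connected8 <- function(mask) {
  n <- sum(mask)
  if (n == 0L) return(FALSE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  start <- which(mask)[1]
  queue <- start
  seen[start] <- TRUE
  count <- 1L
  nr <- nrow(mask)
  while (length(queue) > 0) {
    p <- queue[length(queue)]; queue <- queue[-length(queue)]
    r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
    for (i in 1:8) {
      rr <- r + .moore[i, 1]; cc <- c + .moore[i, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(mask) &&
          mask[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        count <- count + 1L
        queue <- c(queue, rr + (cc - 1L) * nr)
      }
    }
  }
  count == n
}

#' Trace the outer boundary chain of a mask
#'
#' Moore-neighbor tracing (clockwise, Jacob's stopping criterion) of the
#' outer 8-connected boundary. The mask must be a single 8-connected
#' component.
#'
#' @param mask logical matrix, one connected component.
#' @return n x 2 matrix of (row, col) boundary pixel coordinates forming a
#'   closed chain (last connects to first).
#' @export
trace_boundary <- function(mask) {
  if (!any(mask)) stop("empty mask")
  if (!is_connected8(mask)) stop("mask is not a single connected component")
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  start <- which(mask)[1]
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  if (sum(mask) == 1L) return(cbind(row = sr, col = sc))
  # start was found by a column-major scan, so the pixel north of it is
  # background: the backtrack invariant (bdir points at background) holds
  cap <- 4L * sum(mask) + 8L
  chain <- matrix(NA_integer_, cap, 2L)
  chain[1, ] <- c(sr, sc)
  nchain <- 1L
  r <- sr; c <- sc; bdir <- 1L  # index into .moore of the backtrack
  first_state <- NULL
  steps <- 0L
  repeat {
    hit <- NA_integer_
    for (s in 0:7) {
      i <- ((bdir - 1L + s) %% 8L) + 1L
      rr <- r + .moore[i, 1]; cc <- c + .moore[i, 2]
      if (at(rr, cc)) { hit <- i; break }
    }
    if (is.na(hit)) stop("boundary tracing failed")
    rr <- r + .moore[hit, 1]; cc <- c + .moore[hit, 2]
    # the next scan resumes at the last examined background neighbor,
    # seen from the new pixel (consecutive Moore neighbors are adjacent)
    prev <- ((hit - 2L) %% 8L) + 1L
    new_bdir <- opposite_dir(rr, cc, r + .moore[prev, 1], c + .moore[prev, 2])
    steps <- steps + 1L
    state <- c(rr, cc, new_bdir)
    if (steps == 1L) {
      first_state <- state
    } else if (all(state == first_state) || steps > cap) {
      break
    }
    nchain <- nchain + 1L
    chain[nchain, ] <- c(rr, cc)
    r <- rr; c <- cc; bdir <- new_bdir
  }
  out <- chain[seq_len(nchain), , drop = FALSE]
  # the trace re-enters the start just before reproducing its first
  # state; drop the duplicated closing pixel
  if (nchain > 1L && out[nchain, 1] == out[1, 1] && out[nchain, 2] == out[1, 2])
    out <- out[-nchain, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

# direction index (into .moore) of (pr,pc) as seen from (rr,cc)
opposite_dir <- function(rr, cc, pr, pc) {
  dr <- pr - rr; dc <- pc - cc
  dr <- max(-1L, min(1L, dr)); dc <- max(-1L, min(1L, dc))
  which(.moore[, 1] == dr & .moore[, 2] == dc)
}

chain_length <- function(chain, closed = TRUE) {
  n <- nrow(chain)
  if (n == 1L) return(4)  # single-pixel convention: 4 unit edges
  nxt <- if (closed) c(2:n, 1L) else 2:n
  cur <- if (closed) 1:n else 1:(n - 1L)
  steps <- sqrt((chain[nxt, 1] - chain[cur, 1])^2 +
                (chain[nxt, 2] - chain[cur, 2])^2)
  sum(steps)
}

crofton_perimeter <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(pad); nc <- ncol(pad)
  core <- pad[2:(nr - 1L), 2:(nc - 1L)]
  runs_h <- sum(core & !pad[2:(nr - 1L), 1:(nc - 2L)])        # left bg
  runs_v <- sum(core & !pad[1:(nr - 2L), 2:(nc - 1L)])        # up bg
  runs_d1 <- sum(core & !pad[1:(nr - 2L), 1:(nc - 2L)])       # up-left bg
  runs_d2 <- sum(core & !pad[1:(nr - 2L), 3:nc])              # up-right bg
  pi / 4 * (runs_h + runs_v + (runs_d1 + runs_d2) / sqrt(2))
}

#' Cell perimeter of a single mask
#'
#' @param mask logical matrix: one nonempty, 8-connected component
#'   (disconnected masks are an error naming the problem).
#' @param estimator `"chain"` (default; boundary chain with sqrt(2)
#'   diagonals) or `"crofton"` (4-direction Crofton).
#' @return perimeter length in pixels.
#' @export
cell_perimeter <- function(mask, estimator = c("chain", "crofton")) {
  estimator <- match.arg(estimator)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  if (!is_connected8(mask))
    stop("mask has multiple connected components; one cell per mask required")
  if (estimator == "crofton") return(crofton_perimeter(mask))
  chain_length(trace_boundary(mask))
}

#' Shared (contacted) perimeter of one cell in a labelled scene
#'
#' A boundary pixel of cell `cell_id` is "in contact" when any pixel of a
#' different nonzero label lies within Chebyshev distance
#' `contact_distance`. The shared perimeter is the chain length restricted
#' to steps joining two contact pixels, so `shared <= total` always and a
#' fully enclosed cell shares its whole boundary.
#'
#' @param labels integer label matrix.
#' @param cell_id which cell.
#' @param contact_distance Chebyshev tolerance in pixels (default 2,
#'   tolerating 1-px rasterization gaps).
#' @return shared boundary length in pixels.
#' @export
shared_perimeter <- function(labels, cell_id, contact_distance = 2L) {
  if (!cell_id %in% labels) stop("unknown cell_id: ", cell_id)
  mask <- labels == cell_id
  chain <- trace_boundary(mask)
  other <- labels > 0 & labels != cell_id
  d <- as.integer(contact_distance)
  nr <- nrow(labels); nc <- ncol(labels)
  contact <- vapply(seq_len(nrow(chain)), function(i) {
    r <- chain[i, 1]; c <- chain[i, 2]
    rs <- max(1L, r - d):min(nr, r + d)
    cs <- max(1L, c - d):min(nc, c + d)
    any(other[rs, cs])
  }, logical(1))
  n <- nrow(chain)
  if (n == 1L) return(if (contact[1]) 4 else 0)
  nxt <- c(2:n, 1L)
  keep <- contact & contact[nxt]
  if (!any(keep)) return(0)
  steps <- sqrt((chain[nxt, 1] - chain[, 1])^2 + (chain[nxt, 2] - chain[, 2])^2)
  sum(steps[keep])
}

#' Percent cell-cell contact
#'
#' The contact statistic: `100 * shared / total`, the percentage of a
#' cell's boundary length shared with neighboring cells.
#'
#' @param shared shared boundary length(s), `0 <= shared <= total`.
#' @param total total boundary length(s), `> 0`.
#' @return percentage in \[0, 100\]; vectorized.
#' @export
percent_contact <- function(shared, total) {
  if (any(total <= 0)) stop("total perimeter must be > 0")
  if (any(shared < 0)) stop("shared perimeter must be >= 0")
  if (any(shared > total + 1e-9))
    stop("invariant violation: shared perimeter exceeds total perimeter")
  100 * shared / total
}

#' Longitudinal and horizontal extent of a cell
#'
#' Default method fits the ellipse of inertia (second central moments of
#' the pixel centers): longitudinal = 4 sd along the major principal axis,
#' horizontal = 4 sd along the minor axis, floored at 1 px so the ratio of
#' degenerate 1-px-wide masks stays finite. "Longitudinal" is the larger
#' extent irrespective of image axes. The alternative `"feret"` method
#' returns max/min Feret diameters from boundary-point projections over
#' 180 orientations.
#'
#' @param mask logical matrix, nonempty.
#' @param method `"ellipse"` (moments) or `"feret"`.
#' @return list with `longitudinal`, `horizontal`, `ratio` (>= 1), `method`.
#' @export
axis_lengths <- function(mask, method = c("ellipse", "feret")) {
  method <- match.arg(method)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  if (method == "ellipse") {
    xy <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
    n <- nrow(xy)
    cc <- sweep(xy, 2, colMeans(xy))
    covm <- crossprod(cc) / n
    ev <- eigen(covm, symmetric = TRUE)$values
    ev[ev < 0] <- 0
    longi <- 4 * sqrt(ev[1])
    horiz <- 4 * sqrt(ev[2])
  } else {
    ch <- unique(rbind(trace_boundary(mask)))
    pts <- cbind(ch[, 2] - 0.5, ch[, 1] - 0.5)
    th <- seq(0, pi, length.out = 181L)[-181L]
    widths <- vapply(th, function(a) {
      p <- pts %*% c(cos(a), sin(a))
      max(p) - min(p) + 1  # + 1 px for the pixel footprint
    }, numeric(1))
    longi <- max(widths)
    horiz <- min(widths)
  }
  longi <- max(longi, 1)
  horiz <- max(horiz, 1)
  if (horiz > longi) { tmp <- longi; longi <- horiz; horiz <- tmp }
  list(longitudinal = longi, horizontal = horiz,
       ratio = longi / horiz, method = method)
}

#' Per-cell contact and morphology table
#'
#' Computes, for every cell in a segmentation or label mask: total
#' perimeter, shared perimeter, percent contact, and longitudinal /
#' horizontal extents with their ratio.
#'
#' @param seg a [cell_segmentation()] or an integer label matrix.
#' @param contact_distance Chebyshev contact tolerance in pixels.
#' @param estimator perimeter estimator for total perimeter; shared
#'   perimeter (and hence percent contact) always uses the chain.
#' @param axis_method `"ellipse"` or `"feret"`.
#' @return data.frame: cell_id, total_perimeter, shared_perimeter,
#'   percent_contact, longitudinal_length, horizontal_length, axis_ratio,
#'   estimator, contact_distance.
#' @export
contact_morphology <- function(seg, contact_distance = 2L,
                               estimator = c("chain", "crofton"),
                               axis_method = c("ellipse", "feret")) {
  estimator <- match.arg(estimator)
  axis_method <- match.arg(axis_method)
  labels <- if (inherits(seg, "cell_segmentation")) seg$cell_labels else seg
  ids <- cell_ids(labels)
  rows <- lapply(ids, function(k) {
    mask <- labels == k
    total_chain <- cell_perimeter(mask, "chain")
    total <- if (estimator == "chain") total_chain
             else cell_perimeter(mask, "crofton")
    shared <- shared_perimeter(labels, k, contact_distance)
    ax <- axis_lengths(mask, axis_method)
    data.frame(cell_id = k,
               total_perimeter = total,
               shared_perimeter = shared,
               percent_contact = percent_contact(shared, total_chain),
               longitudinal_length = ax$longitudinal,
               horizontal_length = ax$horizontal,
               axis_ratio = ax$ratio,
               estimator = estimator,
               contact_distance = as.integer(contact_distance))
  })
  do.call(rbind, rows)
}
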