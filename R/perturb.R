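# Synthetic contouring-error families. Convention used throughout: masks are
# {0,1} matrices with (row, col) = (y, x), 0-based in all reported
# coordinates; "x-axis" means image columns.

dilate_erode_kernel <- function(axis_mode, magnitude) {
  w <- 2 * magnitude + 1
  switch(axis_mode,
         x = matrix(1, 1, w),
         y = matrix(1, w, 1),
         both = matrix(1, w, w),
         abort("axis_mode must be one of 'x', 'y', 'both'"))
}

#' Dilate or erode a binary mask along chosen axes
#'
#' Realizes the over- / under-contouring error family: the mask boundary is
#' expanded (dilation) or contracted (erosion) by `magnitude` pixels along
#' the x-axis, the y-axis, or both, using a rectangular structuring element
#' (`1 x (2m+1)`, `(2m+1) x 1` or `(2m+1) x (2m+1)`).
#'
#' @param mask Binary matrix.
#' @param family `"dilate"` or `"erode"`.
#' @param axis_mode `"x"`, `"y"` or `"both"`.
#' @param magnitude Pixels per selected direction (default 2).
#' @return The perturbed binary matrix. Erosion that would empty the mask
#'   raises a degenerate-perturbation condition so callers can resample.
#' @export
#' @examples
#' m <- matrix(0L, 10, 10); m[4:7, 4:7] <- 1L
#' sum(mask_dilate_erode(m, "dilate", "both"))  # 4x4 -> 8x8
mask_dilate_erode <- function(mask, family = c("dilate", "erode"),
                              axis_mode = c("both", "x", "y"), magnitude = 2) {
  family <- match.arg(family)
  axis_mode <- match.arg(axis_mode)
  check_mask(mask)
  kern <- dilate_erode_kernel(axis_mode, magnitude)
  out <- if (family == "dilate") EBImage::dilate(mask, kern)
         else EBImage::erode(mask, kern)
  out <- matrix(as.integer(out > 0), nrow(mask), ncol(mask))
  if (family == "erode" && sum(out) == 0)
    abort_degenerate("erosion emptied the mask")
  out
}

#' Translate a binary mask by an integer offset
#'
#' Rigidly shifts the whole mask by `(dx, dy)` pixels (x = columns,
#' y = rows); pixels shifted outside the frame are dropped. A zero shift in
#' both directions is rejected because it would not be a perturbation.
#'
#' @param mask Binary matrix.
#' @param dx,dy Integer offsets, not both zero.
#' @return The shifted binary matrix; raises a degenerate-perturbation
#'   condition if every foreground pixel leaves the frame.
#' @export
mask_shift <- function(mask, dx, dy) {
  check_mask(mask)
  if (dx == 0 && dy == 0)
    abort("a (0, 0) shift is not a perturbation; dx and dy must not both be zero")
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  src <- which(mask == 1, arr.ind = TRUE)
  r <- src[, 1] + dy
  c <- src[, 2] + dx
  keep <- r >= 1 & r <= h & c >= 1 & c <= w
  out[cbind(r[keep], c[keep])] <- 1L
  if (sum(out) == 0)
    abort_degenerate("shift moved the whole mask off-frame")
  out
}

# ordered boundary trace, (y, x) 0-based, one row per vertex
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(mask)
  if (length(oc) == 0) abort_degenerate("mask has no traceable boundary")
  oc[[1]]  # columns: (row, col), 0-based, in traversal order
}

# integer line rasterization between two 0-based (y, x) vertices
bresenham <- function(p0, p1) {
  n <- max(abs(p1 - p0)) + 1
  cbind(round(seq(p0[1], p1[1], length.out = n)),
        round(seq(p0[2], p1[2], length.out = n)))
}

# fill a closed polygon given 0-based (y, x) vertices: interior pixel centers
# (even-odd rule) plus the rasterized edges themselves
fill_polygon <- function(vertices, h, w) {
  stopifnot(nrow(vertices) >= 3)
  out <- matrix(0L, h, w)
  closed <- rbind(vertices, vertices[1, , drop = FALSE])
  # interior test on all pixel centers of the bounding box
  rmin <- max(0, floor(min(vertices[, 1]))); rmax <- min(h - 1, ceiling(max(vertices[, 1])))
  cmin <- max(0, floor(min(vertices[, 2]))); cmax <- min(w - 1, ceiling(max(vertices[, 2])))
  if (rmax >= rmin && cmax >= cmin) {
    grid <- expand.grid(y = rmin:rmax, x = cmin:cmax)
    inside <- mgcv::in.out(cbind(closed[, 2], closed[, 1]),
                           cbind(grid$x, grid$y))
    pts <- grid[inside, , drop = FALSE]
    out[cbind(pts$y + 1, pts$x + 1)] <- 1L
  }
  # edges
  for (i in seq_len(nrow(closed) - 1)) {
    e <- bresenham(closed[i, ], closed[i + 1, ])
    keep <- e[, 1] >= 0 & e[, 1] < h & e[, 2] >= 0 & e[, 2] < w
    e <- e[keep, , drop = FALSE]
    if (nrow(e)) out[cbind(e[, 1] + 1, e[, 2] + 1)] <- 1L
  }
  out
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) <= 1) return(mask)
  matrix(as.integer(lab == which.max(tab)), nrow(mask), ncol(mask))
}

#' Apply boundary noise to a binary mask
#'
#' Traces the closed contour of the mask, displaces a subset of its vertices
#' by small integer offsets (at most 2 px per axis), redraws the displaced
#' vertex sequence as a closed polygon in the original traversal order and
#' fills it. This produces irregular, locally wrong boundaries while
#' preserving the overall organ shape. If the refilled polygon splits into
#' several components, the largest is kept.
#'
#' @param mask Binary matrix with a traceable closed boundary.
#' @param offsets Integer matrix `n_points x 2` of per-vertex `(dx, dy)`
#'   displacements, each in `[-2, 2]`.
#' @param vertex_idx Which boundary vertices (1-based along the trace) to
#'   displace; drawn uniformly without replacement when `NULL`.
#' @param seed Seed used only when `vertex_idx` is `NULL`.
#' @return The perturbed binary matrix.
#' @export
mask_boundary_noise <- function(mask, offsets, vertex_idx = NULL, seed = 1) {
  check_mask(mask)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (any(abs(offsets) > 2))
    abort("boundary-noise offsets must lie within [-2, 2] pixels per axis")
  n_points <- nrow(offsets)
  if (n_points < 1 || n_points > 15)
    abort("boundary noise displaces between 1 and 15 points")
  bd <- trace_boundary(mask)
  if (nrow(bd) < max(3, n_points))
    abort_degenerate("mask too small: boundary has fewer vertices than requested points")
  if (is.null(vertex_idx))
    vertex_idx <- with_rng(seed, sample(nrow(bd), n_points))
  if (length(vertex_idx) != n_points)
    abort("vertex_idx length must match the number of offset rows")
  verts <- bd
  verts[vertex_idx, 1] <- verts[vertex_idx, 1] + offsets[, 2]  # dy -> rows
  verts[vertex_idx, 2] <- verts[vertex_idx, 2] + offsets[, 1]  # dx -> cols
  out <- fill_polygon(verts, nrow(mask), ncol(mask))
  largest_component(out)
}

#' Sample one synthetic contouring error
#'
#' Draws one of the four error families (dilation, erosion, shift, boundary
#' noise) uniformly at random, samples its parameters within the family
#' bounds (+-2 px magnitudes and shifts, 1..15 displaced boundary points),
#' and applies it. Degenerate outcomes (emptied masks, identity results) are
#' resampled with a fresh family and parameters, up to `retries` attempts.
#'
#' @param mask Binary matrix to corrupt.
#' @param seed Integer seed; the same seed returns the identical
#'   (mask, spec) pair.
#' @param family Force a specific family instead of drawing one.
#' @param magnitude Dilation/erosion magnitude in pixels.
#' @param retries Resampling budget before giving up.
#' @return A list with `mask` (the perturbed matrix, always differing from
#'   the input in at least one pixel) and `spec` (family and sampled
#'   parameters).
#' @export
sample_perturbation <- function(mask, seed, family = NULL, magnitude = 2,
                                retries = 20) {
  check_mask(mask)
  families <- c("dilate", "erode", "shift", "boundary_noise")
  if (!is.null(family)) family <- match.arg(family, families)
  shift_space <- expand.grid(dx = -2:2, dy = -2:2)
  shift_space <- shift_space[!(shift_space$dx == 0 & shift_space$dy == 0), ]
  with_rng(seed, {
    for (attempt in seq_len(retries)) {
      fam <- if (is.null(family)) sample(families, 1) else family
      res <- tryCatch({
        if (fam %in% c("dilate", "erode")) {
          axis_mode <- sample(c("x", "y", "both"), 1)
          spec <- list(family = fam, axis_mode = axis_mode,
                       magnitude = magnitude)
          out <- mask_dilate_erode(mask, fam, axis_mode, magnitude)
        } else if (fam == "shift") {
          row <- shift_space[sample(nrow(shift_space), 1), ]
          spec <- list(family = "shift", dx = row$dx, dy = row$dy)
          out <- mask_shift(mask, row$dx, row$dy)
        } else {
          bd_len <- nrow(trace_boundary(mask))
          if (bd_len < 3) abort_degenerate("boundary too short")
          n_points <- sample(seq_len(min(15, bd_len)), 1)
          vertex_idx <- sample(bd_len, n_points)
          offsets <- matrix(sample(-2:2, 2 * n_points, replace = TRUE),
                            ncol = 2)
          spec <- list(family = "boundary_noise", n_points = n_points,
                       vertex_idx = vertex_idx, offsets = offsets)
          out <- mask_boundary_noise(mask, offsets, vertex_idx)
        }
        list(mask = out, spec = spec)
      }, contourqa_degenerate = function(e) NULL)
      if (!is.null(res) && sum(res$mask) > 0 &&
          any(res$mask != mask))
        return(res)
    }
    abort(sprintf(
      "no non-degenerate perturbation found for this mask after %d attempts",
      retries))
  })
}
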