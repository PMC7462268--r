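# Regular tissue grid: phase volume fractions, consumption maps, and the
# trilinear sampling/deposition kernels shared by the oxygen solver.
# Voxel (i, j, k) (1-based) has its center at ((i - 0.5) * spacing, ...).

#' Construct a tissue grid
#'
#' Regular 3D grid of tissue phase volume fractions (normal, viable tumor,
#' necrotic) with Michaelis-Menten consumption maps assembled as
#' `v_m = phi_normal * v_m_host + phi_tumor * v_m_tumor` (necrotic tissue does
#' not consume O2) and `k_m` analogously (defaulting to the host value where
#' no phase dominates).
#'
#' @param spacing Voxel spacing, um.
#' @param shape Integer vector of length 3: voxels per axis.
#' @param phi_normal,phi_tumor,phi_necrotic Arrays of per-voxel volume
#'   fractions (each in \[0, 1\], summing to <= 1 per voxel).
#' @param params A [transport_params()] supplying `v_m_host`, `v_m_tumor`,
#'   `k_m_host`, `k_m_tumor`.
#' @return An object of class `tissue_grid` with fields `spacing`, `shape`,
#'   the phase arrays, `v_m` (uM/s), `k_m` (mm Hg) and `po2` (mm Hg;
#'   initialised to zero until solved).
#' @export
tissue_grid <- function(spacing, shape, phi_normal, phi_tumor, phi_necrotic,
                        params = transport_params("mouse")) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 2), spacing > 0)
  dims <- function(a) identical(dim(a), shape) || length(a) == prod(shape)
  stopifnot(dims(phi_normal), dims(phi_tumor), dims(phi_necrotic))
  phi_normal <- array(phi_normal, shape)
  phi_tumor <- array(phi_tumor, shape)
  phi_necrotic <- array(phi_necrotic, shape)
  if (any(phi_normal < 0) || any(phi_tumor < 0) || any(phi_necrotic < 0)) {
    stop("phase fractions must be >= 0", call. = FALSE)
  }
  tot <- phi_normal + phi_tumor + phi_necrotic
  if (any(tot > 1 + 1e-12)) {
    stop("phase fractions must sum to <= 1 per voxel", call. = FALSE)
  }
  v_m <- phi_normal * params$v_m_host + phi_tumor * params$v_m_tumor
  # k_m blended over consuming phases; host value where nothing consumes
  wsum <- phi_normal + phi_tumor
  k_m <- array(params$k_m_host, shape)
  pos <- wsum > 0
  k_m[pos] <- (phi_normal[pos] * params$k_m_host +
                 phi_tumor[pos] * params$k_m_tumor) / wsum[pos]
  structure(list(spacing = spacing, shape = shape, origin = c(0, 0, 0),
                 phi_normal = phi_normal, phi_tumor = phi_tumor,
                 phi_necrotic = phi_necrotic, v_m = v_m, k_m = k_m,
                 po2 = array(0, shape)),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %d x %d x %d voxels at %g um spacing\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing))
  cat(sprintf("  tumor fraction %.3f, necrotic fraction %.3f\n",
              mean(x$phi_tumor), mean(x$phi_necrotic)))
  invisible(x)
}

#' Tidy a tissue grid into a long voxel table
#'
#' @param x A [tissue_grid()].
#' @param ... Unused.
#' @return Tibble with voxel indices, center coordinates (um), phase
#'   fractions, consumption parameters and the tissue pO2 field.
#' @export
tidy.tissue_grid <- function(x, ...) {
  g <- x
  idx <- expand.grid(i = seq_len(g$shape[1]), j = seq_len(g$shape[2]),
                     k = seq_len(g$shape[3]))
  tibble::tibble(
    i = idx$i, j = idx$j, k = idx$k,
    x = (idx$i - 0.5) * g$spacing,
    y = (idx$j - 0.5) * g$spacing,
    z = (idx$k - 0.5) * g$spacing,
    phi_normal = as.vector(g$phi_normal),
    phi_tumor = as.vector(g$phi_tumor),
    phi_necrotic = as.vector(g$phi_necrotic),
    v_m = as.vector(g$v_m), k_m = as.vector(g$k_m),
    po2 = as.vector(g$po2))
}

# --- trilinear kernels -----------------------------------------------------

# For points (n x 3 matrix, um), return list(idx = n x 8 voxel linear indices,
# w = n x 8 weights). Points are clamped to the cell-center hull so Neumann
# boundaries see constant extrapolation.
trilinear_stencil <- function(points, grid) {
  h <- grid$spacing
  sh <- grid$shape
  out_idx <- matrix(1L, nrow(points), 8)
  out_w <- matrix(0, nrow(points), 8)
  u <- sweep(points, 2, grid$origin) / h - 0.5   # voxel-center coordinates
  for (d in 1:3) u[, d] <- pmin(pmax(u[, d], 0), sh[d] - 1)
  i0 <- pmin(floor(u), rep(1, nrow(points)) %o% (sh - 2))
  fr <- u - i0
  corner <- expand.grid(c(0, 1), c(0, 1), c(0, 1))
  for (c8 in 1:8) {
    off <- as.numeric(corner[c8, ])
    ii <- i0[, 1] + off[1]; jj <- i0[, 2] + off[2]; kk <- i0[, 3] + off[3]
    w <- (ifelse(off[1] == 1, fr[, 1], 1 - fr[, 1]) *
            ifelse(off[2] == 1, fr[, 2], 1 - fr[, 2]) *
            ifelse(off[3] == 1, fr[, 3], 1 - fr[, 3]))
    out_idx[, c8] <- as.integer(ii + sh[1] * (jj + sh[2] * kk)) + 1L
    out_w[, c8] <- w
  }
  list(idx = out_idx, w = out_w)
}

# Sample a per-voxel field at arbitrary points (trilinear).
sample_field <- function(field, points, grid) {
  st <- trilinear_stencil(points, grid)
  vals <- matrix(field[st$idx], nrow(points), 8)
  rowSums(vals * st$w)
}

# Deposit point amounts (e.g. mol/s worth of source) onto voxels by trilinear
# weights; returns a per-voxel array of summed amounts.
deposit_points <- function(amounts, points, grid) {
  st <- trilinear_stencil(points, grid)
  out <- numeric(prod(grid$shape))
  contrib <- as.vector(st$w * amounts)
  idx <- as.vector(st$idx)
  add <- rowsum(contrib, idx)
  out[as.integer(rownames(add))] <- add[, 1]
  array(out, grid$shape)
}

# Evenly spaced sample points along each segment (for line-source splatting
# and for the tissue pO2 seen by a segment). Returns a tibble with segment id,
# point coordinates and the length weight of each point.
segment_sample_points <- function(network, step) {
  nod <- network$nodes
  seg <- network$segments
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  pa <- cbind(nod$x[ia], nod$y[ia], nod$z[ia])
  pb <- cbind(nod$x[ib], nod$y[ib], nod$z[ib])
  n_pts <- pmax(1L, as.integer(ceiling(seg$length / step)))
  reps <- rep(seq_len(nrow(seg)), n_pts)
  tloc <- unlist(lapply(n_pts, function(m) (seq_len(m) - 0.5) / m))
  pts <- pa[reps, , drop = FALSE] +
    (pb[reps, , drop = FALSE] - pa[reps, , drop = FALSE]) * tloc
  tibble::tibble(seg_row = reps,
                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 w_len = rep(seg$length / n_pts, n_pts))
}
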