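## ---- masks for 2D point-pattern analyses -----------------------------------

#' Analysis masks for 2D point patterns
#'
#' \code{disc_mask} is a disc of given center and radius; \code{rect_mask} a
#' rectangle, optionally with periodic (toroidal) boundary conditions for
#' edge-free null models.
#'
#' @param center,radius disc center (um) and radius (um).
#' @param xlim,ylim rectangle extents (um).
#' @param torus logical; wrap distances periodically.
#' @return Object of class \code{"ppp_mask"}.
#' @export
disc_mask <- function(center = c(0, 0), radius = 2.8) {
  stopifnot(radius > 0)
  structure(list(type = "disc", center = center, radius = radius,
                 area = pi * radius^2, torus = FALSE), class = "ppp_mask")
}

#' @rdname disc_mask
#' @export
rect_mask <- function(xlim, ylim, torus = FALSE) {
  stopifnot(diff(xlim) > 0, diff(ylim) > 0)
  structure(list(type = "rect", xlim = xlim, ylim = ylim,
                 area = diff(xlim) * diff(ylim), torus = torus),
            class = "ppp_mask")
}

mask_contains <- function(mask, x, y) {
  if (mask$type == "disc")
    (x - mask$center[1])^2 + (y - mask$center[2])^2 <= mask$radius^2
  else
    x >= mask$xlim[1] & x <= mask$xlim[2] & y >= mask$ylim[1] & y <= mask$ylim[2]
}

## distance to the mask boundary (Inf for a torus: no edges)
mask_edge_dist <- function(mask, x, y) {
  if (mask$type == "disc")
    mask$radius - sqrt((x - mask$center[1])^2 + (y - mask$center[2])^2)
  else if (mask$torus)
    rep(Inf, length(x))
  else
    pmin(x - mask$xlim[1], mask$xlim[2] - x, y - mask$ylim[1], mask$ylim[2] - y)
}

mask_runif <- function(mask, n) {
  if (mask$type == "disc") {
    r <- mask$radius * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    cbind(mask$center[1] + r * cos(a), mask$center[2] + r * sin(a))
  } else {
    cbind(stats::runif(n, mask$xlim[1], mask$xlim[2]),
          stats::runif(n, mask$ylim[1], mask$ylim[2]))
  }
}

pair_dists <- function(x, y, mask = NULL) {
  if (!is.null(mask) && isTRUE(mask$torus)) {
    lx <- diff(mask$xlim); ly <- diff(mask$ylim)
    dx <- abs(outer(x, x, "-")); dx <- pmin(dx, lx - dx)
    dy <- abs(outer(y, y, "-")); dy <- pmin(dy, ly - dy)
    sqrt(dx^2 + dy^2)
  } else {
    as.matrix(stats::dist(cbind(x, y)))
  }
}

## ---- detection --------------------------------------------------------------

#' Detect fluorescent spots in an image stack
#'
#' Scale-matched Laplacian-of-Gaussian detection: the stack is smoothed with
#' an anisotropic Gaussian matched to the expected spot size, local maxima of
#' the scale-normalized -LoG response are collected, maxima closer than half
#' an expected diameter are merged (brightest kept), candidates below the raw
#' intensity threshold are dropped, and positions are refined to sub-voxel
#' precision by a local centroid.
#'
#' @param stack a 3D array from \code{\link{render_stack}}, or any array with
#'   \code{px_nm} and \code{z_step_nm} attributes (or passed explicitly).
#' @param expected_diameter_nm expected lateral spot diameter (nm),
#'   default 120.
#' @param intensity_threshold minimum raw intensity at the peak (counts);
#'   the working range for the synthetic camera model is 3000-5000.
#' @param px_nm,z_step_nm voxel sizes (nm); required if not in attributes.
#' @return A \code{"spot_set"} data frame
#'   (\code{cell_id, x_um, y_um, z_um, intensity, region}).
#' @export
detect_spots <- function(stack, expected_diameter_nm = 120,
                         intensity_threshold = 3000,
                         px_nm = attr(stack, "px_nm"),
                         z_step_nm = attr(stack, "z_step_nm")) {
  if (is.null(px_nm) || is.null(z_step_nm))
    stop("voxel sizes unknown: supply px_nm and z_step_nm")
  if (expected_diameter_nm < 2 * px_nm)
    stop("expected diameter must span at least 2 pixels laterally")
  d <- dim(stack)
  if (length(d) == 2) { stack <- array(stack, c(d, 1)); d <- dim(stack) }
  sig_xy <- (expected_diameter_nm / 2.35482) / px_nm       # voxels
  sig_z <- max((expected_diameter_nm * 2 / 2.35482) / z_step_nm, 0.5)
  sm <- gauss_blur3(stack, sig_xy, if (d[3] > 1) sig_z else 0)
  ## scale-normalized negative Laplacian (bright blobs -> positive response)
  lap <- -laplacian3(sm, c(1, 1, (z_step_nm / px_nm)^2))
  resp <- lap * sig_xy^2
  mx <- local_maxima3(resp)
  idx <- which(mx & resp > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_spot_set())
  peak_raw <- stack[cbind(idx[, 1], idx[, 2], idx[, 3])]
  keep <- peak_raw >= intensity_threshold
  idx <- idx[keep, , drop = FALSE]
  peak_raw <- peak_raw[keep]
  if (nrow(idx) == 0) return(empty_spot_set())
  ## merge maxima closer than half a diameter (keep the brightest)
  pos <- cbind(idx[, 1] * px_nm, idx[, 2] * px_nm, idx[, 3] * z_step_nm)
  ord <- order(-peak_raw)
  keep2 <- logical(length(ord))
  taken <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    if (nrow(taken) == 0 ||
        min(sqrt(rowSums(sweep(taken, 2, pos[i, ])^2))) >
          expected_diameter_nm / 2) {
      keep2[i] <- TRUE
      taken <- rbind(taken, pos[i, ])
    }
  }
  idx <- idx[keep2, , drop = FALSE]
  peak_raw <- peak_raw[keep2]
  ## sub-voxel centroid refinement on the smoothed stack
  org <- attr(stack, "origin_um")
  if (is.null(org)) org <- c(0, 0, 0)
  ref <- t(vapply(seq_len(nrow(idx)), function(i) {
    ii <- idx[i, ]
    xr <- max(1, ii[1] - 2):min(d[1], ii[1] + 2)
    yr <- max(1, ii[2] - 2):min(d[2], ii[2] + 2)
    zr <- max(1, ii[3] - 1):min(d[3], ii[3] + 1)
    blk <- sm[xr, yr, zr, drop = FALSE] - min(sm[xr, yr, zr])
    w <- sum(blk)
    if (w <= 0) return(c(ii[1], ii[2], ii[3]))
    c(sum(slice.index(blk, 1) * blk) / w + xr[1] - 1,
      sum(slice.index(blk, 2) * blk) / w + yr[1] - 1,
      sum(slice.index(blk, 3) * blk) / w + zr[1] - 1)
  }, numeric(3)))
  out <- data.frame(
    cell_id = 1L,
    x_um = org[1] + (ref[, 1] - 1) * px_nm / 1000,
    y_um = org[2] + (ref[, 2] - 1) * px_nm / 1000,
    z_um = org[3] + (ref[, 3] - 1) * z_step_nm / 1000,
    intensity = peak_raw,
    region = "unassigned")
  class(out) <- c("spot_set", "data.frame")
  out
}

empty_spot_set <- function() {
  out <- data.frame(cell_id = integer(0), x_um = numeric(0),
                    y_um = numeric(0), z_um = numeric(0),
                    intensity = numeric(0), region = character(0))
  class(out) <- c("spot_set", "data.frame")
  out
}

## separable FFT-free Gaussian blur (direct 1D convolutions along each axis)
gauss_blur3 <- function(a, sig_xy, sig_z) {
  conv_axis <- function(a, k, axis) {
    if (length(k) == 1) return(a)
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1], dp[2] * dp[3])
    n <- dp[1]; hw <- (length(k) - 1) / 2
    ## reflect-pad then convolve columns
    pad <- rbind(m[rev(seq_len(min(hw, n))), , drop = FALSE], m,
                 m[rev(n + 1 - seq_len(min(hw, n))), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    array(out, dp) -> ap2
    aperm(ap2, order(perm))
  }
  kern <- function(s) {
    if (s <= 0) return(1)
    hw <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-hw, hw))^2 / (2 * s^2))
    k / sum(k)
  }
  a <- conv_axis(a, kern(sig_xy), 1)
  a <- conv_axis(a, kern(sig_xy), 2)
  if (dim(a)[3] > 1) a <- conv_axis(a, kern(sig_z), 3)
  a
}

## discrete Laplacian with axis weights (w3 rescales z for anisotropy)
laplacian3 <- function(a, w = c(1, 1, 1)) {
  d <- dim(a)
  sh <- function(a, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    i <- pmin(pmax(seq_len(n) + by, 1), n)    # replicate edges
    idx[[axis]] <- i
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  out <- (sh(a, 1, 1) + sh(a, 1, -1) - 2 * a) / w[1] +
    (sh(a, 2, 1) + sh(a, 2, -1) - 2 * a) / w[2]
  if (d[3] > 1) out <- out + (sh(a, 3, 1) + sh(a, 3, -1) - 2 * a) / w[3]
  out
}

## strict 26-neighborhood local maxima
local_maxima3 <- function(a) {
  d <- dim(a)
  sh <- function(a, dx, dy, dz) {
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    a[ix, iy, iz, drop = FALSE]
  }
  mx <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (d[3] == 1 && dz != 0) next
    mx <- mx & (a >= sh(a, dx, dy, dz))
  }
  ## exclude flat plateaus at the array border
  mx[c(1, d[1]), , ] <- FALSE
  mx[, c(1, d[2]), ] <- FALSE
  if (d[3] > 2) mx[, , c(1, d[3])] <- FALSE
  mx
}

## ---- nearest-neighbour statistics ------------------------------------------

#' Nearest-neighbour distances of a spot pattern
#'
#' Euclidean nearest-neighbour distance per spot (3D when z is present),
#' with optional edge masking: spots within \code{edge_margin} of the mask
#' boundary are excluded as queries but retained as potential neighbours, so
#' edge spots neither bias the distances nor starve interior spots of
#' neighbours.  Cells are aggregated as mean and SD of per-cell means.
#'
#' @param spots a \code{"spot_set"} (column \code{cell_id} groups cells).
#' @param mask optional \code{\link{disc_mask}}/\code{\link{rect_mask}} for
#'   edge handling (2D analyses).
#' @param edge_margin edge exclusion margin (um).
#' @return Object of class \code{"nnd_result"}: per-spot distances (nm),
#'   per-cell means, and the across-cell mean +/- SD (nm).
#' @export
nearest_neighbor <- function(spots, mask = NULL, edge_margin = 0) {
  cells <- split(seq_len(nrow(spots)), spots$cell_id)
  per_spot <- list(); per_cell <- numeric(0)
  for (ci in names(cells)) {
    s <- spots[cells[[ci]], , drop = FALSE]
    if (nrow(s) < 2)
      stop("nearest-neighbour distances undefined: fewer than 2 spots in cell ", ci)
    use_z <- !is.null(s$z_um) && any(is.finite(s$z_um)) && stats::var(s$z_um) > 0
    if (use_z && is.null(mask)) {
      D <- as.matrix(stats::dist(cbind(s$x_um, s$y_um, s$z_um)))
    } else {
      D <- pair_dists(s$x_um, s$y_um, mask)
    }
    diag(D) <- Inf
    q <- rep(TRUE, nrow(s))
    if (!is.null(mask) && edge_margin > 0)
      q <- mask_edge_dist(mask, s$x_um, s$y_um) >= edge_margin
    if (sum(q) < 1)
      stop("no query spots left after edge masking in cell ", ci)
    nnd <- apply(D[q, , drop = FALSE], 1, min) * 1000   # nm
    per_spot[[ci]] <- nnd
    per_cell[ci] <- mean(nnd)
  }
  out <- list(per_spot_nm = per_spot, per_cell_mean_nm = per_cell,
              mean_nm = mean(per_cell),
              sd_nm = if (length(per_cell) > 1) stats::sd(per_cell) else NA_real_,
              n_cells = length(per_cell), edge_margin_um = edge_margin)
  class(out) <- "nnd_result"
  out
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("Nearest-neighbour distances: %.0f +/- %.0f nm (n = %d cells)\n",
              x$mean_nm, x$sd_nm, x$n_cells))
  invisible(x)
}

#' G-function envelope test against complete spatial randomness
#'
#' Compares the empirical G-function (nearest-neighbour distance CDF) of a
#' 2D pattern with pointwise Monte-Carlo envelopes from \code{n_sim} CSR
#' patterns of the same size in the same mask.  With \code{n_sim = 39}
#' the pointwise min/max envelope is a 5 percent test by construction.  The
#' verdict is "consistent with random" when the empirical curve stays inside
#' the envelopes on at least \code{inside_frac} of the distance grid.
#'
#' @param spots a \code{"spot_set"} (one cell) or matrix of x,y.
#' @param mask a \code{\link{disc_mask}} or \code{\link{rect_mask}}.
#' @param n_sim number of CSR simulations (>= 19), default 39.
#' @param seed RNG seed.
#' @param r_grid distance grid (um), default 0 to 1 um in 10 nm steps.
#' @param inside_frac verdict threshold, default 0.95.
#' @return Object of class \code{"envelope_result"}: \code{r_um},
#'   \code{G_obs}, \code{lo}, \code{hi}, \code{inside_fraction},
#'   \code{consistent_with_csr}.
#' @export
csr_envelope <- function(spots, mask, n_sim = 39, seed = NULL,
                         r_grid = seq(0, 1, by = 0.01), inside_frac = 0.95) {
  if (n_sim < 19) stop("n_sim must be >= 19")
  if (mask$area <= 0) stop("degenerate mask (zero area)")
  if (!is.null(seed)) set.seed(seed)
  x <- spots$x_um; y <- spots$y_um
  n <- length(x)
  if (n < 2) stop("need >= 2 spots")
  gfun <- function(x, y) {
    D <- pair_dists(x, y, mask)
    diag(D) <- Inf
    nnd <- apply(D, 1, min)
    stats::ecdf(nnd)(r_grid)
  }
  G_obs <- gfun(x, y)
  sims <- vapply(seq_len(n_sim), function(i) {
    p <- mask_runif(mask, n)
    gfun(p[, 1], p[, 2])
  }, numeric(length(r_grid)))
  lo <- apply(sims, 1, min)
  hi <- apply(sims, 1, max)
  inside <- mean(G_obs >= lo & G_obs <= hi)
  out <- list(r_um = r_grid, G_obs = G_obs, lo = lo, hi = hi,
              n_sim = n_sim, inside_fraction = inside,
              consistent_with_csr = inside >= inside_frac)
  class(out) <- "envelope_result"
  out
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    "CSR envelope (%d simulations): observed G inside envelope at %.0f%% of distances -> %s\n",
    x$n_sim, 100 * x$inside_fraction,
    if (x$consistent_with_csr) "consistent with random"
    else "departs from random"))
  invisible(x)
}

## ---- per-region densities ---------------------------------------------------

#' Spot densities per membrane region
#'
#' Counts per unit area for the whole cell and for the dimple and rim
#' regions; the enrichment statistic is the mean of per-cell dimple/rim
#' ratios (matching per-cell reporting), not the ratio of pooled densities.
#'
#' @param spots a \code{"spot_set"} with a \code{region} column
#'   ("dimple"/"rim").
#' @param regions a \code{\link{segment_surface}} summary providing the
#'   region areas (um^2).
#' @return Object of class \code{"density_summary"}: per-cell densities and
#'   ratios, and across-cell mean +/- SD of the ratio.
#' @export
region_density <- function(spots, regions) {
  if (regions$dimple_area <= 0 || regions$rim_area <= 0)
    stop("region areas must be positive")
  cells <- split(spots, spots$cell_id)
  rows <- lapply(cells, function(s) {
    nd <- sum(s$region == "dimple"); nr <- sum(s$region == "rim")
    data.frame(cell_id = s$cell_id[1],
               n_total = nrow(s), n_dimple = nd, n_rim = nr,
               total_density = nrow(s) / regions$total_area,
               dimple_density = nd / regions$dimple_area,
               rim_density = nr / regions$rim_area,
               ratio = if (nr > 0) (nd / regions$dimple_area) /
                   (nr / regions$rim_area) else NA_real_)
  })
  per_cell <- do.call(rbind, rows)
  if (any(is.na(per_cell$ratio)))
    warning(sum(is.na(per_cell$ratio)),
            " cell(s) with zero rim count excluded from the ratio")
  rat <- per_cell$ratio[!is.na(per_cell$ratio)]
  out <- list(per_cell = per_cell,
              ratio_mean = mean(rat),
              ratio_sd = if (length(rat) > 1) stats::sd(rat) else NA_real_,
              n_cells = length(rat))
  class(out) <- "density_summary"
  out
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("Dimple/rim density ratio: %.2f +/- %.2f (N = %d cells)\n",
              x$ratio_mean, x$ratio_sd, x$n_cells))
  invisible(x)
}
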