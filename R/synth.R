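#' Spot-generation parameters
#'
#' @param n_spots number of spots per cell, or NULL to draw from the observed
#'   abundance distribution (normal with mean 80.2 and SD 26, truncated at 0).
#' @param density \code{"map"} to sample from a Boltzmann density map,
#'   \code{"uniform"} for area-uniform placement.
#' @param seed optional RNG seed, recorded in the output metadata.
#' @export
spot_gen_params <- function(n_spots = NULL, density = c("map", "uniform"),
                            seed = NULL) {
  density <- match.arg(density)
  if (!is.null(n_spots) && n_spots < 0) stop("n_spots must be >= 0")
  structure(list(n_spots = n_spots, density = density, seed = seed),
            class = "spot_gen_params")
}

#' Imaging parameters for the synthetic camera model
#'
#' Gaussian-PSF emitters with Poisson shot noise on (background + signal) and
#' a constant camera offset; no Gaussian read noise, so intensity units stay
#' comparable to raw-count detection thresholds.
#'
#' @param psf_fwhm_nm lateral PSF FWHM (nm), default 120.
#' @param psf_axial_fwhm_nm axial PSF FWHM (nm), default 300.
#' @param z_step_nm optical section spacing (nm), default 125.
#' @param px_nm lateral pixel size (nm), default 40.
#' @param photons expected peak signal counts per unit spot intensity.
#' @param background expected background counts per voxel.
#' @param offset camera offset (counts).
#' @param seed optional RNG seed.
#' @export
imaging_params <- function(psf_fwhm_nm = 120, psf_axial_fwhm_nm = 300,
                           z_step_nm = 125, px_nm = 40, photons = 5000,
                           background = 50, offset = 100, seed = NULL) {
  if (psf_fwhm_nm < 2 * px_nm)
    stop("PSF FWHM must be at least 2 pixels for resolvable spots")
  stopifnot(photons >= 0, background >= 0, offset >= 0, z_step_nm > 0)
  structure(list(psf_fwhm_nm = psf_fwhm_nm,
                 psf_axial_fwhm_nm = psf_axial_fwhm_nm,
                 z_step_nm = z_step_nm, px_nm = px_nm, photons = photons,
                 background = background, offset = offset, seed = seed),
            class = "imaging_params")
}

#' Sample Piezo1 spot positions on a surface
#'
#' Draws point emitters on the discocyte surface by area-weighted rejection
#' sampling against a surface density (uniform, or a Boltzmann
#' \code{\link{boltzmann_density}} map).  Azimuths are uniform; meridian
#' positions are drawn with probability proportional to the local area
#' element and accepted with probability P/max(P).
#'
#' @param params a \code{\link{spot_gen_params}}.
#' @param surface a \code{"surface_field"} (uniform sampling) or
#'   \code{"density_map"}.
#' @param cell_id cell identifier attached to the output.
#' @return Object of class \code{"spot_set"}: data frame with
#'   \code{cell_id, x_um, y_um, z_um, intensity, region}; attributes record
#'   the generator parameters and seed.
#' @export
sample_spots <- function(params = spot_gen_params(), surface,
                         cell_id = 1L) {
  if (!inherits(surface, "surface_field"))
    stop("surface must be a surface_field or density_map")
  if (params$density == "map" && is.null(surface$P_per_um2))
    stop("density = 'map' requires a density_map surface (with P_per_um2)")
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_spots
  if (is.null(n)) n <- max(0L, round(stats::rnorm(1, 80.2, 26)))
  P <- if (params$density == "map") surface$P_per_um2
       else rep(1 / attr(surface, "total_area"), nrow(surface))
  Pmax <- max(P)
  idx <- integer(0)
  while (length(idx) < n) {
    cand <- sample.int(nrow(surface), size = max(2 * (n - length(idx)), 16),
                       replace = TRUE, prob = surface$dA_um2)
    keep <- stats::runif(length(cand)) < P[cand] / Pmax
    idx <- c(idx, cand[keep])
  }
  idx <- idx[seq_len(n)]
  phi <- stats::runif(n, 0, 2 * pi)
  out <- data.frame(
    cell_id = rep(cell_id, n),
    x_um = surface$rho_um[idx] * cos(phi),
    y_um = surface$rho_um[idx] * sin(phi),
    z_um = surface$z_um[idx],
    intensity = stats::rlnorm(n, 0, 0.15),
    region = ifelse(surface$H_per_um[idx] > 0, "dimple", "rim"))
  attr(out, "params") <- params
  attr(out, "sample_index") <- idx
  class(out) <- c("spot_set", "data.frame")
  out
}

## shared Gaussian-emitter renderer (3D when nz > 1)
.render_gaussians <- function(xs, ys, zs, amps, nx, ny, nz,
                              px_um, zs_um, origin, p) {
  sx <- p$psf_fwhm_nm / 2.35482 / 1000          # um
  sz <- p$psf_axial_fwhm_nm / 2.35482 / 1000
  img <- array(0, c(nx, ny, nz))
  wx <- ceiling(4 * sx / px_um)
  wz <- if (nz > 1) ceiling(4 * sz / zs_um) else 0L
  for (k in seq_along(xs)) {
    ix <- round((xs[k] - origin[1]) / px_um) + 1
    iy <- round((ys[k] - origin[2]) / px_um) + 1
    iz <- if (nz > 1) round((zs[k] - origin[3]) / zs_um) + 1 else 1L
    xr <- max(1, ix - wx):min(nx, ix + wx)
    yr <- max(1, iy - wx):min(ny, iy + wx)
    zr <- max(1, iz - wz):min(nz, iz + wz)
    if (!length(xr) || !length(yr) || !length(zr)) next
    gx <- exp(-((origin[1] + (xr - 1) * px_um) - xs[k])^2 / (2 * sx^2))
    gy <- exp(-((origin[2] + (yr - 1) * px_um) - ys[k])^2 / (2 * sx^2))
    gz <- if (nz > 1)
      exp(-((origin[3] + (zr - 1) * zs_um) - zs[k])^2 / (2 * sz^2)) else 1
    blk <- amps[k] * outer(outer(gx, gy), gz)
    img[xr, yr, zr] <- as.vector(img[xr, yr, zr]) + as.vector(blk)
  }
  img
}

#' Render a synthetic 3D image stack from spot emitters
#'
#' Places Gaussian-PSF emitters at the spot positions, applies Poisson shot
#' noise to (background + signal) and adds the camera offset.  The ground
#' truth is stored alongside the stack.
#'
#' @param spots a \code{\link{sample_spots}} spot set.
#' @param params an \code{\link{imaging_params}}.
#' @param margin_um field-of-view margin around the spots.
#' @param bounds_um optional list(x =, y =, z =) of c(min, max) extents (um);
#'   spots outside are an error.
#' @return A 3D array (x, y, z) of counts with attributes \code{px_nm},
#'   \code{z_step_nm}, \code{origin_um}, \code{truth} and \code{params}.
#' @export
render_stack <- function(spots, params = imaging_params(), margin_um = 0.6,
                         bounds_um = NULL) {
  if (!is.null(params$seed)) set.seed(params$seed)
  px <- params$px_nm / 1000
  zs <- params$z_step_nm / 1000
  if (is.null(bounds_um)) {
    bounds_um <- list(
      x = range(spots$x_um, 0) + c(-1, 1) * margin_um,
      y = range(spots$y_um, 0) + c(-1, 1) * margin_um,
      z = range(spots$z_um, 0) + c(-1, 1) * max(margin_um, 0.4))
  } else {
    oob <- spots$x_um < bounds_um$x[1] | spots$x_um > bounds_um$x[2] |
      spots$y_um < bounds_um$y[1] | spots$y_um > bounds_um$y[2] |
      spots$z_um < bounds_um$z[1] | spots$z_um > bounds_um$z[2]
    if (any(oob))
      stop("spots outside the field of view: rows ",
           paste(which(oob), collapse = ", "))
  }
  nx <- ceiling(diff(bounds_um$x) / px) + 1
  ny <- ceiling(diff(bounds_um$y) / px) + 1
  nz <- ceiling(diff(bounds_um$z) / zs) + 1
  origin <- c(bounds_um$x[1], bounds_um$y[1], bounds_um$z[1])
  sig <- .render_gaussians(spots$x_um, spots$y_um, spots$z_um,
                           params$photons * spots$intensity,
                           nx, ny, nz, px, zs, origin, params)
  img <- array(stats::rpois(length(sig), lambda = sig + params$background),
               dim(sig)) + params$offset
  attr(img, "px_nm") <- params$px_nm
  attr(img, "z_step_nm") <- params$z_step_nm
  attr(img, "origin_um") <- origin
  attr(img, "truth") <- spots
  attr(img, "params") <- params
  img
}

#' Track-generation parameters for hop diffusion
#'
#' A minimal membrane-skeleton model: Brownian steps inside square corrals of
#' side \code{corral_nm} with reflecting walls; at each boundary encounter
#' the walker crosses with probability \code{hop_prob}.  Positions are
#' corrupted by Gaussian localization noise.  An optional bias weight
#' modulates hop acceptance (Metropolis style), so long recordings can show
#' dimple preference.
#'
#' @param D_micro microscopic diffusivity (um^2/s), default 0.037.
#' @param corral_nm corral side (nm), default 500 (the scale of actin-spectrin voids).
#' @param hop_prob crossing probability per boundary encounter.
#' @param sigma_loc_nm localization noise SD (nm), default 20.
#' @param rate_hz frame rate (Hz).
#' @param duration_s recording duration (s); rate*duration must be integral.
#' @param n_tracks number of tracks.
#' @param geometry \code{"square"} corral lattice or a single reflecting
#'   \code{"circle"} of diameter \code{corral_nm}.
#' @param bias weight function w(x, y) (um coords) for biased hopping, or a
#'   \code{"density_map"} (projected through its upper-face radial profile),
#'   or NULL.
#' @param seed RNG seed.
#' @export
track_gen_params <- function(D_micro = 0.037, corral_nm = 500,
                             hop_prob = 0.07, sigma_loc_nm = 20,
                             rate_hz = 100, duration_s = 120, n_tracks = 14,
                             geometry = c("square", "circle"), bias = NULL,
                             seed = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(D_micro >= 0, corral_nm > 0, hop_prob >= 0, hop_prob <= 1,
            sigma_loc_nm >= 0, rate_hz > 0, duration_s > 0, n_tracks >= 1)
  nf <- rate_hz * duration_s
  if (abs(nf - round(nf)) > 1e-9)
    stop("rate_hz * duration_s must be an integer frame count")
  structure(list(D_micro = D_micro, corral_nm = corral_nm,
                 hop_prob = hop_prob, sigma_loc_nm = sigma_loc_nm,
                 rate_hz = rate_hz, duration_s = duration_s,
                 n_tracks = n_tracks, geometry = geometry, bias = bias,
                 seed = seed),
            class = "track_gen_params")
}

## radial bias weight from a density map's upper face
.bias_fun <- function(bias) {
  if (is.null(bias)) return(NULL)
  if (is.function(bias)) return(bias)
  if (inherits(bias, "density_map")) {
    up <- bias[bias$u <= pi / 2, ]
    f <- stats::approxfun(up$rho_um, up$P_per_um2, rule = 2)
    return(function(x, y) f(sqrt(x^2 + y^2)))
  }
  stop("bias must be NULL, a function(x, y), or a density_map")
}

#' Simulate hop-diffusion trajectories
#'
#' @param params a \code{\link{track_gen_params}}.
#' @return List of \code{\link{trajectory}} objects; attributes record the
#'   parameters, seed and the true (noise-free) positions.
#' @export
simulate_tracks <- function(params = track_gen_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  nf <- round(p$rate_hz * p$duration_s)
  dt <- 1 / p$rate_hz
  L <- p$corral_nm / 1000
  step_sd <- sqrt(2 * p$D_micro * dt)
  wfun <- .bias_fun(p$bias)
  nt <- p$n_tracks
  ## start each walker at a random point of its own corral (square) or at
  ## the centre region (circle); corral lattice is anchored at the origin
  if (p$geometry == "square") {
    x <- stats::runif(nt, 0, L); y <- stats::runif(nt, 0, L)
  } else {
    r0 <- (L / 2) * sqrt(stats::runif(nt)); a0 <- stats::runif(nt, 0, 2 * pi)
    x <- r0 * cos(a0); y <- r0 * sin(a0)
  }
  X <- matrix(0, nf, nt); Y <- matrix(0, nf, nt)
  X[1, ] <- x; Y[1, ] <- y
  reflect_axis <- function(cur, new) {
    cell <- floor(cur / L); newcell <- floor(new / L)
    crossed <- which(newcell != cell)
    if (length(crossed)) {
      hop <- stats::runif(length(crossed)) < p$hop_prob
      stay <- crossed[!hop]
      if (length(stay)) {
        b <- ifelse(new[stay] > cur[stay], (cell[stay] + 1) * L,
                    cell[stay] * L)
        new[stay] <- 2 * b - new[stay]
        ## outsized steps: clamp into the corral
        new[stay] <- pmin(pmax(new[stay], cell[stay] * L + 1e-12),
                          (cell[stay] + 1) * L - 1e-12)
      }
    }
    new
  }
  for (i in 2:nf) {
    nx <- x + stats::rnorm(nt, 0, step_sd)
    ny <- y + stats::rnorm(nt, 0, step_sd)
    if (p$geometry == "square") {
      if (is.null(wfun)) {
        nx <- reflect_axis(x, nx)
        ny <- reflect_axis(y, ny)
      } else {
        ## biased hopping: joint acceptance by density ratio
        cellx <- floor(x / L); celly <- floor(y / L)
        ncx <- floor(nx / L); ncy <- floor(ny / L)
        crossed <- which(ncx != cellx | ncy != celly)
        if (length(crossed)) {
          wnew <- wfun(nx[crossed], ny[crossed])
          wold <- wfun(x[crossed], y[crossed])
          acc <- stats::runif(length(crossed)) <
            p$hop_prob * pmin(1, wnew / pmax(wold, 1e-300))
          stay <- crossed[!acc]
          if (length(stay)) {
            bx <- ifelse(nx[stay] > x[stay], (cellx[stay] + 1) * L,
                         cellx[stay] * L)
            by <- ifelse(ny[stay] > y[stay], (celly[stay] + 1) * L,
                         celly[stay] * L)
            nx[stay] <- ifelse(ncx[stay] != cellx[stay],
                               2 * bx - nx[stay], nx[stay])
            ny[stay] <- ifelse(ncy[stay] != celly[stay],
                               2 * by - ny[stay], ny[stay])
            nx[stay] <- pmin(pmax(nx[stay], cellx[stay] * L + 1e-12),
                             (cellx[stay] + 1) * L - 1e-12)
            ny[stay] <- pmin(pmax(ny[stay], celly[stay] * L + 1e-12),
                             (celly[stay] + 1) * L - 1e-12)
          }
        }
      }
    } else {
      r <- sqrt(nx^2 + ny^2)
      out <- which(r > L / 2)
      if (length(out)) {          # radial reflection at the circle wall
        scl <- (L - r[out]) / r[out]
        scl <- pmax(scl, 1e-12)
        nx[out] <- nx[out] * scl
        ny[out] <- ny[out] * scl
      }
    }
    x <- nx; y <- ny
    X[i, ] <- x; Y[i, ] <- y
  }
  sl <- p$sigma_loc_nm / 1000
  tt <- (seq_len(nf) - 1) * dt
  tracks <- lapply(seq_len(nt), function(j) {
    trajectory(tt, X[, j] + stats::rnorm(nf, 0, sl),
               Y[, j] + stats::rnorm(nf, 0, sl),
               track_id = j, sigma_loc_nm = p$sigma_loc_nm)
  })
  attr(tracks, "params") <- p
  attr(tracks, "true_x") <- X
  attr(tracks, "true_y") <- Y
  tracks
}

#' Fixed-cell (immobile) control tracks
#'
#' Stationary emitters observed through localization noise only: the
#' paraformaldehyde-fixed control condition.  Their ensemble MSD plateaus at
#' \eqn{4\sigma_{loc}^2} for all positive lags.
#'
#' @param sigma_loc_nm localization noise SD (nm).
#' @param n number of tracks.
#' @param duration_s recording duration (s).
#' @param rate_hz frame rate (Hz).
#' @param seed RNG seed.
#' @return List of \code{\link{trajectory}} objects.
#' @export
fixed_cell_tracks <- function(sigma_loc_nm = 20, n = 5, duration_s = 120,
                              rate_hz = 100, seed = NULL) {
  if (sigma_loc_nm < 0) stop("sigma_loc_nm must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nf <- round(rate_hz * duration_s)
  sl <- sigma_loc_nm / 1000
  tt <- (seq_len(nf) - 1) / rate_hz
  tracks <- lapply(seq_len(n), function(j) {
    x0 <- stats::runif(1, -2, 2); y0 <- stats::runif(1, -2, 2)
    trajectory(tt, x0 + stats::rnorm(nf, 0, sl), y0 + stats::rnorm(nf, 0, sl),
               track_id = j, sigma_loc_nm = sigma_loc_nm)
  })
  attr(tracks, "params") <- list(sigma_loc_nm = sigma_loc_nm, n = n,
                                 duration_s = duration_s, rate_hz = rate_hz,
                                 seed = seed)
  tracks
}

#' Synthetic two-channel section pair for colocalization analysis
#'
#' Renders a 64 x 64 pixel (12.5 nm/px by default) two-channel section:
#' channel A spots are placed uniformly; a controllable fraction of channel B
#' spots is placed within \code{displacement_nm} of A spots and the rest
#' independently.
#'
#' @param colocalized_fraction fraction of B spots tied to A spots, in [0,1].
#' @param displacement_nm maximum offset of a colocalized B spot from its A
#'   partner (nm).
#' @param n_spots spots per channel.
#' @param params \code{\link{imaging_params}}; the default emulates a STED
#'   section (40 nm PSF, 12.5 nm pixels, low background).
#' @param npx section size in pixels (square), default 64.
#' @param seed RNG seed.
#' @return Object of class \code{"section_pair"}: list with matrices
#'   \code{A}, \code{B} (counts), \code{px_nm} and generator metadata.
#' @export
make_section_pair <- function(colocalized_fraction, displacement_nm = 25,
                              n_spots = 15,
                              params = imaging_params(psf_fwhm_nm = 40,
                                                      px_nm = 12.5,
                                                      photons = 200,
                                                      background = 2,
                                                      offset = 5),
                              npx = 64, seed = NULL) {
  if (colocalized_fraction < 0 || colocalized_fraction > 1)
    stop("colocalized_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  px <- params$px_nm / 1000
  side <- npx * px
  ax <- stats::runif(n_spots, 0, side); ay <- stats::runif(n_spots, 0, side)
  ncol_ <- round(colocalized_fraction * n_spots)
  bx <- by <- numeric(n_spots)
  if (ncol_ > 0) {
    pick <- sample.int(n_spots, ncol_, replace = ncol_ > n_spots)
    r <- (displacement_nm / 1000) * sqrt(stats::runif(ncol_))
    a <- stats::runif(ncol_, 0, 2 * pi)
    bx[seq_len(ncol_)] <- pmin(pmax(ax[pick] + r * cos(a), 0), side)
    by[seq_len(ncol_)] <- pmin(pmax(ay[pick] + r * sin(a), 0), side)
  }
  if (ncol_ < n_spots) {
    idx <- (ncol_ + 1):n_spots
    bx[idx] <- stats::runif(length(idx), 0, side)
    by[idx] <- stats::runif(length(idx), 0, side)
  }
  rend <- function(xs, ys) {
    sig <- .render_gaussians(xs, ys, rep(0, length(xs)),
                             rep(params$photons, length(xs)),
                             npx, npx, 1L, px, 1, c(0, 0, 0), params)[, , 1]
    matrix(stats::rpois(length(sig), sig + params$background),
           npx, npx) + params$offset
  }
  structure(list(A = rend(ax, ay), B = rend(bx, by), px_nm = params$px_nm,
                 meta = list(colocalized_fraction = colocalized_fraction,
                             displacement_nm = displacement_nm,
                             n_spots = n_spots, seed = seed),
                 truth = list(ax = ax, ay = ay, bx = bx, by = by)),
            class = "section_pair")
}
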