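#' Single-particle trajectory
#'
#' A timestamped 2D track in physical units.  Timestamps must be strictly
#' increasing; frame gaps are allowed and flagged.
#'
#' @param t_s time stamps (s).
#' @param x_um,y_um positions (um).
#' @param track_id identifier.
#' @param sigma_loc_nm known localization noise SD (nm), if any.
#' @return Object of class \code{"trajectory"} (a data frame with columns
#'   \code{track_id, frame, t_s, x_um, y_um}).
#' @export
trajectory <- function(t_s, x_um, y_um, track_id = 1L, sigma_loc_nm = NA_real_) {
  stopifnot(length(t_s) == length(x_um), length(t_s) == length(y_um))
  if (length(t_s) == 0) stop("empty track rejected")
  dt <- diff(t_s)
  if (any(dt <= 0))
    stop("non-monotone time at row ", which(dt <= 0)[1] + 1)
  tr <- data.frame(track_id = track_id, frame = seq_along(t_s),
                   t_s = t_s, x_um = x_um, y_um = y_um)
  attr(tr, "dt_s") <- stats::median(dt)
  attr(tr, "has_gaps") <- length(dt) > 0 &&
    any(abs(dt / stats::median(dt) - 1) > 0.01)
  attr(tr, "sigma_loc_nm") <- sigma_loc_nm
  class(tr) <- c("trajectory", "data.frame")
  tr
}

#' Time-averaged mean squared displacement
#'
#' Per track, the time-averaged MSD at lag \eqn{k\,dt} over all ordered frame
#' pairs; the ensemble curve is the unweighted mean of the per-track curves
#' at each lag.  Lags exceeding a track's length are dropped for that track,
#' never zero-filled.
#'
#' @param tracks a \code{"trajectory"} or list of them.
#' @param max_lag largest lag to evaluate (s); default a quarter of the
#'   longest track (time-averaged MSDs at longer lags are poorly averaged).
#' @return Object of class \code{"msd_curve"}: data frame with
#'   \code{lag_s}, \code{msd_um2} (ensemble mean), \code{n_pairs},
#'   \code{n_tracks}; attribute \code{per_track} holds the per-track curves.
#' @export
msd <- function(tracks, max_lag = NULL) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  stopifnot(length(tracks) > 0)
  for (tr in tracks) if (nrow(tr) < 2) stop("each track needs >= 2 frames")
  dt <- attr(tracks[[1]], "dt_s")
  if (is.null(dt)) dt <- stats::median(diff(tracks[[1]]$t_s))
  if (is.null(max_lag))
    max_lag <- dt * max(vapply(tracks, nrow, 1L)) / 4
  K <- max(1L, floor(max_lag / dt + 1e-9))
  per <- matrix(NA_real_, K, length(tracks))
  npair <- matrix(0, K, length(tracks))
  for (j in seq_along(tracks)) {
    x <- tracks[[j]]$x_um; y <- tracks[[j]]$y_um
    n <- length(x)
    for (k in seq_len(min(K, n - 1L))) {
      dx <- x[(k + 1):n] - x[1:(n - k)]
      dy <- y[(k + 1):n] - y[1:(n - k)]
      per[k, j] <- mean(dx * dx + dy * dy)
      npair[k, j] <- n - k
    }
  }
  out <- data.frame(lag_s = dt * seq_len(K),
                    msd_um2 = rowMeans(per, na.rm = TRUE),
                    n_pairs = rowSums(npair),
                    n_tracks = rowSums(!is.na(per)))
  out <- out[out$n_tracks > 0, , drop = FALSE]
  attr(out, "per_track") <- per
  attr(out, "dt_s") <- dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags (dt = %.4g s), %d track(s)\n",
              nrow(x), attr(x, "dt_s"), max(x$n_tracks)))
  invisible(x)
}

#' Fit a diffusion coefficient to an MSD window
#'
#' Ordinary least squares of the ensemble MSD against lag time over the
#' requested window, with a free intercept (which absorbs the localization
#' noise floor); the 2D diffusion coefficient is slope/4.  The two windows
#' of interest are 5 s (macroscopic, corral-to-corral) and 50 ms
#' (microscopic, within-corral) diffusion.
#'
#' @param curve an \code{\link{msd}} curve.
#' @param window fit window (s), e.g. 5 or 0.05.
#' @return Object of class \code{"diffusion_fit"}: \code{D_um2_s},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{window_s},
#'   \code{negative_slope} flag.
#' @export
fit_diffusion <- function(curve, window) {
  sel <- curve$lag_s <= window + 1e-12
  if (sum(sel) < 3) stop("need >= 3 lag points inside the fit window")
  fit <- stats::lm(msd_um2 ~ lag_s, data = curve[sel, ])
  sl <- unname(coef(fit)[2])
  out <- list(D_um2_s = sl / 4, slope = sl,
              intercept = unname(coef(fit)[1]),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              window_s = window, n_points = sum(sel),
              negative_slope = sl < 0)
  if (out$negative_slope)
    warning("negative fitted MSD slope; D reported as non-positive")
  class(out) <- "diffusion_fit"
  out
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion fit (window %.3g s, %d lags): D = %.4g um^2/s (R^2 = %.3f)\n",
              x$window_s, x$n_points, x$D_um2_s, x$r_squared))
  invisible(x)
}

#' Confinement analysis of an MSD curve
#'
#' Fits the saturating model
#' \eqn{MSD(\tau) = A(1 - e^{-\tau/\tau_c}) + 4\sigma_{loc}^2} and compares it
#' against a straight line by AIC.  For diffusion confined to a circular
#' domain the plateau equals the squared domain radius, so the confinement
#' diameter is \eqn{L = 2\sqrt{A}}.
#'
#' @param curve an \code{\link{msd}} curve reaching beyond the initial linear
#'   regime.
#' @return Object of class \code{"confinement_fit"}: \code{confined} flag,
#'   \code{plateau_um2}, \code{L_nm} (confinement diameter),
#'   \code{tau_c_s}, \code{offset_um2} (the fitted noise floor
#'   \eqn{4\sigma_{loc}^2}) and the AIC difference.
#' @export
confinement_fit <- function(curve) {
  d <- data.frame(tau = curve$lag_s, m = curve$msd_um2)
  lin <- stats::lm(m ~ tau, data = d)
  A0 <- max(d$m); tc0 <- d$tau[min(which(d$m > 0.63 * A0), nrow(d))]
  sat <- tryCatch(
    minpack.lm::nlsLM(m ~ A * (1 - exp(-tau / tc)) + c0, data = d,
                      start = list(A = A0, tc = max(tc0, d$tau[1]), c0 = 0),
                      lower = c(0, d$tau[1] / 10, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(sat)) {
    out <- list(confined = FALSE, plateau_um2 = NA_real_, L_nm = NA_real_,
                tau_c_s = NA_real_, offset_um2 = NA_real_,
                delta_aic = NA_real_,
                note = "saturating fit did not converge")
    class(out) <- "confinement_fit"
    return(out)
  }
  daic <- stats::AIC(lin) - stats::AIC(sat)
  cf <- coef(sat)
  ## also require the plateau to be reached inside the observed lags
  confined <- daic > 2 && cf[["tc"]] < max(d$tau) / 2
  out <- list(confined = confined,
              plateau_um2 = unname(cf[["A"]]),
              L_nm = 2 * sqrt(unname(cf[["A"]])) * 1000,
              tau_c_s = unname(cf[["tc"]]),
              offset_um2 = unname(cf[["c0"]]),
              delta_aic = daic)
  class(out) <- "confinement_fit"
  out
}

#' @export
print.confinement_fit <- function(x, ...) {
  if (x$confined)
    cat(sprintf("Confined: diameter L = %.0f nm (tau_c = %.3g s, dAIC = %.1f)\n",
                x$L_nm, x$tau_c_s, x$delta_aic))
  else
    cat(sprintf("Unconfined (dAIC = %.3g)%s\n", x$delta_aic,
                if (!is.null(x$note)) paste0("; ", x$note) else ""))
  invisible(x)
}

#' Dimple occupancy of a trajectory
#'
#' Fraction of frames within a circle approximating the dimple (default
#' radius 1.13 um) about the cell center.  If no center is supplied it is
#' estimated as the centroid of the track's convex hull.
#'
#' @param track a \code{"trajectory"}.
#' @param center cell center \code{c(x, y)} (um), or NULL to estimate.
#' @param radius dimple circle radius (um), default 1.13.
#' @return Object of class \code{"occupancy_result"}: \code{fraction},
#'   \code{center}, \code{radius_um}, \code{n_frames},
#'   \code{center_estimated}.
#' @export
dimple_occupancy <- function(track, center = NULL, radius = 1.13) {
  if (nrow(track) == 0) stop("empty track rejected")
  est <- is.null(center)
  if (est) {
    hull <- grDevices::chull(track$x_um, track$y_um)
    center <- c(mean(track$x_um[hull]), mean(track$y_um[hull]))
  }
  r <- sqrt((track$x_um - center[1])^2 + (track$y_um - center[2])^2)
  out <- list(fraction = mean(r <= radius), center = center,
              radius_um = radius, n_frames = nrow(track),
              center_estimated = est)
  class(out) <- "occupancy_result"
  out
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("Occupancy: %.1f%% of %d frames within %.3g um of (%.3g, %.3g)%s\n",
              100 * x$fraction, x$n_frames, x$radius_um,
              x$center[1], x$center[2],
              if (x$center_estimated) " [center estimated]" else ""))
  invisible(x)
}

#' Mean dispersion time for 3D diffusion
#'
#' The time for a diffusing species to equilibrate over a distance x in three
#' dimensions, \eqn{\tau = x^2 / 6D}.  With the intracellular Ca2+ diffusion
#' coefficient (13-65 um^2/s) and cell-scale distances this is tens of
#' milliseconds, which is why Piezo1 and the Gardos channel need not
#' colocalize for their ion fluxes to couple.
#'
#' @param x distance (um), >= 0.
#' @param D diffusion coefficient (um^2/s), > 0.
#' @return Time in seconds.
#' @examples
#' dispersion_time(2, 13)    # ~0.05 s
#' @export
dispersion_time <- function(x, D) {
  if (any(x < 0)) stop("x must be >= 0")
  if (any(D <= 0)) stop("D must be > 0")
  x^2 / (6 * D)
}
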