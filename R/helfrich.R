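#' Piezo dome parameters
#'
#' The Piezo1 trimer imposes a dome — an approximately spherical cap — on its
#' local membrane.  The cap area is fixed; the radius of curvature can flex
#' about its intrinsic (relaxed, planar-membrane) value at an energetic cost
#' set by the dome bending modulus.
#'
#' @param S_cap cap area (nm^2), default 450.
#' @param R_P0 intrinsic radius of curvature (nm), default 42.
#' @param K_P dome bending modulus (kBT), default 20.
#' @return Object of class \code{"piezo_dome"}.
#' @export
piezo_dome <- function(S_cap = 450, R_P0 = 42, K_P = 20) {
  stopifnot(S_cap > 0, R_P0 > 0, K_P > 0)
  if (S_cap > 4 * pi * R_P0^2)
    stop("infeasible cap: S_cap exceeds the full sphere area 4*pi*R_P0^2")
  structure(list(S_cap = S_cap, R_P0 = R_P0, K_P = K_P),
            class = "piezo_dome")
}

#' @export
print.piezo_dome <- function(x, ...) {
  g <- cap_geometry(x$S_cap, x$R_P0)
  cat(sprintf(
    "Piezo dome: cap area %.4g nm^2, intrinsic radius %.4g nm (K_P = %.3g kBT)\n",
    x$S_cap, x$R_P0, x$K_P))
  cat(sprintf("  half-angle %.2f deg, base radius %.2f nm, height %.2f nm\n",
              g$half_angle * 180 / pi, g$base_radius, g$height))
  invisible(x)
}

#' Spherical cap geometry
#'
#' For a spherical cap of area \code{S_cap} on a sphere of radius \code{R}:
#' half-angle from \eqn{S = 2\pi R^2 (1-\cos\theta)}, base radius
#' \eqn{R\sin\theta} and height \eqn{R(1-\cos\theta)}.
#'
#' @param S_cap cap area (nm^2).
#' @param R radius of curvature (nm).
#' @return List with \code{half_angle} (rad), \code{base_radius} and
#'   \code{height} (nm).
#' @examples
#' cap_geometry(450, 42)   # theta ~ 16.4 deg, base ~ 11.9 nm
#' @export
cap_geometry <- function(S_cap, R) {
  if (S_cap < 0 || S_cap > 4 * pi * R^2)
    stop("infeasible cap: need 0 <= S_cap <= 4*pi*R^2")
  ct <- 1 - S_cap / (2 * pi * R^2)
  theta <- acos(pmin(pmax(ct, -1), 1))
  list(half_angle = theta, base_radius = R * sin(theta),
       height = R * (1 - cos(theta)))
}

#' Vesicle problem for the curvature-coupling energy
#'
#' Each point of the cell surface with signed mean curvature \code{H_rbc} is
#' associated with a closed vesicle whose radius, if spherical, is
#' \eqn{1/|H|}; the vesicle area equals the free membrane area plus the dome
#' cap area.  The dome is mounted inside-out (matching the vesicle curvature
#' orientation) where the sign of \code{H_rbc} matches the dome's
#' concave-outside orientation (H > 0), and outside-out otherwise.
#'
#' @param H_rbc signed mean curvature (1/um); |H| must exceed \code{H_floor}.
#' @param dome a \code{\link{piezo_dome}}.
#' @param Kb lipid bilayer bending modulus (kBT), default 20.
#' @param H_floor small-curvature floor (1/um) below which the vesicle radius
#'   diverges and the planar-limit branch is used instead (see
#'   \code{\link{energy_vs_curvature}}).
#' @return Object of class \code{"vesicle_problem"}.
#' @export
vesicle_problem <- function(H_rbc, dome = piezo_dome(), Kb = 20,
                            H_floor = 0.01) {
  stopifnot(is.finite(H_rbc), Kb > 0)
  if (abs(H_rbc) < H_floor)
    stop("|H_rbc| below the small-curvature floor; use the planar branch ",
         "(energy_vs_curvature interpolates across it)")
  R_v <- 1 / abs(H_rbc)                      # um
  A_ves <- 4 * pi * R_v^2                    # um^2
  free_area <- A_ves - dome$S_cap * 1e-6     # um^2
  if (free_area <= 0) stop("infeasible: vesicle smaller than the dome cap")
  structure(list(H_rbc = H_rbc, R_v_um = R_v, A_ves_um2 = A_ves,
                 free_area_um2 = free_area, Kb = Kb,
                 orientation = if (H_rbc > 0) "inside-out" else "outside-out"),
            class = "vesicle_problem")
}

## ---------------------------------------------------------------------------
## Core shooting solve, in units of the vesicle radius (bending energy is
## scale invariant, so the scaled solution carries the energy in units of Kb).
## Unknowns: pole curvature u0, area multiplier sigma, meridian length L.
## Endpoint targets: r = (cap base radius)/R_v, psi = pi - chi with chi the
## signed contact angle (+theta matched orientation, -theta reversed), and
## accumulated area = (vesicle area - cap area)/R_v^2.
## Continuation starts from the exactly solvable tangent-sphere configuration
## and walks the contact angle to its target.
.helfrich_solve <- function(H, R_dome = 42, S_cap = 450, Kb = 20,
                            tol = 1e-11, warm = NULL) {
  stopifnot(abs(H) > 0)
  Rv <- 1000 / abs(H)                        # nm
  th <- cap_geometry(S_cap, R_dome)$half_angle
  rb <- R_dome * sin(th) / Rv
  Af <- 4 * pi - S_cap / Rv^2
  chi_t <- if (H > 0) th else -th
  resid <- function(x, chi) {
    v <- helfrich_shoot(x[1], x[2], x[3], tol)
    if (v[7] < 1) return(rep(1e6, 3))
    c((v[4] - rb) / rb, v[1] - (pi - chi), (v[5] - Af) / Af)
  }
  newton <- function(x, chi, maxit = 25) {
    r <- resid(x, chi)
    for (it in seq_len(maxit)) {
      if (max(abs(r)) < 1e-9)
        return(list(x = x, ok = TRUE, r = r))
      J <- matrix(0, 3, 3)
      for (j in 1:3) {
        h <- 1e-7 * max(abs(x[j]), 1e-3)
        xj <- x; xj[j] <- xj[j] + h
        J[, j] <- (resid(xj, chi) - r) / h
      }
      st <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(st)) return(list(x = x, ok = FALSE, r = r))
      lam <- 1
      repeat {
        xn <- x + lam * st
        rn <- resid(xn, chi)
        if (sum(rn^2) < sum(r^2) || lam < 1e-3) break
        lam <- lam / 2
      }
      if (sum(rn^2) >= sum(r^2))
        return(list(x = x, ok = max(abs(r)) < 1e-7, r = r))
      x <- xn; r <- rn
    }
    list(x = x, ok = max(abs(r)) < 1e-7, r = r)
  }
  sol <- NULL
  if (!is.null(warm)) {
    s <- newton(warm, chi_t)
    if (s$ok) sol <- s
  }
  if (is.null(sol)) {
    f <- function(rho) 2 * pi * rho^2 * (1 + sqrt(1 - (rb / rho)^2)) - Af
    rho0 <- stats::uniroot(f, c(0.8, 1.2), tol = 1e-14)$root
    chi0 <- asin(rb / rho0)
    x <- c(1 / rho0, 0, rho0 * (pi - chi0))
    chi <- chi0
    dchi <- 0.05 * sign(chi_t - chi0)
    nfail <- 0
    while (abs(chi - chi_t) > 1e-14) {
      chin <- if (abs(chi_t - chi) <= abs(dchi)) chi_t else chi + dchi
      s <- newton(x, chin)
      if (s$ok) {
        x <- s$x; chi <- chin
        dchi <- 1.5 * dchi
        if (abs(dchi) > 0.1) dchi <- 0.1 * sign(dchi)
      } else {
        dchi <- dchi / 2
        nfail <- nfail + 1
        if (nfail > 60)
          stop(sprintf(
            "free-membrane minimization did not converge at H = %.4g (stalled at contact angle %.4g; residuals %s)",
            H, chi, paste(signif(s$r, 3), collapse = ", ")))
      }
    }
    sol <- newton(x, chi_t)
  }
  v <- helfrich_shoot(sol$x[1], sol$x[2], sol$x[3], tol)
  list(G_kBT = v[6] * Kb, x = sol$x, sigma = sol$x[2], residuals = sol$r,
       Rv_nm = Rv, rb = rb, chi = chi_t, ok = sol$ok)
}

#' Minimum bending energy of the free membrane around the Piezo dome
#'
#' Minimizes the Helfrich bending energy \eqn{(K_b/2)\int (c_1+c_2)^2\,dA}
#' over axisymmetric free-membrane shapes of fixed total area, closing
#' smoothly at the pole opposite the dome and meeting the dome edge with
#' continuous position and tangent angle.  The Euler-Lagrange boundary-value
#' problem is solved by shooting from the regular pole with continuation in
#' the contact angle; the area constraint enters through its Lagrange
#' multiplier (a tension-like quantity reported as \code{sigma}).
#'
#' @param problem a \code{\link{vesicle_problem}}.
#' @param dome a \code{\link{piezo_dome}}.
#' @param rigid_dome_radius dome radius of curvature to hold fixed (nm);
#'   defaults to the intrinsic radius.
#' @param tol integrator tolerance (scaled variables).
#' @param trace_n if positive, also return the meridian shape sampled at this
#'   many arclength points.
#' @return Object of class \code{"free_membrane_fit"}: \code{G_free} (kBT),
#'   shooting diagnostics, and optionally \code{shape} (a data frame with
#'   \code{s_nm, r_nm, z_nm, psi}).
#' @examples
#' ## matched curvature: the vesicle stays spherical and the energy equals
#' ## 8*pi*Kb*(free area / vesicle area)
#' p <- vesicle_problem(1000 / 42)
#' fit <- minimize_free_membrane(p)
#' fit$G_free
#' @export
minimize_free_membrane <- function(problem, dome = piezo_dome(),
                                   rigid_dome_radius = dome$R_P0,
                                   tol = 1e-11, trace_n = 0) {
  sol <- .helfrich_solve(problem$H_rbc, R_dome = rigid_dome_radius,
                         S_cap = dome$S_cap, Kb = problem$Kb, tol = tol)
  out <- list(G_free = sol$G_kBT, sigma = sol$sigma, x = sol$x,
              residuals = sol$residuals, problem = problem,
              dome_radius = rigid_dome_radius)
  if (trace_n > 0) {
    tr <- helfrich_trace(sol$x[1], sol$x[2], sol$x[3], as.integer(trace_n))
    z0 <- cumsum(c(0, diff(tr[, "s"]) *
                     sin((tr[-1, "psi"] + tr[-nrow(tr), "psi"]) / 2)))
    out$shape <- data.frame(s_nm = tr[, "s"] * sol$Rv_nm,
                            r_nm = tr[, "r"] * sol$Rv_nm,
                            z_nm = z0 * sol$Rv_nm,
                            psi = tr[, "psi"])
  }
  class(out) <- "free_membrane_fit"
  out
}

#' @export
print.free_membrane_fit <- function(x, ...) {
  cat(sprintf(
    "Free-membrane Helfrich minimum: G = %.6f kBT at H = %+.4g 1/um (%s)\n",
    x$G_free, x$problem$H_rbc, x$problem$orientation))
  cat(sprintf("  dome radius %.4g nm, area multiplier sigma = %.3e Kb/Rv^2\n",
              x$dome_radius, x$sigma))
  invisible(x)
}

#' Curvature-coupling energy profile G(H)
#'
#' Solves the free-membrane minimization over a grid of cell-surface mean
#' curvatures, applying the orientation rule per sign of H.  Inside the
#' small-curvature floor \code{(-H_floor, H_floor)}, where the vesicle radius
#' diverges, the profile takes the planar-limit branch: G is aligned by
#' linear interpolation between the solves at -H_floor and +H_floor (only
#' energy differences enter the Boltzmann map, so the alignment constant is
#' immaterial).  Off-grid evaluation uses monotone (Fritsch-Carlson) cubic
#' interpolation.
#'
#' @param H_grid curvature grid (1/um); default 25 points on [-0.6, 0.3].
#' @param dome a \code{\link{piezo_dome}}.
#' @param Kb bilayer bending modulus (kBT).
#' @param flex if TRUE also record the flexible-dome optimal radius R_opt(H)
#'   and use the flexed (joint-minimum) energy for G.
#' @param H_floor small-curvature floor (1/um).
#' @param tol integrator tolerance.
#' @return Object of class \code{"energy_profile"}: data frame with
#'   \code{H_per_um}, \code{G_kBT} (and \code{R_opt_nm} when \code{flex});
#'   attribute \code{fun} is the interpolating function G(H).
#' @export
energy_vs_curvature <- function(H_grid = seq(-0.6, 0.3, length.out = 25),
                                dome = piezo_dome(), Kb = 20, flex = FALSE,
                                H_floor = 0.01, tol = 1e-11) {
  H_grid <- sort(unique(c(H_grid, -H_floor, H_floor)))
  G <- rep(NA_real_, length(H_grid))
  Ropt <- rep(NA_real_, length(H_grid))
  solve_one <- function(H, warm) {
    if (flex) {
      fx <- flex_dome(H, dome, Kb, tol = tol)
      list(G = fx$G_total, R = fx$R_opt, x = NULL)
    } else {
      s <- .helfrich_solve(H, R_dome = dome$R_P0, S_cap = dome$S_cap,
                           Kb = Kb, tol = tol, warm = warm)
      list(G = s$G_kBT, R = dome$R_P0, x = s$x)
    }
  }
  outer_idx <- which(abs(H_grid) >= H_floor - 1e-12)
  ## march positive H downward and negative H downward, warm-starting
  warm <- NULL
  for (i in rev(outer_idx[H_grid[outer_idx] > 0])) {
    s <- tryCatch(solve_one(H_grid[i], warm), error = function(e)
      stop("energy profile failed at H = ", signif(H_grid[i], 4), ": ",
           conditionMessage(e)))
    G[i] <- s$G; Ropt[i] <- s$R; warm <- s$x
  }
  warm <- NULL
  for (i in rev(outer_idx[H_grid[outer_idx] < 0])) {
    s <- tryCatch(solve_one(H_grid[i], warm), error = function(e)
      stop("energy profile failed at H = ", signif(H_grid[i], 4), ": ",
           conditionMessage(e)))
    G[i] <- s$G; Ropt[i] <- s$R; warm <- s$x
  }
  ## planar branch: align across the floor by linear interpolation
  inner <- is.na(G)
  if (any(inner)) {
    iL <- which(abs(H_grid + H_floor) < 1e-12)
    iR <- which(abs(H_grid - H_floor) < 1e-12)
    w <- (H_grid[inner] - H_grid[iL]) / (H_grid[iR] - H_grid[iL])
    G[inner] <- (1 - w) * G[iL] + w * G[iR]
    Ropt[inner] <- (1 - w) * Ropt[iL] + w * Ropt[iR]
  }
  prof <- data.frame(H_per_um = H_grid, G_kBT = G)
  if (flex) prof$R_opt_nm <- Ropt
  attr(prof, "fun") <- stats::splinefun(H_grid, G, method = "monoH.FC")
  attr(prof, "range") <- range(H_grid)
  attr(prof, "dome") <- dome
  attr(prof, "Kb") <- Kb
  class(prof) <- c("energy_profile", "data.frame")
  prof
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("Curvature-coupling energy profile: %d grid points on [%.3g, %.3g] 1/um\n",
              nrow(x), min(x$H_per_um), max(x$H_per_um)))
  cat(sprintf("  G spans %.4f kBT (decreasing toward dimple-like curvature)\n",
              max(x$G_kBT) - min(x$G_kBT)))
  invisible(x)
}

#' Flexible-dome joint minimization
#'
#' Jointly minimizes the free-membrane bending energy and the dome flexure
#' energy over the dome radius of curvature R at fixed cap area:
#' \deqn{G_{tot}(R) = G_{free}(H; R) + \tfrac{K_P}{2} S_{cap}
#'       \left(\frac{2}{R} - \frac{2}{R_{P0}}\right)^2.}
#' In the rigid limit (K_P large) the optimum returns to the intrinsic
#' radius.  The search reports both minima if the energy in R is found to be
#' multi-modal on the bracket.
#'
#' @param H_rbc signed mean curvature (1/um).
#' @param dome a \code{\link{piezo_dome}} (supplies S_cap, R_P0, K_P).
#' @param Kb bilayer bending modulus (kBT).
#' @param bracket search interval for R (nm).
#' @param tol integrator tolerance.
#' @return List with \code{R_opt} (nm), \code{G_total}, \code{G_free},
#'   \code{G_dome} (kBT).
#' @examples
#' \donttest{
#' flex_dome(0.24)$R_opt    # ~41.6 nm: flexes toward the dimple curvature
#' }
#' @export
flex_dome <- function(H_rbc, dome = piezo_dome(), Kb = 20,
                      bracket = c(36, 50), tol = 1e-11) {
  warm_env <- new.env()
  gfree <- function(R) {
    s <- .helfrich_solve(H_rbc, R_dome = R, S_cap = dome$S_cap, Kb = Kb,
                         tol = tol, warm = warm_env$x)
    warm_env$x <- s$x
    s$G_kBT
  }
  gdome <- function(R) (dome$K_P / 2) * dome$S_cap * (2 / R - 2 / dome$R_P0)^2
  gtot <- function(R) gfree(R) + gdome(R)
  ## coarse modality scan, then a golden-section refinement
  Rs <- seq(bracket[1], bracket[2], length.out = 8)
  Gs <- vapply(Rs, gtot, numeric(1))
  imin <- which.min(Gs)
  interior_minima <- sum(diff(sign(diff(Gs))) > 0)
  if (interior_minima > 1)
    stop("dome flexure energy is multi-modal in R on the bracket; minima near R = ",
         paste(signif(Rs[which(diff(sign(diff(Gs))) > 0) + 1], 4),
               collapse = ", "))
  lo <- Rs[max(1, imin - 1)]; hi <- Rs[min(length(Rs), imin + 1)]
  opt <- stats::optimize(gtot, c(lo, hi), tol = 1e-5)
  R_opt <- opt$minimum
  list(R_opt = R_opt, G_total = opt$objective, G_free = gfree(R_opt),
       G_dome = gdome(R_opt), H_rbc = H_rbc)
}
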