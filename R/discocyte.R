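#' Biconcave discocyte surface models
#'
#' Two axisymmetric parameterizations of the resting (discocyte) shape of a
#' red blood cell are provided.
#'
#' The default, \code{discocyte_arcs()}, is a piecewise-circular construction:
#' each face of the dimple is a spherical cap that joins tangentially onto a
#' toroidal rim.  Given the cell radius \code{R0}, the rim tube radius
#' \code{a} (half the maximum thickness) and the half central thickness
#' \code{h0}, tangency fixes the dimple sphere radius
#' \deqn{R_d = \frac{(R_0-a)^2 + h_0^2 - a^2}{2(a - h_0)}.}
#' For the standard human/mouse cell (diameter 8 um, central thickness 1 um,
#' maximum thickness 2.5 um) this gives \eqn{R_d = 25/6} um, a dimple mean
#' curvature of exactly +0.24 1/um, a rim equator mean curvature of
#' -0.525 1/um, and a closed-surface area of 137.98 um^2.
#'
#' \code{discocyte_quartic()} is the familiar smooth quartic profile
#' \deqn{z(\rho) = \tfrac12 \sqrt{1-(\rho/R_0)^2}\,
#'       (C_0 + C_2 (\rho/R_0)^2 + C_4 (\rho/R_0)^4),}
#' mirrored about the equatorial plane; the coefficients multiply a 1 um unit
#' scale so the central thickness is exactly \code{C0}.
#'
#' The curvature sign convention throughout the package makes the mean
#' curvature positive where the surface is concave toward the cell exterior:
#' the dimple carries H > 0, the convex rim H < 0, and a sphere has
#' H = -1/R everywhere.
#'
#' @param R0 equatorial radius (um), half the cell diameter.
#' @param a rim tube radius (um), half the maximum thickness.
#' @param h0 half the central (dimple) thickness (um).
#' @param C0,C2,C4 quartic profile coefficients (um); \code{C0} equals the
#'   central thickness.
#' @return An object of class \code{"discocyte"}.
#' @examples
#' d <- discocyte_arcs(4, 1.25, 0.5)
#' surface_area(d)                      # ~138 um^2
#' @name discocyte
NULL

#' @rdname discocyte
#' @export
discocyte_arcs <- function(R0, a, h0) {
  stopifnot(R0 > 0, a > 0, h0 > 0, a < R0, h0 < a)
  cc <- R0 - a
  Rd <- (cc^2 + h0^2 - a^2) / (2 * (a - h0))
  if (Rd <= 0) stop("infeasible dimensions: dimple sphere radius <= 0")
  zc <- h0 + Rd                       # dimple sphere center height
  dd <- sqrt(cc^2 + zc^2)             # = Rd + a at exact tangency
  rt <- cc * Rd / dd                  # tangency radius
  zt <- zc * (1 - Rd / dd)
  phi_t <- acos((rt - cc) / a)        # tube angle at tangency
  theta_cap <- asin(rt / Rd)          # cap polar angle at tangency
  s_cap <- Rd * theta_cap             # meridian arclengths of the pieces
  s_tor <- 2 * a * phi_t
  structure(list(profile = "arcs", R0 = R0, a = a, h0 = h0, Rd = Rd,
                 c = cc, zc = zc, rho_t = rt, z_t = zt,
                 phi_t = phi_t, theta_cap = theta_cap,
                 s_cap = s_cap, s_tor = s_tor, s_half = s_cap + a * phi_t,
                 sign_convention = "H>0 concave toward exterior"),
            class = "discocyte")
}

#' @rdname discocyte
#' @export
discocyte_quartic <- function(R0, C0, C2, C4) {
  stopifnot(is.finite(R0), R0 > 0, is.finite(C0), C0 > 0,
            is.finite(C2), is.finite(C4))
  x2 <- seq(0, 1, length.out = 2001)
  q <- C0 + C2 * x2 + C4 * x2^2
  if (any(q < -1e-9))
    stop("invalid profile: z(rho) < 0 somewhere in [0, R0]")
  structure(list(profile = "quartic", R0 = R0, C0 = C0, C2 = C2, C4 = C4,
                 sign_convention = "H>0 concave toward exterior"),
            class = "discocyte")
}

#' @export
print.discocyte <- function(x, ...) {
  if (x$profile == "arcs") {
    cat("Biconcave discocyte (tangent sphere-torus construction)\n")
    cat(sprintf("  R0 = %.4g um, rim tube radius %.4g um, dimple sphere radius %.6g um\n",
                x$R0, x$a, x$Rd))
  } else {
    cat("Biconcave discocyte (quartic profile)\n")
    cat(sprintf("  R0 = %.4g um, C0 = %.6g, C2 = %.6g, C4 = %.6g um\n",
                x$R0, x$C0, x$C2, x$C4))
  }
  b <- biconcavity_ratio(x)
  cat(sprintf("  central thickness %.4g um, max thickness %.4g um (a/b = %.3g)\n",
              b$b, b$a, b$ratio))
  cat(sprintf("  surface area %.6g um^2\n", surface_area(x)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Meridian parameterization u in [0, pi], top pole -> bottom pole.
## Quartic: rho = R0 sin u, z = (1/2) cos(u) Q(sin^2 u) -- regular at the
## axis and the equator.  Arcs: u proportional to meridian arclength.
## Returns position, parameter-derivatives, metric g = |d(rho,z)/du| and the
## two principal curvatures under the package sign convention.
meridian_eval <- function(model, u) {
  if (model$profile == "quartic") meridian_quartic(model, u)
  else meridian_arcs(model, u)
}

meridian_quartic <- function(model, u) {
  R0 <- model$R0
  su <- sin(u); cu <- cos(u)
  y <- su^2
  Q   <- model$C0 + model$C2 * y + model$C4 * y^2
  Qp  <- model$C2 + 2 * model$C4 * y
  Qpp <- 2 * model$C4
  s2u <- sin(2 * u); c2u <- cos(2 * u)
  rho <- R0 * su
  z   <- 0.5 * cu * Q
  rp  <- R0 * cu
  rpp <- -R0 * su
  zp  <- 0.5 * (-su * Q + cu * Qp * s2u)
  zpp <- 0.5 * (-cu * Q - 2 * su * s2u * Qp + cu * s2u^2 * Qpp +
                  2 * cu * c2u * Qp)
  g <- sqrt(rp^2 + zp^2)
  c1 <- (rp * zpp - zp * rpp) / g^3        # meridional principal curvature
  c2c <- zp / (rho * g)                    # azimuthal principal curvature
  pole <- su < 1e-8                        # analytic limit: c1 = c2 there
  if (any(pole)) {
    cpole <- (model$C2 - model$C0 / 2) / R0^2
    c1[pole] <- cpole
    c2c[pole] <- cpole
  }
  list(u = u, rho = rho, z = z, g = g, c1 = c1, c2 = c2c,
       H = (c1 + c2c) / 2)
}

meridian_arcs <- function(model, u) {
  S <- 2 * model$s_half
  s <- u / pi * S                          # arclength from the top pole
  g <- rep(S / pi, length(u))
  ## mirror the lower half onto the upper one, remember the face
  lower <- s > model$s_half
  sm <- ifelse(lower, S - s, s)
  rho <- z <- c1 <- c2c <- numeric(length(u))
  on_cap <- sm <= model$s_cap
  ## dimple spherical cap
  th <- sm[on_cap] / model$Rd
  rho[on_cap] <- model$Rd * sin(th)
  z[on_cap] <- model$zc - model$Rd * cos(th)
  c1[on_cap] <- 1 / model$Rd
  c2c[on_cap] <- 1 / model$Rd
  ## toroidal rim (upper part, tube angle phi from phi_t down to 0)
  phi <- model$phi_t - (sm[!on_cap] - model$s_cap) / model$a
  rho[!on_cap] <- model$c + model$a * cos(phi)
  z[!on_cap] <- model$a * sin(phi)
  c1[!on_cap] <- -1 / model$a
  c2c[!on_cap] <- -cos(phi) / (model$c + model$a * cos(phi))
  z[lower] <- -z[lower]
  list(u = u, rho = rho, z = z, g = g, c1 = c1, c2 = c2c,
       H = (c1 + c2c) / 2)
}

#' Evaluate the discocyte half-profile and its derivatives
#'
#' Returns the upper half-profile height \eqn{z(\rho)} together with its first
#' and second radial derivatives; the lower half is the mirror image.
#'
#' @param model a \code{"discocyte"}.
#' @param rho radial coordinate(s) in um, \code{0 <= rho <= R0}.
#' @return A list with components \code{z}, \code{dz}, \code{d2z}.
#' @export
surface_profile <- function(model, rho) {
  R0 <- model$R0
  if (any(rho < 0 | rho > R0))
    stop("rho outside [0, R0]")
  if (model$profile == "quartic") {
    x <- rho / R0
    s <- sqrt(pmax(1 - x^2, 0))
    se <- pmax(s, .Machine$double.eps)     # slope diverges at the equator
    Q   <- model$C0 + model$C2 * x^2 + model$C4 * x^4
    Qp  <- 2 * model$C2 * x + 4 * model$C4 * x^3
    Qpp <- 2 * model$C2 + 12 * model$C4 * x^2
    sp  <- -x / se
    spp <- -1 / se - x^2 / se^3
    z   <- 0.5 * s * Q
    dz  <- 0.5 * (sp * Q + s * Qp)
    d2z <- 0.5 * (spp * Q + 2 * sp * Qp + s * Qpp)
    list(z = z, dz = dz / R0, d2z = d2z / R0^2)
  } else {
    cap <- rho <= model$rho_t
    z <- dz <- d2z <- numeric(length(rho))
    w <- sqrt(pmax(model$Rd^2 - rho[cap]^2, 0))
    z[cap] <- model$zc - w
    dz[cap] <- rho[cap] / w
    d2z[cap] <- 1 / w + rho[cap]^2 / w^3
    dr <- rho[!cap] - model$c
    w2 <- sqrt(pmax(model$a^2 - dr^2, 0))
    w2e <- pmax(w2, .Machine$double.eps)   # vertical tangent at rho = R0
    z[!cap] <- w2
    dz[!cap] <- -dr / w2e
    d2z[!cap] <- -1 / w2e - dr^2 / w2e^3
    list(z = z, dz = dz, d2z = d2z)
  }
}

#' Total surface area of the closed discocyte
#'
#' Closed form for the tangent-arc construction; Gauss-Legendre quadrature on
#' the regular meridian parameterization for the quartic profile (relative
#' error well below 1e-6 at the default order).
#'
#' @param model a \code{"discocyte"}.
#' @param n quadrature order for the quartic profile.
#' @return Area in um^2.
#' @export
surface_area <- function(model, n = 400) {
  if (model$profile == "arcs") {
    h_cap <- model$Rd * (1 - cos(model$theta_cap))
    2 * (2 * pi * model$Rd * h_cap) +
      2 * pi * model$a * (2 * model$c * model$phi_t +
                            2 * model$a * sin(model$phi_t))
  } else {
    gl <- pracma::gaussLegendre(n, 0, pi)
    m <- meridian_eval(model, gl$x)
    sum(gl$w * 2 * pi * m$rho * m$g)
  }
}

#' Maximum and central thickness of the discocyte
#'
#' Biconcavity is parameterized as the height ratio a/b of the maximum rim
#' thickness to the central dimple thickness.
#'
#' @param model a \code{"discocyte"}.
#' @return A list with \code{a} (max thickness, um), \code{b} (central
#'   thickness, um) and \code{ratio} = a/b.
#' @export
biconcavity_ratio <- function(model) {
  b <- 2 * surface_profile(model, 0)$z
  f <- function(rho) -2 * surface_profile(model, rho)$z
  opt <- stats::optimize(f, c(0, model$R0), tol = 1e-10)
  a <- max(-opt$objective, b)
  list(a = a, b = b, ratio = a / b)
}

#' Calibrate a discocyte to printed cell dimensions
#'
#' With the default \code{profile = "tangent-arcs"} the three shape parameters
#' follow directly from the dimensions (the diameter fixes R0, the thicknesses
#' fix the tube and cap radii) and \code{target_area} is used as a consistency
#' check.  With \code{profile = "quartic"} the central thickness fixes C0 and
#' the two remaining coefficients (C2, C4) are solved by a damped-Newton
#' two-equation root find on the maximum-thickness and area residuals.
#'
#' @param diameter cell diameter (um), default 8.0.
#' @param central_thickness dimple thickness (um), default 1.0.
#' @param max_thickness maximum rim thickness (um), default 2.5.
#' @param target_area total membrane area (um^2), default 138.
#' @param profile \code{"tangent-arcs"} (default) or \code{"quartic"}.
#' @param tol convergence tolerance on the scaled residuals (quartic).
#' @return A calibrated \code{"discocyte"}.
#' @examples
#' m <- calibrate_discocyte()
#' surface_area(m)                                 # 137.98 um^2
#' range(mean_curvature_field(m)$H_per_um)         # -0.525 .. +0.24 1/um
#' @export
calibrate_discocyte <- function(diameter = 8.0, central_thickness = 1.0,
                                max_thickness = 2.5, target_area = 138,
                                profile = c("tangent-arcs", "quartic"),
                                tol = 1e-10) {
  profile <- match.arg(profile)
  if (!(diameter > max_thickness && max_thickness > central_thickness &&
          central_thickness > 0))
    stop("infeasible dimensions: need diameter > max > central thickness > 0")
  if (target_area <= 0) stop("target_area must be positive")
  R0 <- diameter / 2
  if (profile == "tangent-arcs") {
    m <- discocyte_arcs(R0, max_thickness / 2, central_thickness / 2)
    rel <- surface_area(m) / target_area - 1
    if (abs(rel) > 0.01)
      warning(sprintf(
        "tangent-arc area %.2f um^2 differs from target %.2f by %.1f%%",
        surface_area(m), target_area, 100 * abs(rel)))
    return(m)
  }
  C0 <- central_thickness
  resid <- function(p) {
    m <- tryCatch(discocyte_quartic(R0, C0, p[1], p[2]),
                  error = function(e) NULL)
    if (is.null(m)) return(c(10, 10))
    c(biconcavity_ratio(m)$a / max_thickness - 1,
      surface_area(m, n = 200) / target_area - 1)
  }
  p <- c(2 * max_thickness, -max_thickness)   # generic biconcave start
  r <- resid(p)
  for (it in 1:60) {
    if (max(abs(r)) < tol) break
    J <- matrix(0, 2, 2)
    h <- 1e-6 * pmax(abs(p), 1)
    for (j in 1:2) {
      pj <- p; pj[j] <- pj[j] + h[j]
      J[, j] <- (resid(pj) - r) / h[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e)
      stop("calibration failure: singular Jacobian; residuals ",
           paste(signif(r, 4), collapse = ", ")))
    lambda <- 1
    repeat {
      pn <- p + lambda * step
      rn <- resid(pn)
      if (sum(rn^2) < sum(r^2) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    p <- pn; r <- rn
  }
  if (max(abs(r)) > 1e-6)
    stop("calibration failure: no convergence; residuals ",
         paste(signif(r, 4), collapse = ", "))
  discocyte_quartic(R0, C0, p[1], p[2])
}

#' Sampled surface field with curvatures and area elements
#'
#' Samples the closed surface of revolution along the meridian (including the
#' axis points and the equator) and attaches the meridional and azimuthal
#' principal curvatures from the analytic surface-of-revolution formulas, the
#' mean curvature H = (c1 + c2)/2, and composite-Simpson area elements whose
#' sum approximates the total surface area.
#'
#' @param model a \code{"discocyte"}.
#' @param n_samples number of meridian samples (>= 100; forced odd so the
#'   equator is a sample point).
#' @return An object of class \code{"surface_field"}: a data frame with
#'   columns \code{u, rho_um, z_um, c1_per_um, c2_per_um, H_per_um, dA_um2}
#'   and attributes \code{total_area} and \code{model}.
#' @export
mean_curvature_field <- function(model, n_samples = 2001) {
  if (n_samples < 100) stop("n_samples must be >= 100")
  n <- if (n_samples %% 2 == 0) n_samples + 1 else n_samples
  u <- seq(0, pi, length.out = n)
  m <- meridian_eval(model, u)
  h <- pi / (n - 1)
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  w <- w * h / 3                                  # composite Simpson weights
  dA <- 2 * pi * m$rho * m$g * w
  f <- data.frame(u = u, rho_um = m$rho, z_um = m$z,
                  c1_per_um = m$c1, c2_per_um = m$c2, H_per_um = m$H,
                  dA_um2 = dA)
  attr(f, "total_area") <- sum(dA)
  attr(f, "model") <- model
  class(f) <- c("surface_field", "data.frame")
  f
}

#' @export
print.surface_field <- function(x, ...) {
  cat(sprintf("Surface field: %d meridian samples, area %.4f um^2\n",
              nrow(x), attr(x, "total_area")))
  cat(sprintf("  mean curvature H in [%.4f, %.4f] per um\n",
              min(x$H_per_um), max(x$H_per_um)))
  invisible(x)
}

#' Spherical surface field (degenerate test surface)
#'
#' A sphere of radius R sampled like a discocyte field; under the package sign
#' convention H = -1/R everywhere.  Useful as a degenerate control surface.
#'
#' @param R sphere radius (um).
#' @param n_samples meridian samples.
#' @return A \code{"surface_field"}.
#' @export
sphere_field <- function(R, n_samples = 501) {
  mean_curvature_field(discocyte_quartic(R, 2 * R, 0, 0), n_samples)
}

#' Segment a surface field into dimple and rim
#'
#' In \code{"curvature-sign"} mode the dimple is the region of positive mean
#' curvature (concave toward the exterior); in \code{"cylindrical-radius"}
#' mode it is the region within a cylinder of radius \code{rho_d} about the
#' symmetry axis, on both faces.
#'
#' @param field a \code{"surface_field"}.
#' @param mode segmentation mode.
#' @param rho_d dimple circle radius (um) for cylindrical mode; default 1.13.
#' @return A list of class \code{"region_summary"} with per-sample
#'   \code{labels} ("dimple"/"rim"), \code{dimple_area}, \code{rim_area} and
#'   \code{total_area} (um^2).
#' @export
segment_surface <- function(field,
                            mode = c("curvature-sign", "cylindrical-radius"),
                            rho_d = 1.13) {
  mode <- match.arg(mode)
  if (nrow(field) == 0L) stop("empty surface field")
  if (mode == "cylindrical-radius") {
    model <- attr(field, "model")
    R0 <- if (!is.null(model)) model$R0 else max(field$rho_um)
    if (!(rho_d > 0 && rho_d < R0))
      stop("rho_d must lie in (0, R0) for cylindrical segmentation")
    dimple <- field$rho_um <= rho_d
  } else {
    dimple <- field$H_per_um > 0
  }
  labels <- ifelse(dimple, "dimple", "rim")
  da <- sum(field$dA_um2[dimple])
  ra <- sum(field$dA_um2[!dimple])
  if (da <= 0)
    warning("dimple region is empty under this segmentation")
  structure(list(labels = labels, dimple_area = da, rim_area = ra,
                 total_area = da + ra, mode = mode,
                 rho_d = if (mode == "cylindrical-radius") rho_d else NA_real_),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Dimple/rim segmentation (%s)\n", x$mode))
  cat(sprintf("  dimple %.3f um^2 (%.1f%%), rim %.3f um^2, total %.3f um^2\n",
              x$dimple_area, 100 * x$dimple_area / x$total_area,
              x$rim_area, x$total_area))
  invisible(x)
}
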