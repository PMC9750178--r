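#' Boltzmann surface density of Piezo1
#'
#' Maps a curvature-coupling energy profile onto a surface field through the
#' Boltzmann distribution: \eqn{P(x) \propto \exp(-G(H(x))/k_BT)}, normalized
#' so that \eqn{\int P\, dA = 1} over the surface.  Adding any constant to G
#' leaves the map unchanged (only energy differences are physical).
#'
#' @param field a \code{\link{mean_curvature_field}} surface field.
#' @param profile an \code{\link{energy_vs_curvature}} profile covering the
#'   field's H range (extrapolation is refused).
#' @param kT thermal energy in the same units as G (default 1, i.e. G in kBT).
#' @return Object of class \code{"density_map"}: the field data frame with an
#'   added column \code{P_per_um2}; attributes carry the profile and the
#'   normalization integral.
#' @export
boltzmann_density <- function(field, profile, kT = 1) {
  rng <- attr(profile, "range")
  Hf <- field$H_per_um
  if (min(Hf) < rng[1] - 1e-9 || max(Hf) > rng[2] + 1e-9)
    stop(sprintf(
      "surface H range [%.3g, %.3g] exceeds the profile grid [%.3g, %.3g]; extrapolation refused",
      min(Hf), max(Hf), rng[1], rng[2]))
  G <- attr(profile, "fun")(Hf)
  w <- exp(-(G - min(G)) / kT)             # gauge: subtract min before exp
  Z <- sum(w * field$dA_um2)
  out <- field
  out$P_per_um2 <- w / Z
  attr(out, "profile") <- profile
  attr(out, "kT") <- kT
  class(out) <- c("density_map", class(field))
  out
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Boltzmann density map: %d samples, integral %.8f\n",
              nrow(x), sum(x$P_per_um2 * x$dA_um2)))
  cat(sprintf("  P in [%.3g, %.3g] per um^2 (peak where H is maximal)\n",
              min(x$P_per_um2), max(x$P_per_um2)))
  invisible(x)
}

#' Predicted dimple/rim density ratio
#'
#' Fold enrichment of the Boltzmann density in the dimple relative to the
#' rim: the ratio of region-averaged probability densities
#' \eqn{(\int_{dimple} P\,dA / A_{dimple}) / (\int_{rim} P\,dA / A_{rim})}.
#'
#' @param map a \code{\link{boltzmann_density}} map.
#' @param regions a \code{\link{segment_surface}} summary for the same field.
#' @return Fold enrichment (dimensionless).
#' @export
predicted_ratio <- function(map, regions) {
  if (regions$dimple_area <= 0 || regions$rim_area <= 0)
    stop("both regions must have positive area")
  d <- regions$labels == "dimple"
  mean_d <- sum(map$P_per_um2[d] * map$dA_um2[d]) / regions$dimple_area
  mean_r <- sum(map$P_per_um2[!d] * map$dA_um2[!d]) / regions$rim_area
  mean_d / mean_r
}

#' Fit the curvature-coupling model of Piezo1 organization
#'
#' The central model of the package: given a calibrated discocyte surface and
#' the Piezo dome parameters, computes the mean-curvature field, the
#' free-membrane bending-energy profile G(H) (by Helfrich minimization in the
#' associated vesicles), the Boltzmann surface density of Piezo1, and the
#' predicted dimple/rim fold enrichment.
#'
#' @param model a \code{"discocyte"}; default the calibrated 8.0/1.0/2.5 um,
#'   138 um^2 cell.
#' @param dome a \code{\link{piezo_dome}}.
#' @param Kb bilayer bending modulus (kBT), default 20.
#' @param kT thermal energy (kBT units), default 1.
#' @param n_grid energy-profile grid size, default 25 on [-0.6, 0.3] 1/um.
#' @param n_samples meridian samples of the surface field.
#' @param segmentation dimple/rim segmentation mode for the reported ratio.
#' @param flex if TRUE, use flexible-dome (joint-minimum) energies.
#' @return Object of class \code{"curvature_coupling"} with components
#'   \code{model}, \code{field}, \code{regions}, \code{profile},
#'   \code{density}, \code{ratio} and the call parameters.
#' @examples
#' \donttest{
#' cc <- curvature_coupling()
#' cc$ratio          # ~2-fold dimple enrichment
#' predict(cc, newdata = c(-0.52, 0.24), type = "energy")
#' }
#' @export
curvature_coupling <- function(model = calibrate_discocyte(),
                               dome = piezo_dome(), Kb = 20, kT = 1,
                               n_grid = 25, n_samples = 2001,
                               segmentation = c("curvature-sign",
                                                "cylindrical-radius"),
                               flex = FALSE) {
  segmentation <- match.arg(segmentation)
  field <- mean_curvature_field(model, n_samples)
  Hr <- range(field$H_per_um)
  lo <- min(-0.6, Hr[1] - 0.02); hi <- max(0.3, Hr[2] + 0.02)
  profile <- energy_vs_curvature(seq(lo, hi, length.out = n_grid),
                                 dome = dome, Kb = Kb, flex = flex)
  density <- boltzmann_density(field, profile, kT = kT)
  regions <- segment_surface(field, segmentation)
  ratio <- predicted_ratio(density, regions)
  structure(list(model = model, dome = dome, Kb = Kb, kT = kT,
                 field = field, profile = profile, density = density,
                 regions = regions, ratio = ratio, flex = flex,
                 segmentation = segmentation),
            class = "curvature_coupling")
}

#' @export
print.curvature_coupling <- function(x, ...) {
  cat("Curvature-coupling model of Piezo1 on the discocyte surface\n")
  cat(sprintf("  surface area %.2f um^2, H in [%.3f, %.3f] 1/um\n",
              attr(x$field, "total_area"),
              min(x$field$H_per_um), max(x$field$H_per_um)))
  cat(sprintf("  G(H) spans %.3f kBT over the surface curvature range\n",
              diff(range(attr(x$profile, "fun")(range(x$field$H_per_um))))))
  cat(sprintf("  predicted dimple/rim density ratio: %.3f (%s segmentation)\n",
              x$ratio, x$segmentation))
  invisible(x)
}

#' @export
summary.curvature_coupling <- function(object, ...) {
  x <- object
  Hr <- range(x$field$H_per_um)
  G <- attr(x$profile, "fun")
  out <- list(
    area_um2 = attr(x$field, "total_area"),
    H_range = Hr,
    dimple_area_um2 = x$regions$dimple_area,
    dimple_area_fraction = x$regions$dimple_area / x$regions$total_area,
    dG_kBT = G(Hr[2]) - G(Hr[1]),
    ratio = x$ratio,
    P_range = range(x$density$P_per_um2),
    Kb = x$Kb, dome = x$dome, flex = x$flex)
  class(out) <- "summary.curvature_coupling"
  out
}

#' @export
print.summary.curvature_coupling <- function(x, ...) {
  cat("Curvature-coupling model summary\n")
  cat(sprintf("  membrane area: %.2f um^2 (dimple fraction %.1f%%)\n",
              x$area_um2, 100 * x$dimple_area_fraction))
  cat(sprintf("  surface mean curvature: %.3f to %.3f 1/um\n",
              x$H_range[1], x$H_range[2]))
  cat(sprintf("  energy gap dimple vs rim extreme: %.3f kBT\n", x$dG_kBT))
  cat(sprintf("  Boltzmann density: %.4f to %.4f per um^2\n",
              x$P_range[1], x$P_range[2]))
  cat(sprintf("  predicted dimple/rim density ratio: %.3f\n", x$ratio))
  invisible(x)
}

#' @export
coef.curvature_coupling <- function(object, ...) {
  Hr <- range(object$field$H_per_um)
  G <- attr(object$profile, "fun")
  c(dimple_rim_ratio = object$ratio,
    H_min = Hr[1], H_max = Hr[2],
    dG_kBT = G(Hr[2]) - G(Hr[1]))
}

#' Predict energies or densities from a fitted curvature-coupling model
#'
#' @param object a \code{"curvature_coupling"} fit.
#' @param newdata mean curvature values (1/um); defaults to the surface
#'   field's H values.
#' @param type \code{"energy"} for G(H) in kBT (gauge: relative to the grid
#'   minimum is not applied; values are as solved) or \code{"density"} for
#'   the relative Boltzmann weight normalized over the fitted surface.
#' @param ... unused.
#' @export
predict.curvature_coupling <- function(object, newdata = NULL,
                                       type = c("energy", "density"), ...) {
  type <- match.arg(type)
  H <- if (is.null(newdata)) object$field$H_per_um else newdata
  rng <- attr(object$profile, "range")
  if (min(H) < rng[1] - 1e-9 || max(H) > rng[2] + 1e-9)
    stop("newdata outside the fitted curvature grid; extrapolation refused")
  G <- attr(object$profile, "fun")(H)
  if (type == "energy") return(G)
  Gf <- attr(object$profile, "fun")(object$field$H_per_um)
  w0 <- exp(-(Gf - min(Gf)) / object$kT)
  Z <- sum(w0 * object$field$dA_um2)
  exp(-(G - min(Gf)) / object$kT) / Z
}

#' @export
plot.curvature_coupling <- function(x, which = c("profile", "density"), ...) {
  which <- match.arg(which)
  if (which == "profile") {
    G <- x$profile$G_kBT - min(x$profile$G_kBT)
    plot(x$profile$H_per_um, G, type = "l", lwd = 2,
         xlab = "mean curvature H (1/um)",
         ylab = "G - min G (kBT)",
         main = "Curvature-coupling energy profile")
    Hr <- range(x$field$H_per_um)
    graphics::abline(v = Hr, lty = 3)
  } else {
    plot(x$density$rho_um * sign(cos(x$density$u)),
         x$density$P_per_um2, type = "p", pch = 16, cex = 0.4,
         xlab = "signed radial position (um; + upper face)",
         ylab = "P (1/um^2)",
         main = "Boltzmann surface density of Piezo1")
  }
  invisible(x)
}

#' Simulate spot patterns from a fitted curvature-coupling model
#'
#' Draws point patterns of Piezo1 positions on the fitted surface from the
#' model's Boltzmann density (see \code{\link{sample_spots}}).
#'
#' @param object a \code{"curvature_coupling"} fit.
#' @param nsim number of cells (patterns) to simulate.
#' @param seed seed passed to the generator.
#' @param n_spots spots per cell; default draws from the observed abundance
#'   distribution (normal, mean 80.2, SD 26, truncated at 0).
#' @param ... unused.
#' @return A list of \code{"spot_set"} objects of length \code{nsim}.
#' @export
simulate.curvature_coupling <- function(object, nsim = 1, seed = NULL,
                                        n_spots = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    sample_spots(spot_gen_params(n_spots = n_spots), object$density))
}
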