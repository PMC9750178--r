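#' Exact optimal transport plan between two mass distributions
#'
#' Solves the discrete transportation problem exactly (successive shortest
#' augmenting paths with node potentials on the support of the two
#' distributions).  Marginals of the returned plan equal the normalized
#' inputs to machine precision.
#'
#' @param a,b nonnegative masses (normalized internally to unit total).
#' @param cost cost matrix, \code{length(a)} x \code{length(b)}.
#' @return Object of class \code{"transport_plan"}: triplets \code{from},
#'   \code{to}, \code{mass}, and the total \code{cost} under the normalized
#'   masses.
#' @export
transport_plan <- function(a, b, cost) {
  if (any(a < 0) || any(b < 0)) stop("masses must be nonnegative")
  if (sum(a) <= 0 || sum(b) <= 0) stop("each distribution needs positive mass")
  a <- a / sum(a); b <- b / sum(b)
  res <- ot_exact(a, b, cost)
  res$m <- length(a); res$n <- length(b)
  res$marg_a <- tapply(res$mass, factor(res$from, levels = seq_along(a)), sum,
                       default = 0)
  res$marg_b <- tapply(res$mass, factor(res$to, levels = seq_along(b)), sum,
                       default = 0)
  class(res) <- "transport_plan"
  res
}

## extract a channel's support after background subtraction and signal-mass
## pruning; returns pixel-center coordinates (nm) and normalized masses
.otc_support <- function(im, px_nm, mass_frac) {
  ## robust background floor: median + 3 MAD removes isolated shot-noise
  ## pixels from the support (STED sections are sparse)
  bg <- stats::median(im) + 3 * stats::mad(im)
  w <- pmax(im - bg, 0)
  if (sum(w) <= 0) w <- pmax(im - stats::median(im), 0)
  if (sum(w) <= 0) stop("channel has no signal above background")
  nz <- which(w > 0, arr.ind = TRUE)
  mass <- w[w > 0]
  ord <- order(-mass)
  keep <- ord[cumsum(mass[ord]) <=
                mass_frac * sum(mass) * (1 + 1e-12)]
  if (length(keep) < 1) keep <- ord[1]
  keep <- sort(keep)                    # preserve pixel (column-major) order
  list(x = (nz[keep, 1] - 1) * px_nm,
       y = (nz[keep, 2] - 1) * px_nm,
       mass = mass[keep] / sum(mass[keep]))
}

#' Optimal transport colocalization curve
#'
#' Normalizes the two channels of a section to unit mass, computes the exact
#' optimal transport plan between the pixel distributions under a Euclidean
#' ground cost (optionally squared), and reports, for each distance
#' threshold, the fraction of transported mass moved no farther than the
#' threshold.  The curve is non-decreasing and reaches 1 at the maximum
#' inter-pixel distance.
#'
#' @param pair a \code{\link{make_section_pair}} section (or any list with
#'   matrices \code{A}, \code{B} and \code{px_nm}).
#' @param thresholds_nm ascending distance thresholds (nm); default pixel
#'   size up to 300 nm.
#' @param cost_exponent 1 (Euclidean distance cost, default) or 2 (squared).
#'   Thresholding is always on the Euclidean distance.
#' @param mass_frac fraction of above-background signal mass retained per
#'   channel (prunes isolated shot-noise pixels from the support).
#' @return Object of class \code{"otc_curve"}: data frame with
#'   \code{threshold_nm}, \code{otc}; the transport plan in attributes.
#' @export
otc_curve <- function(pair, thresholds_nm = NULL, cost_exponent = 1,
                      mass_frac = 0.995) {
  px <- pair$px_nm
  if (is.null(thresholds_nm)) thresholds_nm <- seq(px, 300, by = px / 2)
  if (is.unsorted(thresholds_nm)) stop("thresholds must be ascending")
  if (!identical(dim(pair$A), dim(pair$B)))
    stop("channels must share dimensions")
  sa <- .otc_support(pair$A, px, mass_frac)
  sb <- .otc_support(pair$B, px, mass_frac)
  D <- sqrt(outer(sa$x, sb$x, "-")^2 + outer(sa$y, sb$y, "-")^2)
  Cm <- if (cost_exponent == 2) D^2 else D
  plan <- transport_plan(sa$mass, sb$mass, Cm)
  dmoved <- D[cbind(plan$from, plan$to)]
  otc <- vapply(thresholds_nm,
                function(t) sum(plan$mass[dmoved <= t + 1e-9]), numeric(1))
  out <- data.frame(threshold_nm = thresholds_nm, otc = otc)
  attr(out, "plan") <- plan
  attr(out, "distances_nm") <- dmoved
  attr(out, "cost_exponent") <- cost_exponent
  class(out) <- c("otc_curve", "data.frame")
  out
}

#' @export
print.otc_curve <- function(x, ...) {
  i100 <- which.min(abs(x$threshold_nm - 100))
  cat(sprintf("OTC curve: %d thresholds (%.3g-%.3g nm); OTC(%.3g nm) = %.3f\n",
              nrow(x), min(x$threshold_nm), max(x$threshold_nm),
              x$threshold_nm[i100], x$otc[i100]))
  invisible(x)
}

#' Mean OTC curve with confidence band across sections
#'
#' Per-threshold mean of the section OTC curves with a t-distribution
#' confidence interval across sections (the band narrows as 1/sqrt(n)).
#'
#' @param sections list of section pairs (see \code{\link{otc_curve}}).
#' @param thresholds_nm common thresholds; default from the first section.
#' @param level confidence level, default 0.95.
#' @param ... passed to \code{\link{otc_curve}}.
#' @return Object of class \code{"otc_bands"}: data frame with
#'   \code{threshold_nm, otc_mean, ci_lo, ci_hi, n}.
#' @export
otc_bands <- function(sections, thresholds_nm = NULL, level = 0.95, ...) {
  if (length(sections) < 1) stop("need at least one section")
  if (is.null(thresholds_nm)) {
    px <- sections[[1]]$px_nm
    thresholds_nm <- seq(px, 300, by = px / 2)
  }
  curves <- vapply(sections,
                   function(s) otc_curve(s, thresholds_nm, ...)$otc,
                   numeric(length(thresholds_nm)))
  if (is.null(dim(curves))) curves <- matrix(curves, ncol = 1)
  n <- ncol(curves)
  mu <- rowMeans(curves)
  if (n >= 2) {
    se <- apply(curves, 1, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
    lo <- mu - tq * se; hi <- mu + tq * se
  } else {
    warning("single section: no confidence band, mean only")
    lo <- hi <- rep(NA_real_, length(mu))
  }
  out <- data.frame(threshold_nm = thresholds_nm, otc_mean = mu,
                    ci_lo = lo, ci_hi = hi, n = n)
  attr(out, "curves") <- curves
  attr(out, "level") <- level
  class(out) <- c("otc_bands", "data.frame")
  out
}

#' @export
print.otc_bands <- function(x, ...) {
  i100 <- which.min(abs(x$threshold_nm - 100))
  cat(sprintf("OTC bands over n = %d sections; OTC(%.3g nm) = %.3f [%.3f, %.3f]\n",
              x$n[1], x$threshold_nm[i100], x$otc_mean[i100],
              x$ci_lo[i100], x$ci_hi[i100]))
  invisible(x)
}
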