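#' Read and write trajectory tables
#'
#' CSV trajectory I/O with a declared column dialect, tolerant to header
#' variants from external tracking tools.  Times must be strictly increasing
#' within a track; violations are rejected with the offending row reported.
#'
#' @param path CSV file path.
#' @param dialect named list mapping the canonical columns
#'   \code{track, t, x, y} to the file's column names; \code{frame} is
#'   optional.  Default matches \code{\link{write_tracks}} output.
#' @param time_unit \code{"s"} or \code{"ms"}.
#' @param length_unit \code{"um"} or \code{"nm"}.
#' @return List of \code{\link{trajectory}} objects.
#' @export
read_tracks <- function(path,
                        dialect = list(track = "track_id", t = "t_s",
                                       x = "x_um", y = "y_um"),
                        time_unit = c("s", "ms"),
                        length_unit = c("um", "nm")) {
  time_unit <- match.arg(time_unit)
  length_unit <- match.arg(length_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(dialect[c("track", "t", "x", "y")])
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  tf <- if (time_unit == "ms") 1e-3 else 1
  lf <- if (length_unit == "nm") 1e-3 else 1
  ids <- unique(d[[dialect$track]])
  lapply(ids, function(id) {
    rows <- which(d[[dialect$track]] == id)
    tt <- d[[dialect$t]][rows] * tf
    bad <- which(diff(tt) <= 0)
    if (length(bad))
      stop("non-monotone time in track ", id, " at file row ",
           rows[bad[1] + 1] + 1)   # +1 for the header line
    trajectory(tt, d[[dialect$x]][rows] * lf, d[[dialect$y]][rows] * lf,
               track_id = id)
  })
}

#' @rdname read_tracks
#' @param tracks list of trajectories.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  d <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read and write image stacks as TIFF
#'
#' Multi-page 16-bit unsigned TIFF with voxel sizes in a YAML sidecar
#' (\code{<path>.yml}).
#'
#' @param stack 3D array of counts with \code{px_nm}/\code{z_step_nm}
#'   attributes (e.g. from \code{\link{render_stack}}).
#' @param path TIFF path.
#' @return \code{read_stack} returns the array with voxel-size attributes.
#' @export
write_stack <- function(stack, path) {
  mx <- max(stack, 1)
  if (mx > 65535) stop("stack exceeds 16-bit range")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) stack[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(px_nm = attr(stack, "px_nm"),
               z_step_nm = attr(stack, "z_step_nm"),
               origin_um = as.numeric(attr(stack, "origin_um")))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- round(pages[[k]] * 65535)
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    attr(a, "px_nm") <- meta$px_nm
    attr(a, "z_step_nm") <- meta$z_step_nm
    attr(a, "origin_um") <- meta$origin_um
  }
  a
}

#' Export a surface field as CSV or PLY mesh
#'
#' \code{export_profile_csv} writes the meridian table
#' (\code{rho_um,z_um,c1_per_um,c2_per_um,H_per_um,dA_um2}).
#' \code{export_ply} triangulates the surface of revolution and writes an
#' ASCII PLY with per-vertex mean curvature, region label (0 = rim,
#' 1 = dimple) and, when given a density map, the Boltzmann density as a
#' vertex quality attribute.
#'
#' @param field a \code{"surface_field"} or \code{"density_map"}.
#' @param path output path.
#' @param n_phi azimuthal mesh resolution.
#' @export
export_profile_csv <- function(field, path) {
  d <- data.frame(rho_um = field$rho_um, z_um = field$z_um,
                  c1_per_um = field$c1_per_um, c2_per_um = field$c2_per_um,
                  H_per_um = field$H_per_um, dA_um2 = field$dA_um2)
  if (!is.null(field$P_per_um2)) d$P_per_um2 <- field$P_per_um2
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile_csv
#' @export
export_ply <- function(field, path, n_phi = 90) {
  sub <- field[seq(1, nrow(field), length.out = min(nrow(field), 181)), ]
  nu <- nrow(sub)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  vx <- as.vector(outer(sub$rho_um, cos(phi)))
  vy <- as.vector(outer(sub$rho_um, sin(phi)))
  vz <- rep(sub$z_um, times = n_phi)
  H <- rep(sub$H_per_um, times = n_phi)
  region <- rep(as.integer(sub$H_per_um > 0), times = n_phi)
  qual <- if (!is.null(sub$P_per_um2)) rep(sub$P_per_um2, times = n_phi)
          else rep(0, length(vx))
  vid <- function(i, k) (k - 1) * nu + i        # 1-based
  faces <- character(0)
  for (k in seq_len(n_phi)) {
    k2 <- if (k == n_phi) 1L else k + 1L
    i <- seq_len(nu - 1)
    faces <- c(faces,
               sprintf("3 %d %d %d", vid(i, k) - 1, vid(i + 1, k) - 1,
                       vid(i + 1, k2) - 1),
               sprintf("3 %d %d %d", vid(i, k) - 1, vid(i + 1, k2) - 1,
                       vid(i, k2) - 1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", length(vx)),
               "property float x", "property float y", "property float z",
               "property float quality", "property float mean_curvature",
               "property uchar region",
               sprintf("element face %d", length(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %.8g %.6f %d",
                     vx, vy, vz, qual, H, region), con)
  writeLines(faces, con)
  invisible(path)
}

#' Export an energy profile or OTC result as CSV
#'
#' @param x an \code{"energy_profile"}, \code{"otc_curve"} or
#'   \code{"otc_bands"}.
#' @param path output path.
#' @export
export_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
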