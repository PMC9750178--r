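#' Pipeline run configuration
#'
#' Assembles and validates the configuration for \code{\link{run_pipeline}}.
#' Unknown keys are rejected; every physical constant carries its unit in the
#' field name.  A configuration can also be read from YAML.
#'
#' @param stages character vector of stages to run, in any order; dependency
#'   order is enforced internally.  Available: \code{"shape"},
#'   \code{"energy"}, \code{"density"}, \code{"sample"}, \code{"spots"},
#'   \code{"spt"}, \code{"otc"}.
#' @param out_dir output directory.
#' @param seed master RNG seed for all stochastic stages.
#' @param ... overrides of the default parameters (see the function source
#'   for the schema: geometry dimensions, Kb_kBT, K_P_kBT, dome_S_cap_nm2,
#'   dome_R_P0_nm, detection thresholds, SPT windows, OTC thresholds, ...).
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(stages = c("shape", "energy", "density", "sample",
                                  "spots"),
                       out_dir = tempfile("piezorbc_run_"), seed = 1L, ...) {
  defaults <- list(
    diameter_um = 8.0, central_thickness_um = 1.0, max_thickness_um = 2.5,
    target_area_um2 = 138,
    Kb_kBT = 20, kT = 1, K_P_kBT = 20,
    dome_S_cap_nm2 = 450, dome_R_P0_nm = 42,
    n_energy_grid = 25, flex = FALSE,
    segmentation = "curvature-sign", rho_d_um = 1.13,
    n_cells = 5, n_spots = NULL,
    detect_diameter_nm = 120, detect_threshold = 3000,
    spt_window_macro_s = 5, spt_window_micro_s = 0.05,
    spt_D_micro_um2_s = 0.037, spt_corral_nm = 500, spt_hop_prob = 0.07,
    spt_sigma_loc_nm = 20, spt_rate_hz = 100, spt_duration_s = 120,
    spt_n_tracks = 14,
    otc_n_sections = 8, otc_n_spots = 15, otc_coloc_fraction = 0.5,
    otc_thresholds_nm = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  known_stages <- c("shape", "energy", "density", "sample", "spots", "spt",
                    "otc")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$stages <- stages
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (shape -> energy -> density -> sample -> spots; spt and otc are
#' independent), writes stage outputs under \code{config$out_dir}, and
#' returns a run report sufficient to rerun deterministic stages
#' bit-identically.
#'
#' @param config a \code{\link{run_config}}.
#' @return Object of class \code{"run_report"}: output paths, summary
#'   statistics, package version and the configuration echo.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  order_all <- c("shape", "energy", "density", "sample", "spots", "spt", "otc")
  stages <- order_all[order_all %in% config$stages]
  deps <- list(energy = character(0), density = c("shape", "energy"),
               sample = "density", spots = "sample")
  for (s in stages)
    if (!all(deps[[s]] %in% c(stages, "")) && length(deps[[s]]))
      stages <- unique(c(deps[[s]], stages))
  stages <- order_all[order_all %in% stages]
  paths <- list(); summaries <- list()
  st <- list()
  t0 <- Sys.time()
  set.seed(config$seed)
  for (stage in stages) {
    res <- tryCatch(switch(stage,
      shape = {
        st$model <- calibrate_discocyte(config$diameter_um,
                                        config$central_thickness_um,
                                        config$max_thickness_um,
                                        config$target_area_um2)
        st$field <- mean_curvature_field(st$model)
        p <- file.path(config$out_dir, "surface_profile.csv")
        export_profile_csv(st$field, p)
        p2 <- file.path(config$out_dir, "surface.ply")
        export_ply(st$field, p2)
        paths$shape <- c(p, p2)
        summaries$shape <- list(area_um2 = attr(st$field, "total_area"),
                                H_range = range(st$field$H_per_um))
        NULL
      },
      energy = {
        dome <- piezo_dome(config$dome_S_cap_nm2, config$dome_R_P0_nm,
                           config$K_P_kBT)
        st$dome <- dome
        st$profile <- energy_vs_curvature(
          seq(-0.6, 0.3, length.out = config$n_energy_grid),
          dome = dome, Kb = config$Kb_kBT, flex = config$flex)
        p <- file.path(config$out_dir, "energy_profile.csv")
        export_csv(st$profile, p)
        paths$energy <- p
        summaries$energy <- list(
          G_span_kBT = diff(range(st$profile$G_kBT)),
          K_P_kBT = config$K_P_kBT)
        NULL
      },
      density = {
        st$density <- boltzmann_density(st$field, st$profile, config$kT)
        st$regions <- segment_surface(st$field, config$segmentation,
                                      rho_d = config$rho_d_um)
        st$ratio <- predicted_ratio(st$density, st$regions)
        p <- file.path(config$out_dir, "density_map.csv")
        export_profile_csv(st$density, p)
        p2 <- file.path(config$out_dir, "density_map.ply")
        export_ply(st$density, p2)
        paths$density <- c(p, p2)
        summaries$density <- list(dimple_rim_ratio = st$ratio)
        NULL
      },
      sample = {
        st$spots <- do.call(rbind, lapply(seq_len(config$n_cells), function(i) {
          s <- sample_spots(spot_gen_params(n_spots = config$n_spots),
                            st$density, cell_id = i)
          s
        }))
        class(st$spots) <- c("spot_set", "data.frame")
        p <- file.path(config$out_dir, "spots.csv")
        utils::write.csv(as.data.frame(st$spots), p, row.names = FALSE)
        paths$sample <- p
        summaries$sample <- list(n_cells = config$n_cells,
                                 n_spots = nrow(st$spots))
        NULL
      },
      spots = {
        dens <- region_density(st$spots, st$regions)
        nnd <- nearest_neighbor(st$spots)
        summaries$spots <- list(ratio_mean = dens$ratio_mean,
                                ratio_sd = dens$ratio_sd,
                                nnd_mean_nm = nnd$mean_nm)
        NULL
      },
      spt = {
        tracks <- simulate_tracks(track_gen_params(
          D_micro = config$spt_D_micro_um2_s,
          corral_nm = config$spt_corral_nm, hop_prob = config$spt_hop_prob,
          sigma_loc_nm = config$spt_sigma_loc_nm,
          rate_hz = config$spt_rate_hz, duration_s = config$spt_duration_s,
          n_tracks = config$spt_n_tracks, seed = config$seed))
        p <- file.path(config$out_dir, "tracks.csv")
        write_tracks(tracks, p)
        curve <- msd(tracks, max_lag = config$spt_window_macro_s * 1.2)
        fmac <- fit_diffusion(curve, config$spt_window_macro_s)
        fmic <- fit_diffusion(curve, config$spt_window_micro_s)
        paths$spt <- p
        summaries$spt <- list(D_macro_um2_s = fmac$D_um2_s,
                              D_micro_um2_s = fmic$D_um2_s)
        NULL
      },
      otc = {
        secs <- lapply(seq_len(config$otc_n_sections), function(i)
          make_section_pair(config$otc_coloc_fraction,
                            n_spots = config$otc_n_spots,
                            seed = config$seed + i))
        bands <- otc_bands(secs, config$otc_thresholds_nm)
        p <- file.path(config$out_dir, "otc_bands.csv")
        export_csv(bands, p)
        paths$otc <- p
        i100 <- which.min(abs(bands$threshold_nm - 100))
        summaries$otc <- list(otc_100nm = bands$otc_mean[i100],
                              n_sections = config$otc_n_sections)
        NULL
      }), error = function(e) e)
    if (inherits(res, "error")) {
      warning("stage '", stage, "' failed: ", conditionMessage(res),
              "; downstream dependents halted")
      bad_downstream <- names(deps)[vapply(deps, function(d) stage %in% d,
                                           TRUE)]
      stages <- setdiff(stages, bad_downstream)
      summaries[[stage]] <- list(error = conditionMessage(res))
    }
  }
  report <- list(paths = paths, summaries = summaries,
                 config = unclass(config),
                 version = as.character(utils::packageVersion("piezorbc")),
                 started = format(t0), elapsed_s =
                   as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report[c("summaries", "config", "version")],
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("piezorbc %s pipeline run (%.1f s)\n", x$version, x$elapsed_s))
  for (s in names(x$summaries)) {
    vals <- x$summaries[[s]]
    cat(sprintf("  %-8s %s\n", s,
                paste(names(vals), vapply(vals, function(v)
                  paste(signif(unlist(v), 4), collapse = ","), ""),
                  sep = "=", collapse = "  ")))
  }
  invisible(x)
}
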