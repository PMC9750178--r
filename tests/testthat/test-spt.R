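test_that("MSD handles degenerate and closed-form tracks exactly", {
  tt <- seq(0, 10, by = 0.1)
  still <- trajectory(tt, rep(1, length(tt)), rep(-2, length(tt)))
  expect_true(all(msd(still, max_lag = 5)$msd_um2 == 0))
  ## ballistic motion: MSD(tau) = v^2 tau^2
  v <- 0.3
  ball <- trajectory(tt, v * tt, rep(0, length(tt)))
  cv <- msd(ball, max_lag = 5)
  expect_equal(cv$msd_um2, v^2 * cv$lag_s^2, tolerance = 1e-10)
  ## pair counts decrease with lag; lags beyond track length are dropped
  expect_true(all(diff(cv$n_pairs) <= 0))
  expect_lte(max(cv$lag_s), 5 + 1e-9)
  expect_error(msd(trajectory(1:2, 1:2, 1:2)[0, ]), "2 frames|empty")
})

test_that("MSD of duplicated tracks equals the single-track MSD", {
  set.seed(41)
  tt <- seq(0, 20, by = 0.01)
  tr <- trajectory(tt, cumsum(rnorm(length(tt), 0, 0.02)),
                   cumsum(rnorm(length(tt), 0, 0.02)))
  one <- msd(tr, max_lag = 2)
  three <- msd(list(tr, tr, tr), max_lag = 2)
  expect_equal(three$msd_um2, one$msd_um2, tolerance = 1e-12)
})

test_that("free 2D diffusion is recovered as 4 D tau", {
  D <- 0.05
  tr <- simulate_tracks(track_gen_params(D_micro = D, corral_nm = 1e7,
                                         hop_prob = 1, sigma_loc_nm = 0,
                                         rate_hz = 100, duration_s = 60,
                                         n_tracks = 40, seed = 8))
  cv <- msd(tr, max_lag = 0.3)
  fit <- fit_diffusion(cv, 0.3)
  expect_equal(fit$D_um2_s, D, tolerance = 0.1)
  expect_gt(fit$r_squared, 0.99)
})

test_that("diffusion fit is exact on an exact line and flags negatives", {
  curve <- data.frame(lag_s = seq(0.01, 1, by = 0.01))
  curve$msd_um2 <- 4 * 0.02 * curve$lag_s
  class(curve) <- c("msd_curve", "data.frame")
  fit <- fit_diffusion(curve, 1)
  expect_equal(fit$D_um2_s, 0.02, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  curve$msd_um2 <- 0.1 - 0.01 * curve$lag_s
  expect_warning(fitn <- fit_diffusion(curve, 1), "negative")
  expect_true(fitn$negative_slope)
  expect_lte(fitn$D_um2_s, 0)
  expect_error(fit_diffusion(curve, 0.015), ">= 3 lag points")
})

test_that("hop-diffusion: microscopic window recovers D, macroscopic is smaller", {
  tr <- simulate_tracks(track_gen_params(seed = 12))
  cv <- msd(tr, max_lag = 5.5)
  micro <- fit_diffusion(cv, 0.05)
  macro <- fit_diffusion(cv, 5)
  expect_equal(micro$D_um2_s, 0.037, tolerance = 0.15)
  expect_lt(macro$D_um2_s, micro$D_um2_s)
})

test_that("microscopic D is unbiased when corrals dwarf the 50 ms diffusion length", {
  ## short-window slopes carry a wall deficit ~ (1-p) sqrt(2 D tau)/L; in the
  ## weak-confinement regime the estimator recovers D essentially unbiased
  Ds <- vapply(1:5, function(s) {
    tr <- simulate_tracks(track_gen_params(corral_nm = 2000, hop_prob = 0.3,
                                           duration_s = 60, n_tracks = 10,
                                           seed = 100 + s))
    fit_diffusion(msd(tr, max_lag = 0.06), 0.05)$D_um2_s
  }, numeric(1))
  expect_lt(abs(mean(Ds) / 0.037 - 1), 0.10)
})

test_that("confinement fit recovers corral sizes and rejects free diffusion", {
  ## circular corral, diameter 400 nm
  tr <- simulate_tracks(track_gen_params(hop_prob = 0, corral_nm = 400,
                                         geometry = "circle", duration_s = 30,
                                         n_tracks = 10, seed = 5))
  cf <- confinement_fit(msd(tr, max_lag = 10))
  expect_true(cf$confined)
  expect_equal(cf$L_nm, 400, tolerance = 0.2)
  ## square corrals across the 200-600 nm range: plateau = L^2/3
  for (L in c(250, 550)) {
    trs <- simulate_tracks(track_gen_params(hop_prob = 0, corral_nm = L,
                                            duration_s = 30, n_tracks = 10,
                                            seed = L))
    cfs <- confinement_fit(msd(trs, max_lag = 10))
    expect_true(cfs$confined)
    expect_equal(cfs$L_nm, 2 * L / sqrt(3), tolerance = 0.2)
  }
  ## free diffusion has no plateau
  trf <- simulate_tracks(track_gen_params(corral_nm = 1e7, hop_prob = 1,
                                          duration_s = 30, n_tracks = 6,
                                          seed = 6))
  expect_false(confinement_fit(msd(trf, max_lag = 6))$confined)
})

test_that("fixed-cell controls sit on the localization-noise floor", {
  fx <- fixed_cell_tracks(sigma_loc_nm = 20, n = 6, duration_s = 60,
                          seed = 16)
  cv <- msd(fx, max_lag = 2)
  expect_equal(mean(cv$msd_um2), 4 * 0.02^2, tolerance = 0.1)
  Dfix <- suppressWarnings(fit_diffusion(cv, 2))$D_um2_s
  ## far below any mobile simulation
  tr <- simulate_tracks(track_gen_params(duration_s = 30, n_tracks = 4,
                                         seed = 17))
  Dmob <- fit_diffusion(msd(tr, max_lag = 2), 2)$D_um2_s
  expect_lt(abs(Dfix), Dmob / 50)
  ## sigma = 0 collapses to exactly zero MSD
  fx0 <- fixed_cell_tracks(sigma_loc_nm = 0, n = 2, duration_s = 5, seed = 1)
  expect_true(all(msd(fx0, max_lag = 1)$msd_um2 == 0))
})

test_that("occupancy follows containment and area-ratio oracles", {
  tt <- 0:999
  ctr <- trajectory(tt, rep(0.01, 1000), rep(-0.02, 1000))
  expect_equal(dimple_occupancy(ctr, center = c(0, 0))$fraction, 1.0)
  ## uniform positions on a disc of radius 4: P(r <= 1.13) = (1.13/4)^2
  set.seed(23)
  r <- 4 * sqrt(runif(4000)); a <- runif(4000, 0, 2 * pi)
  unif <- trajectory(seq_len(4000), r * cos(a), r * sin(a))
  occ <- dimple_occupancy(unif, center = c(0, 0))
  p0 <- (1.13 / 4)^2
  expect_lt(abs(occ$fraction - p0), 3 * sqrt(p0 * (1 - p0) / 4000))
  ## center estimation fallback is flagged
  expect_true(dimple_occupancy(unif)$center_estimated)
  expect_error(dimple_occupancy(unif[0, ]), "empty")
})

test_that("density-biased walkers prefer the dimple circle; unbiased do not", {
  dm <- boltzmann_density(rbc_field(), rbc_profile())
  ## sharpen the radial preference so a 3-min walk shows it clearly
  f <- .bias_sharp <- local({
    up <- dm[dm$u <= pi / 2, ]
    g <- stats::approxfun(up$rho_um, up$P_per_um2, rule = 2)
    function(x, y) g(sqrt(x^2 + y^2))^8
  })
  pb <- track_gen_params(corral_nm = 600, hop_prob = 0.5, duration_s = 180,
                         rate_hz = 25, n_tracks = 12, bias = f, seed = 71)
  pu <- track_gen_params(corral_nm = 600, hop_prob = 0.5, duration_s = 180,
                         rate_hz = 25, n_tracks = 12, seed = 72)
  frac <- function(p) {
    tr <- simulate_tracks(p)
    mean(vapply(tr, function(t)
      dimple_occupancy(t, center = c(0, 0))$fraction, numeric(1)))
  }
  area_frac <- (1.13 / 2)^2 * pi / (pi * 2^2)   # walkers roam ~2 um here
  fb <- frac(pb); fu <- frac(pu)
  expect_gt(fb, fu)            # bias detected
})

test_that("dispersion time follows x^2/6D with the printed Ca2+ range", {
  expect_equal(dispersion_time(0, 30), 0)
  expect_equal(dispersion_time(1, 65), 1 / 390, tolerance = 1e-12)
  expect_equal(dispersion_time(1, 65), 0.0026, tolerance = 0.02)
  t2 <- dispersion_time(2, 13)
  expect_equal(t2, 0.0513, tolerance = 0.01)   # tens of ms
  expect_lt(t2, 0.1)
  expect_error(dispersion_time(1, 0), "D must be")
  expect_error(dispersion_time(-1, 1), "x must be")
})

test_that("trajectory validation rejects non-monotone time", {
  expect_error(trajectory(c(0, 2, 1), 1:3, 1:3), "non-monotone time at row 3")
})
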