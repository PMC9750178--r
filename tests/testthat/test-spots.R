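test_that("detection finds seeded emitters with high recall and precision", {
  cc_field <- rbc_field()
  dm <- boltzmann_density(cc_field, rbc_profile())
  sp <- sample_spots(spot_gen_params(n_spots = 80, seed = 21), dm)
  stk <- render_stack(sp, imaging_params(seed = 22))
  det <- detect_spots(stk)
  D <- sqrt(outer(det$x_um, sp$x_um, "-")^2 +
              outer(det$y_um, sp$y_um, "-")^2 +
              outer(det$z_um, sp$z_um, "-")^2)
  recall <- mean(apply(D, 2, min) < 0.15)
  precision <- mean(apply(D, 1, min) < 0.15)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("a blank stack yields no spots and metadata is mandatory", {
  blank <- render_stack(sample_spots(
    spot_gen_params(n_spots = 0, density = "uniform"), rbc_field()),
    imaging_params(seed = 2),
    bounds_um = list(x = c(-1, 1), y = c(-1, 1), z = c(-0.5, 0.5)))
  expect_equal(nrow(detect_spots(blank)), 0)
  a <- array(0, c(32, 32, 4))
  expect_error(detect_spots(a), "voxel sizes")
})

test_that("detection is translation-equivariant for whole-voxel shifts", {
  set.seed(77)
  sp <- data.frame(cell_id = 1L,
                   x_um = c(0.6, 1.7, 2.5), y_um = c(0.7, 2.1, 1.1),
                   z_um = c(0, 0.25, -0.25),
                   intensity = 1, region = "unassigned")
  class(sp) <- c("spot_set", "data.frame")
  p <- imaging_params(seed = 3)
  b0 <- list(x = c(-0.5, 3.3), y = c(-0.5, 3.3), z = c(-1, 1))
  stk <- render_stack(sp, p, bounds_um = b0)
  shift <- c(5, 3)                               # voxels
  sp2 <- sp
  sp2$x_um <- sp$x_um + shift[1] * 0.04
  sp2$y_um <- sp$y_um + shift[2] * 0.04
  p2 <- imaging_params(seed = 3)
  stk2 <- render_stack(sp2, p2, bounds_um = b0)
  d1 <- detect_spots(stk)
  d2 <- detect_spots(stk2)
  expect_equal(nrow(d1), nrow(d2))
  o1 <- order(d1$x_um); o2 <- order(d2$x_um)
  expect_equal(d2$x_um[o2] - d1$x_um[o1], rep(shift[1] * 0.04, nrow(d1)),
               tolerance = 0.02)
  expect_equal(d2$y_um[o2] - d1$y_um[o1], rep(shift[2] * 0.04, nrow(d1)),
               tolerance = 0.02)
})

test_that("nearest-neighbour distances: pair identity and rigid invariance", {
  two <- data.frame(cell_id = 1L, x_um = c(0, 0.3), y_um = c(0, 0.4),
                    z_um = 0, intensity = 1, region = "unassigned")
  class(two) <- c("spot_set", "data.frame")
  nn <- nearest_neighbor(two)
  expect_equal(unname(nn$per_cell_mean_nm), 500)
  expect_equal(unname(nn$per_spot_nm[["1"]]), c(500, 500))
  ## rigid motion leaves all NNDs unchanged
  set.seed(13)
  s <- data.frame(cell_id = 1L, x_um = runif(30, 0, 5),
                  y_um = runif(30, 0, 5), z_um = 0,
                  intensity = 1, region = "unassigned")
  class(s) <- c("spot_set", "data.frame")
  th <- 0.7
  s2 <- s
  s2$x_um <- cos(th) * s$x_um - sin(th) * s$y_um + 3
  s2$y_um <- sin(th) * s$x_um + cos(th) * s$y_um - 1
  expect_equal(sort(nearest_neighbor(s)$per_spot_nm[[1]]),
               sort(nearest_neighbor(s2)$per_spot_nm[[1]]), tolerance = 1e-9)
  expect_error(nearest_neighbor(s[1, , drop = FALSE]), "fewer than 2")
})

test_that("edge masking drops edge queries but keeps them as neighbours", {
  ## an interior spot whose nearest neighbour sits near the boundary
  s <- data.frame(cell_id = 1L,
                  x_um = c(0.5, 2.0, -1.45), y_um = c(0, 0, 0),
                  z_um = 0, intensity = 1, region = "unassigned")
  class(s) <- c("spot_set", "data.frame")
  m <- disc_mask(c(0, 0), 2.2)
  nn <- nearest_neighbor(s, mask = m, edge_margin = 0.3)
  ## spot 2 (0.2 um from the boundary) is excluded as a query, so only
  ## spots 1 and 3 are queried -- but spot 1's nearest neighbour is still
  ## the masked edge spot 2 at 1.5 um, not spot 3 at 1.95 um
  expect_equal(length(nn$per_spot_nm[[1]]), 2)
  expect_equal(min(nn$per_spot_nm[[1]]), 1500, tolerance = 1e-9)
})

test_that("across-cell aggregation is the mean and SD of per-cell means", {
  s1 <- data.frame(cell_id = 1L, x_um = c(0, 1), y_um = 0, z_um = 0,
                   intensity = 1, region = "unassigned")
  s2 <- data.frame(cell_id = 2L, x_um = c(0, 0.5), y_um = 0, z_um = 0,
                   intensity = 1, region = "unassigned")
  s <- rbind(s1, s2)
  class(s) <- c("spot_set", "data.frame")
  nn <- nearest_neighbor(s)
  expect_equal(nn$mean_nm, mean(c(1000, 500)))
  expect_equal(nn$sd_nm, sd(c(1000, 500)))
  expect_equal(nn$n_cells, 2)
})

test_that("CSR on a torus matches the closed-form mean NND", {
  ## Poisson intensity lambda: E[NND] = 1/(2 sqrt(lambda)); a torus has no
  ## edge effects so the closed form is exact
  lambda <- 0.58
  side <- 6.565                                  # area ~ 43.1 um^2, n ~ 25
  m <- rect_mask(c(0, side), c(0, side), torus = TRUE)
  set.seed(55)
  means <- replicate(60, {
    n <- rpois(1, lambda * m$area)
    if (n < 2) return(NA_real_)
    p <- cbind(runif(n, 0, side), runif(n, 0, side))
    D <- piezorbc:::pair_dists(p[, 1], p[, 2], m)
    diag(D) <- Inf
    mean(apply(D, 1, min)) * 1000
  })
  means <- means[!is.na(means)]
  expected <- 1000 / (2 * sqrt(lambda))          # ~656 nm
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 10)
})

test_that("CSR envelopes are calibrated and detect Thomas clustering", {
  m <- disc_mask(c(0, 0), 3.3)
  set.seed(202)
  ## calibration: CSR draws stay inside their own envelopes at ~ the nominal
  ## rate (pointwise min/max of 39 simulations is a 5% test)
  inside <- replicate(20, {
    p <- piezorbc:::mask_runif(m, 26)
    s <- data.frame(cell_id = 1, x_um = p[, 1], y_um = p[, 2], z_um = 0,
                    intensity = 1, region = "unassigned")
    csr_envelope(s, m, n_sim = 39)$inside_fraction
  })
  expect_gte(mean(inside), 0.92)
  ## power: a Thomas process (parents 0.1 / um^2, 5 offspring, sigma 50 nm)
  ## exits the upper envelope at short distances in >= 90% of runs
  hits <- replicate(20, {
    np <- max(1, rpois(1, 0.1 * m$area))
    px <- piezorbc:::mask_runif(m, np)
    nk <- rpois(np, 5)
    x <- rep(px[, 1], nk) + rnorm(sum(nk), 0, 0.05)
    y <- rep(px[, 2], nk) + rnorm(sum(nk), 0, 0.05)
    keep <- piezorbc:::mask_contains(m, x, y)
    if (sum(keep) < 5) return(NA)
    s <- data.frame(cell_id = 1, x_um = x[keep], y_um = y[keep], z_um = 0,
                    intensity = 1, region = "unassigned")
    env <- csr_envelope(s, m, n_sim = 39)
    short <- env$r_um <= 0.3
    any(env$G_obs[short] > env$hi[short])
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
  expect_error(csr_envelope(s, m, n_sim = 5), "19")
})

test_that("model-sampled patterns at observed abundance look random", {
  ## spots drawn from the smooth curvature-coupling density in an unroofed
  ## patch: at n = 26 per patch the pattern is indistinguishable from CSR
  dm <- boltzmann_density(rbc_field(), rbc_profile())
  m <- disc_mask(c(0, 0), 3.3)
  verdicts <- vapply(1:5, function(s) {
    sp <- sample_spots(spot_gen_params(n_spots = 200, seed = 300 + s), dm)
    up <- sp[sp$z_um > 0 & sqrt(sp$x_um^2 + sp$y_um^2) < m$radius, ]
    up <- up[seq_len(min(26, nrow(up))), ]
    csr_envelope(up, m, n_sim = 39, seed = 400 + s)$consistent_with_csr
  }, logical(1))
  expect_gte(mean(verdicts), 0.8)
})

test_that("region densities aggregate per cell with the ratio convention", {
  f <- rbc_field()
  seg <- segment_surface(f)
  ## construct two cells with known counts
  mk <- function(cell, nd, nr) data.frame(
    cell_id = cell, x_um = 0, y_um = 0, z_um = 0, intensity = 1,
    region = c(rep("dimple", nd), rep("rim", nr)))
  s <- rbind(mk(1, 10, 20), mk(2, 30, 10))
  class(s) <- c("spot_set", "data.frame")
  rd <- region_density(s, seg)
  r1 <- (10 / seg$dimple_area) / (20 / seg$rim_area)
  r2 <- (30 / seg$dimple_area) / (10 / seg$rim_area)
  expect_equal(rd$ratio_mean, mean(c(r1, r2)), tolerance = 1e-12)
  expect_equal(rd$ratio_sd, sd(c(r1, r2)), tolerance = 1e-12)
  ## mean of per-cell ratios, not the pooled-density ratio
  pooled <- (40 / seg$dimple_area) / (30 / seg$rim_area)
  expect_false(isTRUE(all.equal(rd$ratio_mean, pooled)))
  ## zero rim count excluded with a warning
  s3 <- rbind(s, mk(3, 5, 0))
  class(s3) <- c("spot_set", "data.frame")
  expect_warning(rd3 <- region_density(s3, seg), "zero rim")
  expect_equal(rd3$n_cells, 2)
})

test_that("uniformly sampled spots have unit dimple/rim density ratio", {
  f <- rbc_field()
  seg <- segment_surface(f)
  sp <- sample_spots(spot_gen_params(n_spots = 5000, density = "uniform",
                                     seed = 61), f)
  rd <- region_density(sp, seg)
  expect_equal(rd$ratio_mean, 1, tolerance = 0.1)
  ## labels match an independent geometric assignment: on the tangent-arc
  ## cell the dimple caps are exactly the points within the tangency radius
  model <- attr(f, "model")
  rho <- sqrt(sp$x_um^2 + sp$y_um^2)
  expect_equal(sp$region == "dimple", rho <= model$rho_t + 1e-9)
})

test_that("sampling from the density map reproduces its region integrals", {
  dm <- boltzmann_density(rbc_field(), rbc_profile())
  seg <- segment_surface(rbc_field())
  sp <- sample_spots(spot_gen_params(n_spots = 20000, seed = 62), dm)
  p_dimple <- sum(dm$P_per_um2[seg$labels == "dimple"] *
                    dm$dA_um2[seg$labels == "dimple"])
  obs <- c(sum(sp$region == "dimple"), sum(sp$region == "rim"))
  chi <- stats::chisq.test(obs, p = c(p_dimple, 1 - p_dimple))
  expect_gte(chi$p.value, 0.01)
})
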