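## small synthetic section with arbitrary masses at given pixels
mk_pair <- function(npx, px_nm, apix, bpix, avals = NULL, bvals = NULL) {
  A <- matrix(0, npx, npx); B <- matrix(0, npx, npx)
  A[apix] <- if (is.null(avals)) 10 else avals
  B[bpix] <- if (is.null(bvals)) 10 else bvals
  list(A = A, B = B, px_nm = px_nm)
}

test_that("identical images colocalize completely at every threshold", {
  set.seed(1)
  A <- matrix(0, 16, 16)
  A[sample(256, 12)] <- rpois(12, 50) + 5
  oc <- otc_curve(list(A = A, B = A, px_nm = 12.5),
                  thresholds_nm = c(0, 12.5, 100), mass_frac = 1)
  expect_equal(oc$otc, c(1, 1, 1), tolerance = 1e-12)
})

test_that("two offset point masses force a step at their separation", {
  p <- mk_pair(16, 12.5, cbind(3, 3), cbind(7, 3))   # 4 px = 50 nm apart
  oc <- otc_curve(p, thresholds_nm = c(12.5, 25, 49, 50, 60), mass_frac = 1)
  expect_equal(oc$otc, c(0, 0, 0, 1, 1), tolerance = 1e-12)
})

test_that("OTC is symmetric in the two channels", {
  set.seed(8)
  A <- matrix(0, 20, 20); B <- matrix(0, 20, 20)
  A[sample(400, 15)] <- runif(15, 1, 20)
  B[sample(400, 11)] <- runif(11, 1, 20)
  th <- seq(12.5, 300, by = 12.5)
  o1 <- otc_curve(list(A = A, B = B, px_nm = 12.5), th, mass_frac = 1)
  o2 <- otc_curve(list(A = B, B = A, px_nm = 12.5), th, mass_frac = 1)
  expect_equal(o1$otc, o2$otc, tolerance = 1e-9)
})

test_that("plans conserve marginals and OTC curves are monotone to 1", {
  set.seed(9)
  A <- matrix(0, 16, 16); B <- matrix(0, 16, 16)
  A[sample(256, 10)] <- runif(10, 1, 5)
  B[sample(256, 14)] <- runif(14, 1, 5)
  pair <- list(A = A, B = B, px_nm = 12.5)
  dmax <- 12.5 * 16 * sqrt(2)
  oc <- otc_curve(pair, thresholds_nm = seq(5, dmax, length.out = 40),
                  mass_frac = 1)
  expect_true(all(diff(oc$otc) >= -1e-12))
  expect_true(all(oc$otc >= 0 & oc$otc <= 1 + 1e-12))
  expect_equal(oc$otc[40], 1, tolerance = 1e-12)
  plan <- attr(oc, "plan")
  sa <- A[A > 0] / sum(A[A > 0]); sb <- B[B > 0] / sum(B[B > 0])
  expect_equal(as.numeric(plan$marg_a), sa, tolerance = 1e-9)
  expect_equal(as.numeric(plan$marg_b), sb, tolerance = 1e-9)
  expect_true(all(plan$mass > 0))
})

test_that("the production solver matches an exhaustive matching oracle", {
  ## equal unit masses: the transportation LP reduces to optimal assignment,
  ## solvable exactly by enumerating all permutations
  for (seed in 1:4) {
    set.seed(seed)
    n <- 6
    pos_a <- cbind(sample(16, n), sample(16, n))
    pos_b <- cbind(sample(16, n), sample(16, n))
    D <- sqrt(outer(pos_a[, 1], pos_b[, 1], "-")^2 +
                outer(pos_a[, 2], pos_b[, 2], "-")^2) * 12.5
    pl <- transport_plan(rep(1, n), rep(1, n), D)
    bf <- bf_matching(D)
    expect_equal(pl$cost, bf$cost, tolerance = 1e-6)
    th <- seq(12.5, 300, by = 12.5)
    moved <- D[cbind(pl$from, pl$to)]
    otc_prod <- vapply(th, function(t) sum(pl$mass[moved <= t + 1e-9]), 0)
    expect_equal(otc_prod, bf_otc(D, bf$perm, th), tolerance = 1e-6)
  }
})

test_that("plans on random unequal masses pass the dual optimality certificate", {
  for (seed in 5:8) {
    set.seed(seed)
    m <- 12; n <- 9
    C <- matrix(runif(m * n, 0, 100), m, n)
    a <- runif(m); b <- runif(n)
    pl <- transport_plan(a, b, C)
    expect_true(check_plan_optimal(pl, C))
  }
})

test_that("confidence bands collapse for identical sections and shrink as 1/sqrt(n)", {
  set.seed(3)
  A <- matrix(0, 16, 16); B <- matrix(0, 16, 16)
  A[sample(256, 8)] <- 30; B[sample(256, 8)] <- 30
  sec <- list(A = A, B = B, px_nm = 12.5)
  b0 <- otc_bands(list(sec, sec, sec), mass_frac = 1)
  expect_equal(b0$ci_lo, b0$otc_mean, tolerance = 1e-9)
  expect_equal(b0$ci_hi, b0$otc_mean, tolerance = 1e-9)
  ## iid-perturbed small sections: band width scales ~ 1/sqrt(n)
  gen <- function(k) make_section_pair(0.5, n_spots = 4, npx = 16,
                                       seed = 1000 + k)
  th <- seq(12.5, 200, by = 25)
  w <- vapply(c(4, 16, 64), function(n) {
    b <- otc_bands(lapply(seq_len(n), gen), thresholds_nm = th)
    mean(b$ci_hi - b$ci_lo)
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.45)
  expect_equal(w[2] / w[3], 2, tolerance = 0.45)
  expect_warning(otc_bands(list(sec)), "single section")
})

test_that("colocalized and independent fixtures separate at 100 nm", {
  band3_like <- otc_bands(lapply(1:4, function(k)
    make_section_pair(0.85, displacement_nm = 25, n_spots = 5, seed = 50 + k)))
  piezo_like <- otc_bands(lapply(1:4, function(k)
    make_section_pair(0.10, displacement_nm = 25, n_spots = 5, seed = 60 + k)))
  i100 <- which.min(abs(band3_like$threshold_nm - 100))
  expect_gt(band3_like$otc_mean[i100], 0.5)
  expect_lt(piezo_like$otc_mean[i100], 0.3)
  expect_gt(band3_like$otc_mean[i100], piezo_like$otc_mean[i100] + 0.3)
})

test_that("coincident channels give OTC ~ 1 at the first threshold", {
  p <- make_section_pair(1, displacement_nm = 0, n_spots = 6, npx = 32,
                         seed = 1)
  oc <- otc_curve(p)
  expect_gt(oc$otc[1], 0.9)
})

test_that("OTC at 100 nm rises with the colocalized fraction", {
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    mean(vapply(1:3, function(s) {
      oc <- otc_curve(make_section_pair(f, displacement_nm = 20,
                                        n_spots = 10, npx = 32,
                                        seed = round(1000 * f) + s))
      oc$otc[which.min(abs(oc$threshold_nm - 100))]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("degenerate inputs are rejected", {
  A <- matrix(0, 8, 8)
  expect_error(otc_curve(list(A = A, B = A, px_nm = 12.5), mass_frac = 1),
               "no signal")
  expect_error(transport_plan(c(-1, 2), c(1), matrix(0, 2, 1)),
               "nonnegative")
  B <- matrix(1, 4, 4)
  expect_error(otc_curve(list(A = matrix(1, 8, 8), B = B, px_nm = 12.5)),
               "dimensions")
})
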