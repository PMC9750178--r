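## Independent oracles used across the suite.  These deliberately avoid the
## code paths they check.

## Brute-force optimal matching between n equal-mass points (exhaustive over
## permutations): the exact LP solution of the transportation problem when
## both sides carry n unit masses.
bf_matching <- function(D) {
  n <- nrow(D)
  stopifnot(n <= 7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; bcost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(D[cbind(seq_len(n), p)])
    if (cost < bcost) { bcost <- cost; best <- p }
  }
  list(cost = bcost / n, perm = best)
}

## OTC curve implied by a unit-mass matching
bf_otc <- function(D, perm, thresholds) {
  moved <- D[cbind(seq_along(perm), perm)]
  vapply(thresholds, function(t) mean(moved <= t + 1e-9), numeric(1))
}

## Complementary-slackness certificate: given a transport plan on supports
## with cost matrix C, recover dual potentials over the support graph and
## verify that no arc has negative reduced cost (optimality of the plan).
check_plan_optimal <- function(plan, C, tol = 1e-7) {
  m <- plan$m; n <- plan$n
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  edges <- cbind(plan$from, plan$to)
  u[edges[1, 1]] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      if (!is.na(u[i]) && is.na(v[j])) { v[j] <- C[i, j] - u[i]; changed <- TRUE }
      if (is.na(u[i]) && !is.na(v[j])) { u[i] <- C[i, j] - v[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  ## disconnected support components: anchor each separately
  while (any(is.na(u)) || any(is.na(v))) {
    k <- which(is.na(u[edges[, 1]]))[1]
    if (is.na(k)) break
    u[edges[k, 1]] <- 0
    repeat {
      changed <- FALSE
      for (kk in seq_len(nrow(edges))) {
        i <- edges[kk, 1]; j <- edges[kk, 2]
        if (!is.na(u[i]) && is.na(v[j])) { v[j] <- C[i, j] - u[i]; changed <- TRUE }
        if (is.na(u[i]) && !is.na(v[j])) { u[i] <- C[i, j] - v[j]; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  ok_cs <- all(abs(C[edges] - u[edges[, 1]] - v[edges[, 2]]) < tol)
  rc <- outer(u, v, "+")
  ok_feas <- all(C - rc > -tol, na.rm = TRUE)
  ok_cs && ok_feas
}

## finite-difference principal curvatures of an axisymmetric upper profile
## z(rho), under the package sign convention (sphere -> -1/R)
fd_curvatures <- function(model, rho, h = 1e-5) {
  z <- function(r) surface_profile(model, r)$z
  zp <- (z(rho + h) - z(rho - h)) / (2 * h)
  zpp <- (z(rho + h) - 2 * z(rho) + z(rho - h)) / h^2
  list(c1 = zpp / (1 + zp^2)^1.5,
       c2 = zp / (rho * sqrt(1 + zp^2)))
}

## trapezoid bending energy recomputed from a traced meridian shape,
## independent of the ODE's own energy accumulator
trace_energy <- function(tr, Kb) {
  s <- tr[, "s"]; psi <- tr[, "psi"]; r <- tr[, "r"]
  u <- c(diff(psi) / diff(s), NA)
  u <- (c(u[1], u[-length(u)]) + c(u[-length(u)], u[length(u) - 1])) / 2
  w <- u + sin(psi) / r
  integrand <- pi * r * w^2
  Kb * sum(diff(s) * (integrand[-1] + integrand[-length(s)]) / 2)
}

## small calibrated model cached for reuse across tests
rbc_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- calibrate_discocyte()
    m
  }
})

rbc_field <- local({
  f <- NULL
  function() {
    if (is.null(f)) f <<- mean_curvature_field(rbc_model(), 2001)
    f
  }
})

## energy profile cached (25-point default grid)
rbc_profile <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- energy_vs_curvature()
    p
  }
})
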