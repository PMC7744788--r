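test_that("flow fields respect profile shape, no-slip and the mean-velocity identity", {
  g <- buildPVOstium(13, spacingMm = 0.5)
  f0 <- makeFlowField(g, 0)
  expect_true(all(f0@vx == 0 & f0@vy == 0 & f0@vz == 0))

  f <- makeFlowField(g, 0.16, "poiseuille")
  lab <- voxelLabels(g)
  expect_true(all(f@vz[lab != scenarioLabelCodes()[["blood"]]] == 0))

  # centreline velocity equals the peak; wall-adjacent blood is zero
  d <- dim(lab)
  ic <- round(d[1] / 2)
  kMid <- round(mean(g@meta$slabZIdx))
  expect_equal(max(f@vz[, , kMid]), 0.16, tolerance = 0.01)

  # cross-section mean = peak/2 for the parabolic profile (lumen slice away
  # from the wall layer; mask is the analytic lumen disc)
  cc <- (seq_len(d[1]) - 0.5) * 0.5
  r2 <- outer((cc - g@meta$centerMm[1])^2, (cc - g@meta$centerMm[2])^2, `+`)
  lum <- r2 < (13 / 2)^2
  expect_equal(mean(f@vz[, , 3][lum]), 0.16 / 2, tolerance = 0.05)

  # no-slip: every blood voxel with a non-blood face neighbour is static
  blood <- lab == scenarioLabelCodes()[["blood"]]
  w <- which(blood, arr.ind = TRUE)
  for (r in sample(nrow(w), 500)) {
    i <- w[r, 1]; j <- w[r, 2]; k <- w[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
               nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3], ,
             drop = FALSE]
    if (any(!blood[nb]))
      expect_identical(f@vz[i, j, k], 0)
  }

  gNoBlood <- ScenarioGrid({
    lab <- array(2L, c(5, 5, 5)); lab[1, 1, 1] <- 3L; lab[5, 5, 5] <- 4L; lab
  }, 1)
  expect_error(makeFlowField(gNoBlood, 0.1), "no blood")
})

test_that("Joule source follows q = duty * sigma * E^2 and vanishes where it must", {
  g <- makeParallelPlates(nx = 6, ny = 6, nz = 12, h = 1, sigma = 0.5)
  sol <- solvePotential(g, 100)           # 10 mm -> 1e4 V/m in the slab
  q <- jouleSource(sol, g, 0.5)
  myoInterior <- array(FALSE, dim(q)); myoInterior[, , 4:9] <- TRUE
  expect_equal(range(q[myoInterior]), rep(0.5 * 0.5 * (1e4)^2, 2),
               tolerance = 1e-6)

  expect_true(all(jouleSource(sol, g, 0) == 0))

  # insulator voxels stay cold regardless of the local field
  lab <- voxelLabels(g); lab[3, 3, 6] <- scenarioLabelCodes()[["insulator"]]
  gI <- assignMaterials(ScenarioGrid(lab, 1), defaultMaterialTable())
  solI <- solvePotential(gI, 100)
  qI <- jouleSource(solI, gI, 0.5)
  expect_identical(qI[3, 3, 6], 0)
})

test_that("zero source leaves the domain exactly at baseline", {
  g <- assignMaterials(buildSeptal(15, spacingMm = 1))
  tr <- simulateTransient(g, source = NULL, burstS = 1e-4, relaxS = 0.02)
  expect_true(all(abs(probeSeries(tr)$domain_max - 37) < 1e-9))
  expect_true(all(abs(peakMapC(tr) - 37) < 1e-9))
})

test_that("1D diffusion of a Gaussian excess matches the heat-kernel solution", {
  g <- makeRod(n = 400, h = 0.2)
  d <- dim(voxelLabels(g))
  z <- (seq_len(d[3]) - 0.5) * 0.2       # mm
  z0 <- 40; s0 <- 1.0; A <- 5
  init <- array(37, d)
  for (k in seq_len(d[3])) init[, , k] <- 37 + A * exp(-(z[k] - z0)^2 / (2 * s0^2))
  alpha <- 0.56 / (1081 * 3686) * 1e6    # mm^2/s
  tEnd <- 3
  tr <- simulateTransient(g, source = NULL, burstS = 0, relaxS = tEnd,
                          dtRelaxS = 0.002, boundary = "adiabatic",
                          initialC = init)
  sT2 <- s0^2 + 2 * alpha * tEnd
  analytic <- A * s0 / sqrt(sT2) * exp(-(z - z0)^2 / (2 * sT2))
  profile <- finalMapC(tr)[2, 2, ] - 37
  l2 <- sqrt(sum((profile - analytic)^2) / sum(analytic^2))
  expect_lt(l2, 0.01)
})

test_that("burst heating conserves energy under adiabatic boundaries", {
  g <- assignMaterials(buildSeptal(15, spacingMm = 1, padMm = 5, bloodMm = 6))
  sol <- solvePotential(g, 1500)
  q <- jouleSource(sol, g, 0.5)
  m <- gridMaterials(g)
  hM <- spacingMm(g) * 1e-3
  tr <- simulateTransient(g, q, burstS = 1e-4, relaxS = 0,
                          dtBurstS = 1e-6, boundary = "adiabatic")
  injected <- sum(q) * hM^3 * 1e-4
  gained <- sum(m$rho * m$cp * (finalMapC(tr) - 37)) * hM^3
  expect_equal(gained, injected, tolerance = 0.02)

  # energy is conserved through the relaxation as well (no boundary loss)
  trR <- simulateTransient(g, q, burstS = 1e-4, relaxS = 0.02,
                           boundary = "adiabatic")
  gainedR <- sum(m$rho * m$cp * (finalMapC(trR) - 37)) * hM^3
  expect_equal(gainedR, injected, tolerance = 0.02)
})

test_that("doubling the applied voltage quadruples the initial heating rate", {
  g <- assignMaterials(buildSeptal(15, spacingMm = 1))
  s1 <- solvePotential(g, 750)
  s2 <- solvePotential(g, 1500)
  q1 <- jouleSource(s1, g, 0.5)
  q2 <- jouleSource(s2, g, 0.5)
  tr1 <- simulateTransient(g, q1, burstS = 1e-5, relaxS = 0, dtBurstS = 1e-6)
  tr2 <- simulateTransient(g, q2, burstS = 1e-5, relaxS = 0, dtBurstS = 1e-6)
  rise1 <- utils::tail(probeSeries(tr1)$domain_max, 1) - 37
  rise2 <- utils::tail(probeSeries(tr2)$domain_max, 1) - 37
  expect_equal(rise2 / rise1, 4, tolerance = 0.01)
})

test_that("post-burst relaxation is monotone and flow cooling is ordered and saturating", {
  g <- assignMaterials(buildAtrialWall(spacingMm = 1, bloodMm = 8))
  sol <- solvePotential(g, 900)
  q <- jouleSource(sol, g, 0.5)

  # no-flow: domain max never increases after the burst ends
  tr <- simulateTransient(g, q, burstS = 1e-4, relaxS = 0.1)
  dm <- probeSeries(tr)$domain_max
  post <- dm[-(1:101)]
  expect_true(all(diff(post) <= 1e-9))

  # sweep: end-of-relaxation blood temperature decreases with velocity and
  # the marginal effect shrinks (convective saturation)
  ends <- vapply(c(0, 0.08, 0.16), function(v) {
    flow <- if (v > 0) makeFlowField(g, v, "poiseuille") else NULL
    trV <- simulateTransient(g, q, flow, burstS = 1e-4, relaxS = 0.2)
    utils::tail(probeSeries(trV)$blood, 1)
  }, numeric(1))
  expect_true(all(diff(ends) < 0))
  expect_lt(abs(ends[3] - ends[2]), abs(ends[2] - ends[1]))

  # peak blood temperature non-increasing in velocity (numerical tolerance)
  peaks <- vapply(c(0, 0.08, 0.16), function(v) {
    flow <- if (v > 0) makeFlowField(g, v, "poiseuille") else NULL
    trV <- simulateTransient(g, q, flow, burstS = 1e-4, relaxS = 0.05)
    max(probeSeries(trV)$blood)
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-6))
})

test_that("unstable explicit steps and CFL violations are rejected with bounds", {
  g <- assignMaterials(buildSeptal(15, spacingMm = 1))
  expect_error(
    simulateTransient(g, NULL, burstS = 0, relaxS = 0.05, dtRelaxS = 2e-2,
                      scheme = "explicit"),
    "stability|unstable")
  flow <- makeFlowField(g, 1.5, "plug")   # CFL bound ~ h/u = 6.7e-4 s
  expect_error(
    simulateTransient(g, NULL, flow = flow, burstS = 0, relaxS = 0.01,
                      dtRelaxS = 1e-3),
    "CFL")
})
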