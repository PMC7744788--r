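test_that("decay fitting recovers generator parameters exactly and under noise", {
  d <- genDecaySeries(amplitudeC = 7.6, tauMs = 9.22, noiseFrac = 0)
  f <- fitExponentialDecay(d$series$time_s, d$series$temp_c)
  expect_equal(f@amplitudeC, 7.6, tolerance = 1e-3 * 0.1)
  expect_equal(f@tauMs, 9.22, tolerance = 1e-3 * 0.1)
  expect_equal(f@baselineC, 37, tolerance = 1e-6)

  dN <- genDecaySeries(noiseFrac = 0.01, seed = 21)
  fN <- fitExponentialDecay(dN$series$time_s, dN$series$temp_c)
  expect_equal(fN@tauMs, 9.22, tolerance = 0.05)

  # residual excess at t = 4*tau is e^-4 of the amplitude (analytic check on
  # the noiseless series)
  t4 <- 4 * 9.22 / 1000
  idx <- which.min(abs(d$series$time_s - t4))
  expect_equal((d$series$temp_c[idx] - 37) / 7.6, exp(-4), tolerance = 0.02)
})

test_that("decay fitting rejects constant, short and non-decaying series", {
  t <- seq(0, 0.05, by = 1e-3)
  expect_error(fitExponentialDecay(t, rep(37, length(t))), "constant")
  expect_error(fitExponentialDecay(t[1:5], 37 + exp(-t[1:5])), "10 samples")
  expect_error(fitExponentialDecay(t, 37 + 5 * (1 - exp(-t / 0.01))),
               "not decay")
})

test_that("noisy decay recovery stays within 2% median error over 100 replicates", {
  errs <- vapply(1:100, function(s) {
    d <- genDecaySeries(noiseFrac = 0.01, seed = s)
    f <- fitExponentialDecay(d$series$time_s, d$series$temp_c)
    abs(f@tauMs - 9.22) / 9.22
  }, numeric(1))
  expect_lte(median(errs), 0.02)
  expect_lte(max(errs), 0.05)
})

# synthetic point-electrode field: E = V a / r^2 (V/cm after conversion),
# the far-field of a small spherical electrode at voltage V with radius a
makePointSourceField <- function(se, V) {
  rM <- pmax(se$rMm, se$aMm) * 1e-3           # m
  eVm <- V * (se$aMm * 1e-3) / rM^2
  new("FieldSolution", potential = array(0, dim(se$rMm)),
      eMag = eVm / 100, jMag = eVm * 0.381 / 1000,
      totalCurrentA = 0, appliedVolts = V, residual = 0, currentBalance = 0)
}

test_that("effective field radius matches the spherical-electrode closed form", {
  h <- 0.5
  # domain wide enough that the far-field return shell is never the nearest
  # electrode for any super-threshold voxel
  se <- makeSphericalElectrode(aMm = 1, h = h, LMm = 10)
  sol <- makePointSourceField(se, 900)
  # super-threshold outer radius sqrt(V a / E_th) = 4.74 mm at 400 V/cm
  rOut <- sqrt(900 * 1e-3 / 4e4) * 1e3
  rad <- effectiveFieldRadius(sol, se$grid, 400, "electrode_surface")
  expect_equal(rad, rOut - 1, tolerance = h / (rOut - 1))

  # independent brute-force oracle over the mask (surface voxels found by a
  # direct neighbour scan)
  lab <- voxelLabels(se$grid)
  mask <- lab == scenarioLabelCodes()[["myocardium"]] & fieldVcm(sol) >= 400
  elecCode <- scenarioLabelCodes()[["electrode_line"]]
  elec <- which(lab == elecCode, arr.ind = TRUE)
  dd <- dim(lab)
  onSurf <- vapply(seq_len(nrow(elec)), function(r) {
    i <- elec[r, 1]; j <- elec[r, 2]; k <- elec[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= dd[1] & nb[, 2] >= 1 &
               nb[, 2] <= dd[2] & nb[, 3] >= 1 & nb[, 3] <= dd[3], ,
             drop = FALSE]
    any(lab[nb] != elecCode)
  }, logical(1))
  surf <- elec[onSurf, , drop = FALSE]
  mi <- which(mask, arr.ind = TRUE)
  bf <- max(vapply(seq_len(nrow(mi)), function(r)
    sqrt(min(colSums((t(surf) - mi[r, ])^2))) * h, numeric(1)))
  expect_equal(rad, bf, tolerance = 1e-9)

  # threshold above the global maximum: nothing treated
  expect_identical(effectiveFieldRadius(sol, se$grid, 1e9), 0)
})

test_that("effective radius is monotone in voltage and in threshold", {
  se <- makeSphericalElectrode(aMm = 1, h = 0.5, LMm = 7)
  radAtV <- vapply(c(300, 600, 900, 1200), function(V)
    effectiveFieldRadius(makePointSourceField(se, V), se$grid, 400),
    numeric(1))
  expect_true(all(diff(radAtV) >= 0))

  sol <- makePointSourceField(se, 900)
  radAtTh <- vapply(c(200, 400, 800, 1600), function(th)
    effectiveFieldRadius(sol, se$grid, th), numeric(1))
  expect_true(all(diff(radAtTh) <= 0))
})

test_that("untreated gap orders aligned vs misaligned septa and matches a 1D scan", {
  h <- 1
  gA <- buildSeptal(15, 0, 0, spacingMm = h)
  sA <- solvePotential(gA, 1500)
  gM <- buildSeptal(15, 10, 0, spacingMm = h)
  sM <- solvePotential(gM, 1500)

  expect_identical(untreatedGap(sA, gA, thresholdVcm = 1e-12), 0)

  th <- 400
  gapA <- untreatedGap(sA, gA, th)
  gapM <- untreatedGap(sM, gM, th)
  expect_gte(gapM, gapA)

  # independent re-scan of the aligned axis
  eg <- electrodeGroups(gA)
  p0 <- colMeans((which(eg$groups == 1L, arr.ind = TRUE) - 0.5) * h)
  p1 <- colMeans((which(eg$groups == 2L, arr.ind = TRUE) - 0.5) * h)
  nS <- 400
  tt <- seq(0, 1, length.out = nS)
  runBest <- run <- 0
  for (i in seq_len(nS)) {
    p <- p0 + tt[i] * (p1 - p0)
    ijk <- pmin(pmax(ceiling(p / h), 1), dim(voxelLabels(gA)))
    myo <- voxelLabels(gA)[ijk[1], ijk[2], ijk[3]] ==
      scenarioLabelCodes()[["myocardium"]]
    sub <- myo && fieldVcm(sA)[ijk[1], ijk[2], ijk[3]] < th
    run <- if (sub) run + 1 else 0
    runBest <- max(runBest, run)
  }
  stepMm <- sqrt(sum((p1 - p0)^2)) / (nS - 1)
  expect_equal(gapA, runBest * stepMm, tolerance = 0.15)

  expect_error(untreatedGap(sA, gA, 400,
                            axis = list(p0 = c(0.5, 0.5, 0.5),
                                        p1 = c(0.5, 0.5, 1.5))),
               "misses")
})

test_that("alignment sensitivity is the sample CV in percent", {
  expect_identical(alignmentSensitivity(c(3, 3, 3)), 0)
  expect_equal(alignmentSensitivity(c(1, 2, 3)), 50)
  expect_equal(alignmentSensitivity(c(5.0, 5.5, 4.5, 5.0)), 8.164966,
               tolerance = 1e-6)
  expect_error(alignmentSensitivity(5), ">= 2")
  expect_error(alignmentSensitivity(c(-1, 1)), "mean is zero")
})

test_that("lesion reports carry the full summary-table structure for all scenarios", {
  need <- c("voltageAppliedV", "eFieldMaxKVcm", "eFieldMeanVcm", "jMeanKAm2",
            "jMaxKAm2", "tInterfaceMaxC", "effectiveRadiusMm",
            "untreatedGapMm", "thresholdVcm")
  for (kind in c("pv_ostium", "atrial_wall", "septal")) {
    g <- switch(kind,
                pv_ostium = buildPVOstium(13, spacingMm = 1),
                atrial_wall = buildAtrialWall(spacingMm = 1),
                septal = buildSeptal(15, spacingMm = 1))
    g <- assignMaterials(g)
    V <- if (kind == "septal") 1500 else 900
    sol <- solvePotential(g, V)
    q <- jouleSource(sol, g, 0.5)
    tr <- simulateTransient(g, q, burstS = 1e-4, relaxS = 0.05)
    rep <- lesionReport(g, sol, trace = tr)
    expect_true(all(need %in% names(rep)))
    expect_equal(rep$voltageAppliedV, V)
    expect_gte(rep$effectiveRadiusMm, 0)
    expect_gt(rep$tInterfaceMaxC, 37 - 1e-9)
    if (kind == "septal") expect_false(is.na(rep$untreatedGapMm))
    else expect_true(is.na(rep$untreatedGapMm))
  }
})
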