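test_that("PV ostium geometry resolves the lumen and the alternating ring", {
  g <- suppressWarnings(buildPVOstium(13, spacingMm = 0.25))
  expect_s4_class(g, "ScenarioGrid")

  # lumen voxel cross-section area within 5% of pi r^2 (slice mid-wall)
  kMid <- round(mean(g@meta$slabZIdx))
  sl <- voxelLabels(g)[, , kMid]
  areaVox <- sum(sl == scenarioLabelCodes()[["blood"]]) * 0.25^2
  expect_equal(areaVox, pi * 6.5^2, tolerance = 0.05)

  # 10 electrode groups, polarity alternating line/neutral around the ring
  eg <- electrodeGroups(g)
  expect_length(eg$polarity, 10L)
  expect_identical(eg$polarity, rep(c("line", "neutral"), 5))
  expect_setequal(unique(as.vector(eg$groups)), 0:10)

  expect_error(buildPVOstium(0), "positive")
  expect_warning(buildPVOstium(16), "12-14")
  expect_error(buildPVOstium(13, electrodeMm = 1, spacingMm = 1.5), "coarse")
})

test_that("lumen voxelization converges to the analytic area with refinement", {
  errs <- vapply(c(1, 0.5, 0.25), function(h) {
    g <- buildPVOstium(13, spacingMm = h)
    kMid <- round(mean(g@meta$slabZIdx))
    area <- sum(voxelLabels(g)[, , kMid] ==
                  scenarioLabelCodes()[["blood"]]) * h^2
    abs(area - pi * 6.5^2) / (pi * 6.5^2)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("atrial wall build places a 10-electrode loop on the endocardial face", {
  g <- buildAtrialWall(wallMm = 5.85, spacingMm = 0.25, loopDiameterMm = 20)
  lab <- voxelLabels(g)
  slab <- g@meta$slabZIdx
  expect_true((diff(slab) + 1L) %in% 23:24)   # 5.85 mm at 0.25 mm spacing

  eg <- electrodeGroups(g)
  expect_length(eg$polarity, 10L)
  expect_identical(eg$polarity, rep(c("line", "neutral"), 5))

  # every group touches the slab: its voxels sit in the first blood layer
  # above the wall, face-adjacent to myocardium
  zE <- g@meta$electrodeZIdx
  expect_identical(zE, max(slab) + 1L)
  for (grpId in 1:10) {
    w <- which(eg$groups == grpId, arr.ind = TRUE)
    expect_true(all(w[, 3] == zE))
    below <- lab[cbind(w[, 1], w[, 2], w[, 3] - 1L)]
    expect_true(all(below == scenarioLabelCodes()[["myocardium"]]))
  }

  expect_error(buildAtrialWall(loopDiameterMm = 30, lateralMm = 25),
               "loop larger")
})

test_that("septal build honours separation, misalignment and symmetry", {
  h <- 0.5
  g0 <- buildSeptal(15, 0, 0, spacingMm = h)
  lab <- voxelLabels(g0)
  line <- which(lab == scenarioLabelCodes()[["electrode_line"]],
                arr.ind = TRUE)
  neut <- which(lab == scenarioLabelCodes()[["electrode_neutral"]],
                arr.ind = TRUE)
  gap <- (min(line[, 3]) - max(neut[, 3]) - 1) * h   # face-to-face, mm
  expect_equal(gap, 15, tolerance = h / 15)

  gOff <- buildSeptal(15, 10, 0, spacingMm = h)
  labO <- voxelLabels(gOff)
  lineX <- mean(which(labO == scenarioLabelCodes()[["electrode_line"]],
                      arr.ind = TRUE)[, 1]) * h
  neutX <- mean(which(labO == scenarioLabelCodes()[["electrode_neutral"]],
                      arr.ind = TRUE)[, 1]) * h
  expect_equal(abs(lineX - neutX), 10, tolerance = h / 10)
  expect_equal(diff(gOff@meta$axisXMm), 10)

  # tilted + offset build is valid and records its parameters
  gT <- buildSeptal(15, 10, 45, spacingMm = h)
  expect_s4_class(gT, "ScenarioGrid")
  expect_equal(gT@meta$tiltDeg, 45)

  # mirror symmetry of the aligned construction with equal tips
  gS <- buildSeptal(15, 0, 0, spacingMm = h,
                    tipLenMm = c(line = 3, neutral = 3))
  labS <- voxelLabels(gS)
  mirrored <- labS[, , rev(seq_len(dim(labS)[3]))]
  swapped <- mirrored
  swapped[mirrored == scenarioLabelCodes()[["electrode_line"]]] <-
    scenarioLabelCodes()[["electrode_neutral"]]
  swapped[mirrored == scenarioLabelCodes()[["electrode_neutral"]]] <-
    scenarioLabelCodes()[["electrode_line"]]
  expect_identical(labS, swapped)
})

test_that("septal construction is translation-invariant voxel for voxel", {
  h <- 0.5
  gA <- buildSeptal(15, 0, 0, spacingMm = h, bloodMm = 8)
  gB <- buildSeptal(15, 0, 0, spacingMm = h, bloodMm = 8 + h)
  labA <- voxelLabels(gA); labB <- voxelLabels(gB)
  nzA <- dim(labA)[3]
  expect_identical(labB[, , 1 + seq_len(nzA)], labA)
})

test_that("grid validity rejects shorted or single-polarity geometries", {
  lab <- array(2L, c(6, 6, 6))
  lab[2, 2, 2] <- 3L
  expect_error(ScenarioGrid(lab, 1), "electrode_neutral")
  lab[2, 2, 3] <- 4L                      # face-adjacent: dead short
  expect_error(ScenarioGrid(lab, 1), "short circuit")
  lab[2, 2, 3] <- 2L
  lab[2, 2, 4] <- 4L                      # diagonal-free separation
  expect_s4_class(ScenarioGrid(lab, 1), "ScenarioGrid")
})

test_that("material attachment populates per-voxel fields and honours overrides", {
  tb <- defaultMaterialTable()
  expect_gt(tb@values["blood", "sigma"], tb@values["myocardium", "sigma"])
  expect_lte(tb@values["insulator", "sigma"], 1e-6)

  g <- assignMaterials(buildAtrialWall(spacingMm = 1))
  m <- gridMaterials(g)
  myo <- voxelLabels(g) == scenarioLabelCodes()[["myocardium"]]
  expect_true(all(m$sigma[myo] == 0.381))
  expect_true(all(m$k[!myo & voxelLabels(g) ==
                        scenarioLabelCodes()[["blood"]]] == 0.52))

  gOv <- assignMaterials(buildAtrialWall(spacingMm = 1),
                         defaultMaterialTable(list(myocardium = c(sigma = 0.5))))
  expect_true(all(gridMaterials(gOv)$sigma[myo] == 0.5))

  # missing label is reported by name
  small <- defaultMaterialTable()
  small@values <- small@values[rownames(small@values) != "myocardium", ]
  expect_error(assignMaterials(buildAtrialWall(spacingMm = 1), small),
               "myocardium")
})
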