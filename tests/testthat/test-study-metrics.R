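test_that("volume fractions count labels correctly and always sum to 100", {
  lab <- array(1L, c(10, 10, 5))
  lab[1:2, , ] <- 2L           # 20% of the specimen non-myocardial
  seg <- SegmentationVolume(lab, voxelMm = 0.5)
  vf <- volumeFractions(seg)
  expect_equal(vf$nonmyoPct, 20)
  expect_equal(vf$vPct, 80)
  expect_identical(vf$vPct + vf$nonmyoPct, 100)

  allMyo <- SegmentationVolume(array(1L, c(4, 4, 4)), voxelMm = 1)
  expect_equal(volumeFractions(allMyo)$nonmyoPct, 0)

  # generator ground truth at an awkward fraction
  s <- genSegmentation(dims = c(40, 40, 24), lesionFraction = 0,
                       nativeFraction = 0.0925, seed = 8)
  expect_equal(volumeFractions(s)$nonmyoPct, 9.25, tolerance = 0.5 / 9.25)

  # per-slice values also complement
  ps <- vf$perSlice
  expect_true(all(abs(ps$v_pct + ps$nonmyo_pct - 100) < 1e-12, na.rm = TRUE))
})

test_that("control subtraction reproduces the worked example and flags negatives", {
  expect_identical(ablatedFraction(20.25, 9.225, digits = 2), 11.03)
  expect_identical(ablatedFraction(15, 15), 0)
  expect_warning(out <- ablatedFraction(5, 9), "negative")
  expect_equal(out, -4)

  # recovery of an injected lesion fraction from a synthetic pair
  for (seed in c(1, 7)) {
    tr <- genSegmentation(dims = c(48, 48, 30), lesionFraction = 0.11,
                          nativeFraction = 0.09, seed = seed)
    ct <- genSegmentation(dims = c(48, 48, 30), lesionFraction = 0,
                          nativeFraction = 0.09, seed = seed + 100)
    abl <- ablatedFraction(volumeFractions(tr)$nonmyoPct,
                           volumeFractions(ct)$nonmyoPct)
    expect_equal(abl, 11, tolerance = 0.5 / 11)
  }
})

test_that("extruded-cylinder reference ratio recovers construction truth and scales as d^-2", {
  # slab specimen with an odd voxel count across the wall: thickness exact
  seg <- genSegmentation(dims = c(48, 48, 20), wallMm = 5.5, voxelMm = 0.5,
                         shape = "slab", lesionFraction = 0,
                         nativeFraction = 0, seed = 1)
  er <- extrusionReferenceRatio(seg, ablatedVolumeMm3 = 100,
                                loopDiameterMm = 20)
  expect_equal(er$maxWallMm, 5.5, tolerance = 1e-9)

  # ratio 1 when the ablated volume equals the reference cylinder
  er1 <- extrusionReferenceRatio(seg, er$referenceMm3, 20)
  expect_equal(er1$ratio, 1)

  # synthetic atrium built with ratio 1.4
  target <- 1.4 * pi * 10^2 * 5.5
  expect_equal(extrusionReferenceRatio(seg, target, 20)$ratio, 1.4,
               tolerance = 0.1 / 1.4)

  # doubling the loop diameter quarters the ratio
  expect_equal(extrusionReferenceRatio(seg, target, 40)$ratio,
               extrusionReferenceRatio(seg, target, 20)$ratio / 4)
})

test_that("summary-statistics one-sample t reproduces printed and hand-computed cases", {
  r <- oneSampleTSummary(20.25, 4.40, 5, 9.225)
  expect_equal(round(r$p, 3), 0.005)

  expect_equal(oneSampleTSummary(10, 2, 4, 10)$t, 0)
  expect_equal(oneSampleTSummary(10, 2, 4, 10)$p, 1)

  r2 <- oneSampleTSummary(10, 2, 4, 8)
  expect_equal(r2$t, 2.0)
  expect_equal(r2$p, 0.139, tolerance = 0.01)

  # independent t-CDF oracle: numerically integrate the t density
  tTail <- function(q, df) {
    dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
    integrate(dens, abs(q), Inf, rel.tol = 1e-10)$value
  }
  set.seed(1)
  for (i in 1:20) {
    m <- rnorm(1, 10, 5); s <- runif(1, 0.5, 5); n <- sample(3:40, 1)
    mu0 <- rnorm(1, 10, 5)
    r <- oneSampleTSummary(m, s, n, mu0)
    expect_equal(r$p, 2 * tTail(r$t, n - 1), tolerance = 1e-6)
  }
})

test_that("paired change statistics match per-pair deltas and detect Table-style effects", {
  co <- genEgmCohort(10, seed = 3)
  same <- co$samples
  same$amplitude_post_mv <- same$amplitude_pre_mv
  r <- pairedChangeStats(same, "amplitude")
  expect_equal(r$meanDelta, 0)
  expect_equal(r$p, 1)

  co30 <- genEgmCohort(30, seed = 17)
  ra <- pairedChangeStats(co30$samples, "amplitude")
  expect_lt(ra$p, 1e-4)
  expect_lt(ra$meanDelta, 0)      # amplitude falls after ablation
  rd <- pairedChangeStats(co30$samples, "duration")
  expect_gt(rd$meanDelta, 0)      # duration lengthens

  # brute-force oracle for the delta
  expect_equal(ra$meanDelta,
               mean(co30$samples$amplitude_post_mv -
                      co30$samples$amplitude_pre_mv))

  rw <- pairedChangeStats(co30$samples, "impedance", welch = TRUE)
  expect_match(rw$method, "Welch")
  expect_lt(rw$meanDelta, 0)
})

test_that("Kruskal-Wallis + Dunn matches a hand-ranked oracle and orders p-values", {
  gIdent <- list(a = c(2, 2), b = c(2, 2), c = c(2, 2))
  rI <- kruskalDunn(gIdent)
  expect_equal(rI$omnibusP, 1)
  expect_equal(rI$H, 0)

  # hand-ranked 3x4 toy, no ties: H = 12/(N(N+1)) * sum ni Ri^2 - 3(N+1)
  g <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8), c = c(20, 21, 22, 23))
  rk <- rank(unlist(g))
  Ri <- c(mean(rk[1:4]), mean(rk[5:8]), mean(rk[9:12]))
  Hhand <- 12 / (12 * 13) * sum(4 * Ri^2) - 3 * 13
  r <- kruskalDunn(g)
  expect_equal(r$H, Hhand, tolerance = 1e-12)

  # clearly shifted group: its pairwise comparisons significant
  set.seed(99)
  gs <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, mean = 10))
  rs <- kruskalDunn(gs)
  sig <- rs$pairs[rs$pairs$group1 == "c" | rs$pairs$group2 == "c", ]
  expect_true(all(sig$pAdjusted < 0.01))

  # adjusted p never below unadjusted
  expect_true(all(rs$pairs$pAdjusted >= rs$pairs$p))
  expect_error(kruskalDunn(list(a = 1:3, b = 1:3)), ">= 3 groups")
})
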