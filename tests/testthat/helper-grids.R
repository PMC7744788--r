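# Analytic verification geometries built in code.

# Concentric spherical electrodes (inner line at radius aMm, outer neutral
# shell at bMm) in uniform myocardium; phi has the 1/r closed form.
makeConcentricSpheres <- function(aMm = 2, bMm = 20, h = 0.5) {
  L <- 2 * (bMm + 2 * h)
  n <- round(L / h)
  cc <- (seq_len(n) - 0.5) * h - L / 2
  r <- sqrt(outer(outer(cc^2, cc^2, `+`), cc^2, `+`))
  lab <- array(2L, c(n, n, n))
  lab[r <= aMm] <- 3L
  lab[r >= bMm] <- 4L
  list(grid = ScenarioGrid(lab, h, kind = "custom"), rMm = r,
       aMm = aMm, bMm = bMm)
}

sphereAnalyticPhi <- function(r, a, b, V) V * (1 / r - 1 / b) / (1 / a - 1 / b)

# Full-face plate electrodes across a uniform slab: E = V/d with
# d = (nz - 2) * h, the electrode-face separation. With buffer = TRUE the
# voxel layers touching the plates are relabelled blood (same conductivity),
# so the "myocardium" mask selects the interior where central differences
# are second-order.
makeParallelPlates <- function(nx = 10, ny = 10, nz = 31, h = 0.5,
                               sigma = 0.381, buffer = FALSE) {
  lab <- array(2L, c(nx, ny, nz))
  lab[, , 1] <- 3L
  lab[, , nz] <- 4L
  if (buffer) {
    lab[, , 2] <- 1L
    lab[, , nz - 1] <- 1L
  }
  g <- ScenarioGrid(lab, h, kind = "custom")
  assignMaterials(g, defaultMaterialTable(
    list(myocardium = c(sigma = sigma), blood = c(sigma = sigma))))
}

# Spherical line electrode of radius aMm centred in myocardium; the outer
# voxel shell is the neutral return (far field).
makeSphericalElectrode <- function(aMm = 1, h = 0.25, LMm = 14) {
  n <- round(2 * LMm / h)
  cc <- (seq_len(n) - 0.5) * h - LMm
  r <- sqrt(outer(outer(cc^2, cc^2, `+`), cc^2, `+`))
  lab <- array(2L, c(n, n, n))
  lab[r <= aMm] <- 3L
  shell <- array(FALSE, dim(lab))
  shell[c(1, n), , ] <- TRUE; shell[, c(1, n), ] <- TRUE
  shell[, , c(1, n)] <- TRUE
  lab[shell] <- 4L
  list(grid = ScenarioGrid(lab, h, kind = "custom"), rMm = r, aMm = aMm)
}

# Thermally homogeneous rod (3 x 3 x n myocardium) for 1D diffusion checks;
# the two token electrode voxels sit at one end and get myocardial thermal
# properties so the rod is uniform.
makeRod <- function(n = 400, h = 0.2) {
  lab <- array(2L, c(3, 3, n))
  lab[1, 1, 1] <- 3L
  lab[3, 3, 1] <- 4L
  g <- ScenarioGrid(lab, h, kind = "custom")
  tb <- defaultMaterialTable(list(
    electrode_line = c(k = 0.56, rho = 1081, cp = 3686),
    electrode_neutral = c(k = 0.56, rho = 1081, cp = 3686)))
  assignMaterials(g, tb)
}

# independent polarity-run cycle counter for sampled bipolar waveforms: one
# full cycle = one positive and one negative lobe
countCyclesByZeroCrossing <- function(v) {
  s <- sign(v[v != 0])
  length(rle(s)$lengths) / 2
}
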