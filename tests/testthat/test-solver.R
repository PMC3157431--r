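test_that("presets encode the study geometries", {
  d <- configPreset("default")
  expect_equal(halfLength(d$chamber), 10.8e-3)
  expect_equal(chamberHeight(d$chamber), 150e-6)
  expect_identical(nSpots(d$layout), 900L)
  expect_equal(chamberHeight(configPreset("deep")$chamber), 750e-6)
  expect_equal(halfLength(configPreset("small")$chamber), 4.5e-3)
  fc <- configPreset("full_coverage")
  expect_identical(nSpots(fc$layout), 5040L)
  expect_equal(chamberHeight(fc$chamber), 250e-6)
  for (nm in c("default", "deep", "small", "full_coverage")) {
    lay <- configPreset(nm)$layout
    expect_equal(spotDiameter(lay), 150e-6)
    expect_equal(spotPitch(lay), 300e-6)
  }
  expect_error(configPreset("huge"), "arg")
})

test_that("grid construction is deterministic and rasterizes spots correctly", {
  cfg <- configPreset("small")
  g1 <- buildGrid(cfg$chamber, cfg$layout)
  g2 <- buildGrid(cfg$chamber, cfg$layout)
  expect_identical(g1@spotId, g2@spotId)
  expect_identical(nrow(g1@spotTable), 225L)  # quadrant of 30x30

  # mask must equal an independent enumeration of cell centers in disks
  ctr <- spotCenters(cfg$layout)
  xc <- g1@x0 + (seq_len(g1@nx) - 0.5) * g1@dx
  yc <- g1@y0 + (seq_len(g1@ny) - 0.5) * g1@dy
  rad <- spotDiameter(cfg$layout) / 2
  inAny <- matrix(FALSE, g1@nx, g1@ny)
  for (s in seq_len(nrow(ctr))) {
    dx2 <- (xc - ctr$x[s])^2
    dy2 <- (yc - ctr$y[s])^2
    inAny <- inAny | (outer(dx2, dy2, `+`) <= rad^2)
  }
  expect_identical(unname(g1@spotId > 0L), unname(inAny))

  # rasterized area converges to n * pi r^2 under refinement
  areaErr <- function(res) {
    g <- buildGrid(cfg$chamber, cfg$layout, lateralResolution = res)
    a <- sum(g@spotId > 0) * g@dx * g@dy
    abs(a - nrow(g@spotTable) * pi * rad^2) / (nrow(g@spotTable) * pi * rad^2)
  }
  expect_lt(areaErr(12.5e-6), areaErr(50e-6))
  expect_lt(areaErr(12.5e-6), 0.05)
  expect_error(buildGrid(chamberGeometry(10.8e-3, 150e-6),
                         spotArrayLayout(31, 30)), "even")
  expect_error(buildGrid(cfg$chamber, cfg$layout, lateralResolution = 4e-4),
               "coarser")
})

test_that("quadrant grids carry exactly a quarter of the sink cells", {
  ch <- chamberGeometry(1.2e-3, 150e-6)
  lay <- spotArrayLayout(4, 4)
  gq <- buildGrid(ch, lay, symmetry = "quadrant")
  gf <- buildGrid(ch, lay, symmetry = "full")
  expect_identical(sum(gf@spotId > 0L), 4L * sum(gq@spotId > 0L))
  expect_identical(nrow(gf@spotTable), 4L * nrow(gq@spotTable))
})

test_that("initial field is uniform and carries the chamber mass", {
  cfg <- configPreset("small")
  g <- buildGrid(cfg$chamber, cfg$layout)
  f <- initializeField(g)
  expect_equal(range(f@values), c(1, 1))
  expect_equal(totalMass(g, f),
               (2 * halfLength(cfg$chamber))^2 * chamberHeight(cfg$chamber))
})

test_that("without sinks the field stays exactly uniform (pure Neumann)", {
  ch <- chamberGeometry(1.2e-3, 150e-6)
  g <- buildGrid(ch, spotArrayLayout(4, 4), symmetry = "full")
  g@spotId[] <- 0L   # strip the sinks: all boundaries no-flux
  f <- initializeField(g)
  for (i in 1:5) f <- advanceField(g, f, dt = 100, D = 1e-9)
  expect_equal(range(f@values), c(1, 1), tolerance = 1e-13)
  expect_equal(sum(spotFlux(g, f, 1e-9)), 0)
})

test_that("spot flux implements Fick's law on a prescribed linear profile", {
  ch <- chamberGeometry(1.2e-3, 150e-6)
  g <- buildGrid(ch, spotArrayLayout(4, 4), symmetry = "full")
  H <- chamberHeight(ch)
  zc <- (seq_len(g@nz) - 0.5) * g@dz
  f <- initializeField(g)
  f@values <- array(rep(zc / H, each = g@nx * g@ny),
                    dim = c(g@nx, g@ny, g@nz))
  fl <- spotFlux(g, f, D = 1e-9)
  for (s in seq_len(nrow(g@spotTable))) {
    A <- sum(g@spotId == s) * g@dx * g@dy
    expect_equal(fl[s], 1e-9 * A / H, tolerance = 1e-12)
  }
})

test_that("all-absorbing floor matches the 1D slab series solution", {
  # C(z,t) = sum 4/((2n+1)pi) sin((2n+1)pi z/(2H)) exp(-((2n+1)pi/(2H))^2 D t)
  # absorbed fraction = 1 - sum 8/((2n+1)^2 pi^2) exp(...)
  slab_absorbed <- function(t, H, D, nterms = 200) {
    n <- 0:(nterms - 1)
    lam <- ((2 * n + 1) * pi / (2 * H))^2 * D
    1 - sum(8 / ((2 * n + 1)^2 * pi^2) * exp(-lam * t))
  }
  ch <- chamberGeometry(0.5e-3, 150e-6)
  lay <- spotArrayLayout(2, 2)  # ignored: allAbsorbingFloor
  tEnd <- 10; D <- 1e-9
  absorbed_frac <- function(nzc, dt) {
    fx <- runSimulation(ch, lay, D = D, duration = tEnd, dt = dt,
                        verticalCells = nzc, symmetry = "full",
                        allAbsorbingFloor = TRUE, outputInterval = tEnd)
    sum(fx@cumulative[nrow(fx@cumulative), ]) / fx@initialMass
  }
  exact <- slab_absorbed(tEnd, 150e-6, D)
  coarse <- abs(absorbed_frac(6, 0.5) - exact) / exact
  fine <- abs(absorbed_frac(24, 0.1) - exact) / exact
  expect_lt(fine, coarse)      # refinement converges toward the series
  expect_lt(fine, 0.01)        # within 1% when refined
})

test_that("halving D and doubling time reproduces identical fluxes", {
  ch <- chamberGeometry(1.2e-3, 150e-6)
  lay <- spotArrayLayout(4, 4)
  a <- runSimulation(ch, lay, D = 1e-9, duration = 600, dt = 30,
                     outputInterval = 600)
  b <- runSimulation(ch, lay, D = 0.5e-9, duration = 1200, dt = 60,
                     outputInterval = 1200)
  expect_equal(a@cumulative[nrow(a@cumulative), ],
               b@cumulative[nrow(b@cumulative), ], tolerance = 1e-12)
})

test_that("quadrant symmetry reproduces the full-domain solution", {
  q <- mini_bias_run(duration = 1800, symmetry = "quadrant")
  f <- mini_bias_run(duration = 1800, symmetry = "full")
  key <- function(x) order(x@spots$row, x@spots$col)
  cq <- q@cumulative[nrow(q@cumulative), key(q)]
  cf <- f@cumulative[nrow(f@cumulative), key(f)]
  expect_equal(length(cq), length(cf))
  expect_lt(max(abs(cq - cf) / cf), 0.005)
})

test_that("per-spot flux map respects the square symmetry group", {
  f <- mini_bias_run(duration = 1800, symmetry = "full")
  ft <- fluxTable(f)
  m <- matrix(NA_real_, 8, 8)
  m[cbind(ft$row + 1L, ft$col + 1L)] <- ft$cumulative_flux
  for (tr in list(t(m), m[8:1, ], m[, 8:1], t(m)[8:1, ])) {
    expect_lt(max(abs(m - tr) / m), 0.005)
  }
})

test_that("solver conserves mass and obeys the maximum principle", {
  fx <- mini_bias_run(duration = 3600, outputInterval = 600)
  expect_lt(max(massBalanceError(fx)), 5e-3)   # property bound
  expect_lt(max(massBalanceError(fx)), 1e-9)   # scheme is conservative
  # instantaneous rates track the loss of total mass between outputs
  dm <- -diff(fx@mass)
  dt <- diff(fx@times)
  approx <- (rowSums(fx@instantaneous)[-1] +
             rowSums(fx@instantaneous)[-length(fx@times)]) / 2 * dt
  expect_lt(max(abs(approx - dm) / dm), 0.05)
  # short runs may carry small start-up transients...
  expect_gte(min(fx@finalField), -1e-4)
  expect_lte(max(fx@finalField), 1 + 1e-4)
  # ...which decay: at 24 h the field is in [0, 1] to solver tolerance
  fx24 <- mini_bias_run(duration = 24 * 3600)
  expect_gte(min(fx24@finalField), -1e-9)
  expect_lte(max(fx24@finalField), 1 + 1e-9)
})

test_that("zero spotless margin removes the boundary bias exactly", {
  # with a 75 um margin the chamber is tiled perfectly by 300 um spot
  # tiles, so all spots are equivalent by symmetry: flux spread ~ 0
  cfg <- configPreset("small")
  fx <- runSimulation(cfg$chamber, cfg$layout)
  v <- fluxTable(fx)$cumulative_flux
  expect_lt((max(v) - min(v)) / mean(v), 1e-10)
  expect_equal(innerOuterRatio(fx), 100, tolerance = 1e-10)
})

test_that("full-coverage design is flat along the exactly tiled axis", {
  # 72 columns x 300 um tile the 21.6 mm chamber exactly; the 70-row
  # axis leaves a 375 um spotless strip whose enhancement the model
  # confines to the outermost few rows
  cfg <- configPreset("full_coverage")
  fx <- runSimulation(cfg$chamber, cfg$layout)
  ft <- fluxTable(fx)
  mid <- ft[ft$row >= 20 & ft$row <= 49, ]
  cm <- tapply(mid$cumulative_flux,
               pmin(mid$col, 71 - mid$col) + 1L, mean)
  expect_lt((max(cm) - min(cm)) / mean(cm), 1e-10)
  rowm <- tapply(ft$cumulative_flux, ft$row, mean)
  central <- median(rowm)
  expect_gt(rowm[1] / central, 1.2)        # margin-side rows enhanced
  expect_lt(max(abs(rowm[10:60] / central - 1)), 0.01)  # interior flat
})

test_that("cumulative flux decreases from the boundary inward", {
  fx <- mini_bias_run(duration = 2 * 3600)
  ft <- fluxTable(fx)
  means <- tapply(ft$cumulative_flux, ft$ring_position, mean)
  expect_identical(names(means), as.character(1:4))
  expect_true(all(diff(as.numeric(means)) <= 0))
  # corner spots receive the most target (transect maximum at corners)
  corner <- ft$cumulative_flux[ft$row == 0 & ft$col == 0]
  edgeMid <- ft$cumulative_flux[ft$row == 0 & ft$col == 3]
  expect_gt(corner, edgeMid)
})
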