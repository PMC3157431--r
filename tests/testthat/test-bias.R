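test_that("position summaries recover uniform and profiled tables", {
  u <- uniform_table(8, 8, value = 42)
  s <- summarizeByPosition(u)
  expect_identical(s$position, 1:4)
  expect_true(all(s$mean == 42))
  expect_true(all(s$sd == 0))
  # replicate counts on the 30x30 grid: 116, 108, ..., 4
  s30 <- summarizeByPosition(uniform_table(30, 30, 1))
  expect_identical(s30$n, as.integer(116 - 8 * (0:14)))
  expect_identical(s30$n[15], 4L)
  # exact ring-mean profile is recovered with zero spread
  prof <- c(40, 30, 20, 10)
  sp <- summarizeByPosition(ring_profile_table(prof, 8, 8))
  expect_equal(sp$mean, prof)
  expect_true(all(sp$sd == 0))
})

test_that("pooled replicate summaries equal the weighted per-table combination", {
  p <- syntheticArrayParams(nRows = 10, nCols = 10, nReplicates = 3,
                            noiseCV = 0.2, flagFraction = 0, seed = 9)
  tabs <- generateTables(p)$tables
  pooled <- summarizeByPosition(tabs)
  per <- lapply(tabs, summarizeByPosition)
  for (i in seq_len(nrow(pooled))) {
    w <- vapply(per, function(x) x$n[i], 1L)
    m <- vapply(per, function(x) x$mean[i], 1)
    expect_equal(pooled$mean[i], sum(w * m) / sum(w))
  }
  expect_true("repMeanSd" %in% names(pooled))
})

test_that("flagged spots are excluded and empty rings warn", {
  u <- uniform_table(6, 6, value = 10)
  u@spots$ch1[u@spots$flag >= 0][1:3] <- 1e6   # corrupt three spots...
  u@spots$flag[1:3] <- -100L                   # ...then flag them out
  s <- summarizeByPosition(u)
  expect_true(all(s$mean == 10))
  # flag out the entire innermost ring (central 2x2 of a 6x6)
  ctr <- ringMembers(3, 6, 6)
  u2 <- uniform_table(6, 6, value = 10)
  sel <- paste(u2@spots$row, u2@spots$col) %in% paste(ctr$row, ctr$col)
  u2@spots$flag[sel] <- -50L
  expect_warning(s2 <- summarizeByPosition(u2), "position")
  expect_false(3L %in% s2$position)
})

test_that("normalization modes rescale to their reference position", {
  sp <- summarizeByPosition(ring_profile_table(c(40, 30, 20, 10), 8, 8))
  nmax <- normalizePositions(sp, "max")
  nmin <- normalizePositions(sp, "min")
  expect_equal(max(nmax$relativeMean), 1)
  expect_equal(min(nmin$relativeMean), 1)
  expect_equal(nmin$relativeMean / nmax$relativeMean,
               rep(4, 4))  # modes differ by one multiplicative constant
})

test_that("inner/outer ratio is a scale-free percentage", {
  expect_equal(innerOuterRatio(uniform_table(8, 8, 5)), 100)
  tab <- ring_profile_table(c(40, 30, 20, 10), 8, 8)
  expect_equal(innerOuterRatio(tab), 25)
  tab2 <- ring_profile_table(7 * c(40, 30, 20, 10), 8, 8)
  expect_equal(innerOuterRatio(tab2), 25)   # invariant to rescaling
  df <- data.frame(row = tab@spots$row, col = tab@spots$col,
                   value = tab@spots$ch1)
  expect_equal(innerOuterRatio(df, nRows = 8, nCols = 8), 25)
})

test_that("channel ratios by position are exact and swap to reciprocals", {
  u <- uniform_table(8, 8, value = 30, two = TRUE, ch2value = 10)
  cr <- channelRatioByPosition(u)
  expect_equal(cr$ratio, rep(3, 4))
  # swapping channels inverts the ratio
  sw <- u
  sw@spots[c("ch1", "ch2")] <- sw@spots[c("ch2", "ch1")]
  expect_equal(channelRatioByPosition(sw)$ratio, 1 / cr$ratio)
  # permuting spot order within the table leaves ratios unchanged
  perm <- u
  perm@spots <- perm@spots[sample(nrow(perm@spots)), ]
  expect_equal(channelRatioByPosition(perm)$ratio, cr$ratio)
  expect_error(channelRatioByPosition(uniform_table(8, 8, 5)), "channel")
})

test_that("position t-test matches the pooled-variance textbook formula", {
  # three replicate hybridizations whose ring means are 9,10,11 (ring 1)
  # and 19,20,21 (ring 2): t = -10 / sqrt(1 * 2/3), df = 4
  tabs <- lapply(0:2, function(i) {
    tab <- ring_profile_table(c(9 + i, 19 + i), 4, 4)
    tab
  })
  res <- positionTTest(tabs, ringA = 1, ringB = 2)
  tExp <- (10 - 20) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, tExp)
  expect_identical(res$df, 4L)
  expect_equal(res$p, 2 * pt(-abs(tExp), 4))
  expect_lt(res$p, 0.01)
  # symmetric: swapping groups negates t, preserves p
  res2 <- positionTTest(tabs, ringA = 2, ringB = 1)
  expect_equal(res2$t, -res$t)
  expect_equal(res2$p, res$p)
  # identical groups: t = 0, p = 1 (degenerate variance handled)
  same <- positionTTest(tabs, ringA = 1, tables2 = tabs)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(positionTTest(tabs[1], ringA = 1, ringB = 2), "replicate")
})

test_that("transect profiles are flat for uniform data and consistent for ring-constant data", {
  u <- uniform_table(8, 8, value = 7)
  for (kind in c("diagonal", "center_line")) {
    tp <- transectProfile(u, kind)
    expect_equal(tp$relativeMean, rep(1, 4))
  }
  # a ring-constant table gives transect means equal to the ring summary
  prof <- c(40, 30, 20, 10)
  tab <- ring_profile_table(prof, 8, 8)
  tp <- transectProfile(tab, "diagonal")
  expect_equal(tp$mean, prof)
  expect_identical(tp$n, rep(4L, 4))  # 4 diagonal paths
  expect_identical(transectProfile(tab, "center_line")$n, rep(8L, 4))
})

test_that("simulated fluxes show the corner-dominated U-profile on transects", {
  fx <- mini_bias_run(duration = 2 * 3600)
  tab <- tableFromFlux(fx)
  dia <- transectProfile(tab, "diagonal")
  mid <- transectProfile(tab, "center_line")
  # diagonal transects start at corners, which see the largest flux
  expect_gt(dia$mean[1], mid$mean[1])
  expect_gt(dia$relativeMean[1], 1)
})

test_that("noise-free generator output makes all estimators exact", {
  p <- syntheticArrayParams(nRows = 8, nCols = 8, noiseCV = 0,
                            flagFraction = 0, nReplicates = 2, seed = 3)
  out <- generateTables(p)
  s <- summarizeByPosition(out$tables)
  expect_equal(s$mean, out$truth$ringMeans[, 1])
  expect_true(all(s$sd == 0))
  expect_equal(innerOuterRatio(out$tables[[1]]),
               100 * out$truth$ringMeans[4, 1] / out$truth$ringMeans[1, 1])
})
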