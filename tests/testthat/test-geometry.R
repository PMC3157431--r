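test_that("ring positions reproduce the printed layout anchors", {
  expect_identical(ringPosition(0, 0, 30, 30), 1L)
  expect_identical(ringPosition(14, 14, 30, 30), 15L)
  expect_identical(ringPosition(29, 29, 30, 30), 1L)
  g <- expand.grid(r = 0:69, c = 0:71)
  expect_identical(max(ringPosition(g$r, g$c, 70, 72)), 35L)
  expect_identical(maxRing(30, 30), 15L)
  expect_identical(maxRing(70, 72), 35L)
  expect_error(ringPosition(30, 0, 30, 30), "out of range")
})

test_that("ring positions agree with the brute-force border-distance oracle", {
  set.seed(42)
  dims <- rbind(cbind(sample(2:40, 8, TRUE), sample(2:40, 8, TRUE)),
                c(100, 100))
  for (i in seq_len(nrow(dims))) {
    nR <- dims[i, 1]; nC <- dims[i, 2]
    cells <- data.frame(r = sample(0:(nR - 1), 25, TRUE),
                        c = sample(0:(nC - 1), 25, TRUE))
    expected <- mapply(ring_oracle, cells$r, cells$c,
                       MoreArgs = list(nR = nR, nC = nC))
    expect_equal(ringPosition(cells$r, cells$c, nR, nC), expected)
  }
})

test_that("ring membership counts match the replicate-spot bookkeeping", {
  expect_identical(nrow(ringMembers(1, 30, 30)), 116L)   # position 1
  expect_identical(nrow(ringMembers(15, 30, 30)), 4L)    # central 2x2
  inner <- ringMembers(2, 4, 4)
  expect_setequal(paste(inner$row, inner$col),
                  c("1 1", "1 2", "2 1", "2 2"))
  # rings partition the grid, and ring 1 is the full perimeter
  for (d in list(c(5, 9), c(30, 30), c(12, 8))) {
    counts <- vapply(seq_len(maxRing(d[1], d[2])),
                     function(r) nrow(ringMembers(r, d[1], d[2])), 1L)
    expect_equal(sum(counts), d[1] * d[2])
    expect_equal(counts[1], 2 * d[1] + 2 * d[2] - 4)
  }
  expect_error(ringMembers(16, 30, 30), "out of range")
})

test_that("spot centers form a centered grid in physical units", {
  lay <- spotArrayLayout(30, 30)
  ctr <- spotCenters(lay)
  expect_equal(mean(ctr$x), 0)
  expect_equal(mean(ctr$y), 0)
  expect_equal(spotCenters(spotArrayLayout(2, 2))[1, c("x", "y")],
               data.frame(x = -150e-6, y = -150e-6))
  expect_equal(unname(spanLengths(lay)["x"]), 8.85e-3)
  # neighbouring columns are exactly one pitch apart
  expect_equal(diff(sort(unique(ctr$x)))[1], 300e-6)
})

test_that("spotless margins follow (2L - span)/2 and reject overflow", {
  lay <- spotArrayLayout(30, 30)
  expect_equal(unname(spotlessMargin(chamberGeometry(10.8e-3, 150e-6), lay)),
               c(6.375e-3, 6.375e-3))
  expect_equal(unname(spotlessMargin(chamberGeometry(4.5e-3, 150e-6), lay)),
               c(75e-6, 75e-6))
  expect_error(spotlessMargin(chamberGeometry(4e-3, 150e-6), lay),
               "margin")
  expect_error(spotCenters(lay, chamberGeometry(4e-3, 150e-6)),
               "exceeds")
})

test_that("transects visit every ring exactly once, in order", {
  lay <- spotArrayLayout(30, 30)
  diag <- transects(lay, "diagonal")
  mid <- transects(lay, "center_line")
  expect_length(diag, 4L)
  expect_length(mid, 8L)
  for (p in c(diag, mid)) {
    expect_identical(nrow(p), 15L)
    expect_identical(p$ring, 1:15)
  }
  expect_identical(diag[[1]]$row, 0:14)
  expect_identical(diag[[1]]$col, 0:14)
  # no path revisits a spot (the 8 half-paths do share the 4 central
  # cells pairwise, which is inherent to the definition)
  for (p in mid)
    expect_identical(anyDuplicated(paste(p$row, p$col)), 0L)
  expect_error(transects(spotArrayLayout(7, 8), "diagonal"), "even")
})

test_that("transects generalize to the full-coverage 70 x 72 grid", {
  lay <- spotArrayLayout(70, 72)
  for (kind in c("diagonal", "center_line")) {
    for (p in transects(lay, kind)) expect_identical(p$ring, 1:35)
  }
})
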