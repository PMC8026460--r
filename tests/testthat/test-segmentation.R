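test_that("constant image traces to the whole grid", {
  img <- matrix(7, 6, 9)
  tr <- levelTrace(img, c(3, 4), 0)
  expect_true(all(tr@filled))
  b <- tr@boundary
  expect_identical(b[1, ], b[nrow(b), ])
  expect_equal(nrow(b) - 1L, 2L * (6L + 9L))      # border perimeter
  expect_equal(shoelace(b), 6 * 9)
})

test_that("a plus-shaped region is traced with a 12-edge boundary", {
  img <- matrix(0, 5, 5)
  img[2:4, 3] <- 1000
  img[3, 2:4] <- 1000
  tr <- levelTrace(img, c(3, 3), 0)
  expect_equal(sum(tr@filled), 5L)
  expect_true(all(tr@filled[cbind(c(2, 3, 4, 3, 3), c(3, 3, 3, 2, 4))]))
  b <- tr@boundary
  expect_equal(nrow(b) - 1L, 12L)                  # 12 unit crack edges
  expect_equal(shoelace(b), 5)                     # area = 5 pixels
  ## simple contour: no corner repeats except the closing vertex
  expect_false(anyDuplicated(b[-nrow(b), ]) > 0)
})

test_that("level tracing equals the brute-force flood-fill oracle", {
  set.seed(33)
  for (i in 1:100) {
    img <- matrix(sample(0:4, 32 * 32, replace = TRUE), 32, 32)
    seed <- c(sample(32, 1), sample(32, 1))
    tr <- levelTrace(img, seed, 0)
    expect_identical(tr@filled, bruteFloodFill(img, seed, 0))
  }
  ## and with nonzero tolerance
  for (i in 1:20) {
    img <- matrix(sample(0:40, 32 * 32, replace = TRUE), 32, 32)
    seed <- c(sample(32, 1), sample(32, 1))
    tol <- sample(0:10, 1)
    tr <- levelTrace(img, seed, tol)
    expect_identical(tr@filled, bruteFloodFill(img, seed, tol))
  }
})

test_that("the traced region grows monotonically with tolerance", {
  set.seed(34)
  img <- matrix(sample(0:20, 900, replace = TRUE), 30, 30)
  seed <- c(15, 15)
  prev <- levelTrace(img, seed, 0)@filled
  for (tol in c(2, 5, 9, 20)) {
    cur <- levelTrace(img, seed, tol)@filled
    expect_true(all(cur[prev]))                    # set inclusion
    prev <- cur
  }
  expect_true(all(prev))                           # tol >= range: everything
})

test_that("re-seeding inside a traced region reproduces it (tolerance 0)", {
  set.seed(35)
  img <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  tr <- levelTrace(img, c(10, 10), 0)
  inside <- which(tr@filled, arr.ind = TRUE)
  for (j in seq_len(min(5, nrow(inside)))) {
    tr2 <- levelTrace(img, inside[j, ], 0)
    expect_identical(tr2@filled, tr@filled)
  }
})

test_that("seed and tolerance preconditions are enforced", {
  img <- matrix(0, 5, 5)
  expect_error(levelTrace(img, c(0, 3), 0), "outside")
  expect_error(levelTrace(img, c(3, 6), 0), "outside")
  expect_error(levelTrace(img, c(3, 3), -1), ">= 0")
})

test_that("segmenting a noise-free phantom equals midpoint thresholding", {
  lm <- femaleTemplate()$landmarks
  vol <- rasterizePhantom(lm, spacing = 3, bone_intensity = 1000,
                          background_intensity = 0, noise_sd = 0)
  seeds <- suggestBoneSeeds(vol, 500)
  mask <- segmentVolume(vol, seeds, tolerance = 500)
  expect_identical(maskArray(mask), intensities(vol) >= 500)
  expect_length(provenance(mask)$warnings, 0L)
  ## determinism
  mask2 <- segmentVolume(vol, seeds, tolerance = 500)
  expect_identical(maskArray(mask), maskArray(mask2))
  ## unseeded slices stay empty
  one <- seeds[seeds$slice == seeds$slice[1], ]
  m1 <- segmentVolume(vol, one, tolerance = 500)
  expect_true(all(!maskArray(m1)[, , -one$slice[1]]))
})

test_that("segmentVolume validates seeds", {
  vol <- rasterizePhantom(femaleTemplate()$landmarks, spacing = 4)
  expect_error(segmentVolume(vol, data.frame(slice = integer(0),
                                             row = integer(0),
                                             col = integer(0)), 1),
               "at least one seed")
  expect_error(segmentVolume(vol, data.frame(slice = 1e6, row = 1, col = 1),
                             1), "out of range")
})

test_that("a background seed is flagged in provenance, not an error", {
  vol <- rasterizePhantom(femaleTemplate()$landmarks, spacing = 3)
  mask <- segmentVolume(vol, data.frame(slice = 2, row = 2, col = 2),
                        tolerance = 500)
  expect_gt(length(provenance(mask)$warnings), 0L)
})

test_that("seed suggestion yields one seed per component per slice", {
  lm <- femaleTemplate()$landmarks
  vol <- rasterizePhantom(lm, spacing = 3)
  seeds <- suggestBoneSeeds(vol, 500)
  vox <- intensities(vol)
  for (k in unique(seeds$slice)[c(1, 10, 20)]) {
    bw <- vox[, , k] >= 500
    expect_equal(sum(seeds$slice == k), countComponents4(bw))
  }
  ## every suggested seed lies on bone
  expect_true(all(vox[cbind(seeds$row, seeds$col, seeds$slice)] >= 500))
  ## all-background volume: no supra-threshold voxels, no seeds
  bg <- new("VoxelVolume", intensities = array(0, c(4, 4, 4)),
            spacing = c(1, 1, 1), origin = c(0, 0, 0), frame = "LPS")
  expect_equal(nrow(suggestBoneSeeds(bg, 500)), 0L)
})

test_that("a threshold below the minimum yields one seed per slice", {
  vol <- new("VoxelVolume",
             intensities = array(runif(5 * 5 * 3, 10, 20), c(5, 5, 3)),
             spacing = c(1, 1, 1), origin = c(0, 0, 0), frame = "LPS")
  seeds <- suggestBoneSeeds(vol, min(intensities(vol)))
  expect_equal(seeds$slice, 1:3)
})

test_that("suggested tolerance halves the bone/background contrast", {
  sl <- matrix(c(rep(0, 50), rep(1000, 50)), 10, 10)
  expect_equal(suggestTolerance(sl), 500)
  expect_equal(suggestTolerance(matrix(3, 4, 4)), 0)
})
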