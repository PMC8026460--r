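test_that("templates hit published distance targets within 5%", {
  fit <- femaleTemplate()
  rep <- fit$report
  dist_res <- abs(rep$rel_residual[rep$type == "distance"])
  expect_lte(max(dist_res), 0.05)
  ## obstetric conjugate within 5% of the published female mean
  m <- measures(computePelvimetry(fit$landmarks))
  expect_lt(abs(m[["obstetric_conjugate"]] - 126.2) / 126.2, 0.05)
  ## male bis-ischiatic diameter, checked by the independent suite run
  mm <- measures(computePelvimetry(maleTemplate()$landmarks))
  expect_lt(abs(mm[["bis_ischiatic_diameter"]] - 102.2) / 102.2, 0.05)
  ## the report lists exactly the realized suite values
  expect_equal(rep$realized,
               unname(measures(computePelvimetry(fit$landmarks))[rep$measure]))
})

test_that("templates are mirror-symmetric about the mid-sagittal plane", {
  for (tpl in list(femaleTemplate(), maleTemplate())) {
    co <- landmarkCoords(tpl$landmarks)
    lefts <- grep("_L$", rownames(co), value = TRUE)
    for (l in lefts) {
      r <- sub("_L$", "_R", l)
      expect_equal(co[l, ] * c(-1, 1, 1), co[r, ], tolerance = 1e-6)
    }
    mids <- setdiff(rownames(co), c(lefts, sub("_L$", "_R", lefts)))
    expect_true(all(abs(co[mids, 1]) < 1e-6))
  }
})

test_that("fitting targets realized by an existing set is a fixed point", {
  tpl <- femaleTemplate()$landmarks
  m <- measures(computePelvimetry(tpl))
  refit <- buildTemplate(m, seed = 5)
  expect_lt(max(abs(refit$report$rel_residual)), 1e-6)
})

test_that("infeasible target combinations are rejected by name", {
  tg <- defaultMeasureTargets("female")
  bad <- tg
  bad$mean[bad$measure == "promontory_to_coccyx"] <- 200
  expect_error(buildTemplate(bad), "promontory_to_coccyx")
  bad2 <- tg
  bad2$mean[bad2$measure == "pelvic_depth"] <- 300
  expect_error(buildTemplate(bad2), "pelvic_depth")
  incomplete <- tg[tg$measure != "pelvic_depth", ]
  expect_error(buildTemplate(incomplete), "pelvic_depth")
  neg <- tg; neg$mean[1] <- -5
  expect_error(buildTemplate(neg), "positive")
})

test_that("non-convergence errors carry the best-so-far report", {
  ## published targets are mutually inconsistent at the 1e-9 level, so an
  ## absurdly tight residual bound cannot be met
  err <- tryCatch(
    buildTemplate(defaultMeasureTargets("female"), max_residual = 1e-9,
                  maxiter = 50L, restarts = 0L),
    pelvimetryFitError = function(e) e)
  expect_s3_class(err, "pelvimetryFitError")
  expect_s3_class(err$report, "data.frame")
  expect_equal(nrow(err$report), 21L)
})

test_that("zero landmark noise yields exact template copies", {
  p <- phantomParams("female", landmark_noise_scale = 0, seed = 3)
  coh <- sampleLandmarkCohort(p, 5)
  expect_length(coh, 5L)
  ref <- landmarkCoords(attr(coh, "template"))
  for (s in coh) expect_identical(unname(landmarkCoords(s)), unname(ref))
})

test_that("cohort sampling is reproducible given the seed", {
  p <- phantomParams("female", seed = 17)
  a <- sampleLandmarkCohort(p, 4)
  b <- sampleLandmarkCohort(p, 4)
  for (i in 1:4)
    expect_identical(landmarkCoords(a[[i]]), landmarkCoords(b[[i]]))
  c2 <- sampleLandmarkCohort(phantomParams("female", seed = 18), 4)
  expect_false(identical(landmarkCoords(a[[1]]), landmarkCoords(c2[[1]])))
  ## every sampled set passes schema validation
  expect_true(all(vapply(a, function(s) validateSchema(s)$pass, logical(1))))
})

test_that("realized measure SDs approximate their targets", {
  p <- phantomParams("male", seed = 29)
  coh <- sampleLandmarkCohort(p, 120)
  M <- t(vapply(coh, function(s) measures(computePelvimetry(s)), numeric(21)))
  tg <- defaultMeasureTargets("male")
  isd <- tg$type == "distance"
  ratio <- apply(M[, tg$measure[isd]], 2, sd) / tg$sd[isd]
  expect_true(all(ratio > 0.7 & ratio < 1.3))
})

test_that("phantom rasterization is binary without noise and reproducible", {
  lm <- femaleTemplate()$landmarks
  vol <- rasterizePhantom(lm, spacing = 4, bone_intensity = 1000,
                          background_intensity = 0, noise_sd = 0)
  expect_setequal(unique(as.vector(intensities(vol))), c(0, 1000))
  vol2 <- rasterizePhantom(lm, spacing = 4, noise_sd = 25, seed = 9)
  vol3 <- rasterizePhantom(lm, spacing = 4, noise_sd = 25, seed = 9)
  expect_identical(intensities(vol2), intensities(vol3))
  expect_false(identical(intensities(vol2), intensities(vol)))
})

test_that("every landmark lies inside the phantom bone shell", {
  lm <- femaleTemplate()$landmarks
  vol <- rasterizePhantom(lm, spacing = 2, noise_sd = 0)
  co <- landmarkCoords(lm)
  idx <- round(sweep(sweep(co, 2, volumeOrigin(vol), "-"), 2,
                     voxelSpacing(vol), "/")) + 1
  vals <- intensities(vol)[cbind(idx[, 1], idx[, 2], idx[, 3])]
  expect_true(all(vals == 1000))
  ## >= 10-voxel margin beyond the landmarks on every side
  d <- dim(intensities(vol))
  expect_true(all(idx > 10))
  expect_true(all(sweep(idx, 2, d, "-") < -10))
})

test_that("rasterized phantom volume matches the generating solid within 5%", {
  lm <- femaleTemplate()$landmarks
  vol <- rasterizePhantom(lm, spacing = 2, noise_sd = 0)
  vox_vol <- sum(intensities(vol) >= 500) * prod(voxelSpacing(vol))
  solid <- phantomSolidVolume(lm, n = 4e5, seed = 2)
  expect_lt(abs(vox_vol - solid) / solid, 0.05)
})

test_that("too-coarse spacing is rejected with advice", {
  expect_error(rasterizePhantom(femaleTemplate()$landmarks, spacing = 9),
               "finer spacing")
  expect_error(rasterizePhantom(femaleTemplate()$landmarks, spacing = 2,
                                bone_intensity = 0, background_intensity = 10),
               "exceed")
})

test_that("phantom parameter invariants are enforced", {
  tg <- defaultMeasureTargets("female")
  bad <- tg; bad$sd[3] <- -1
  expect_error(phantomParams("female", measure_targets = bad), "sd|SD")
  expect_error(phantomParams("female", landmark_noise_scale = -1), ">= 0")
  rogue <- rbind(tg, data.frame(measure = "femur_length", type = "distance",
                                mean = 400, sd = 10))
  expect_error(phantomParams("female", measure_targets = rogue), "registry")
})
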