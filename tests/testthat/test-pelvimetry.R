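test_that("point distance matches Euclidean geometry", {
  expect_identical(pointDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pointDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pointDistance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  ## symmetry
  set.seed(4)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(pointDistance(a, b), pointDistance(b, a))
  expect_error(pointDistance(c(0, 0, NA), c(1, 1, 1)), "finite")
})

test_that("three-point angle agrees with the law-of-cosines oracle", {
  expect_equal(threePointAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(threePointAngle(c(-2, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  ## acos is ill-conditioned near 0 degrees; a few microdegrees is exact
  ## to within the conditioning of the formula
  expect_lt(threePointAngle(c(1, 1, 0), c(0, 0, 0), c(2, 2, 0)), 1e-4)
  expect_error(threePointAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincides")
  set.seed(11)
  for (i in 1:1000) {
    a <- rnorm(3, sd = 50); v <- rnorm(3, sd = 50); b <- rnorm(3, sd = 50)
    la <- sqrt(sum((a - v)^2)); lb <- sqrt(sum((b - v)^2))
    lab <- sqrt(sum((a - b)^2))
    oracle <- acos(pmin(1, pmax(-1, (la^2 + lb^2 - lab^2) /
                                      (2 * la * lb)))) * 180 / pi
    expect_equal(threePointAngle(a, v, b), oracle, tolerance = 1e-9)
  }
})

test_that("line-plane elevation angle matches the arcsine formula", {
  expect_equal(lineAxisAngle(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)), 0)
  expect_equal(lineAxisAngle(c(0, 0, 0), c(0, 0, 7), c(0, 0, 1)), 90)
  expect_error(lineAxisAngle(c(1, 1, 1), c(1, 1, 1), c(0, 0, 1)),
               "zero-length")
  expect_error(lineAxisAngle(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2)), "unit")
  set.seed(12)
  for (i in 1:200) {
    p <- rnorm(3, sd = 50); q <- rnorm(3, sd = 50)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    d <- q - p
    oracle <- asin(abs(sum(d * ax)) / sqrt(sum(d^2))) * 180 / pi
    expect_equal(lineAxisAngle(p, q, ax), oracle, tolerance = 1e-9)
  }
})

test_that("derived points follow the configuration", {
  lm <- femaleTemplate()$landmarks
  dp <- derivedPoints(lm)
  ## mirror-symmetric template: femoral centre on the mid-sagittal plane
  expect_lt(abs(dp$femoral_centre[1]), 1e-6)
  co <- landmarkCoords(lm)
  expect_equal(dp$inlet_midpoint,
               (co["PS_SUP", ] + co["SACRAL_PROMONTORY", ]) / 2)
  ## switching conjugates moves the midpoint by half the symphysis offset
  dp_true <- derivedPoints(lm, measureConfig(inlet_conjugate = "true"))
  expect_equal(dp_true$inlet_midpoint - dp$inlet_midpoint,
               (co["PS_MID", ] - co["PS_SUP", ]) / 2)
})

test_that("the suite emits exactly the 21 registry measures, all finite", {
  rec <- computePelvimetry(femaleTemplate()$landmarks)
  m <- measures(rec)
  expect_length(m, 21L)
  expect_identical(names(m), measureRegistry()$measure)
  expect_true(all(is.finite(m)))
  reg <- measureRegistry()
  expect_true(all(m[reg$type == "distance"] > 0))
  expect_true(all(m[reg$type == "angle"] > 0 & m[reg$type == "angle"] < 180))
})

test_that("measure bindings follow their landmark definitions", {
  lm <- femaleTemplate()$landmarks
  co <- landmarkCoords(lm)
  m <- measures(computePelvimetry(lm))
  d <- function(a, b) sqrt(sum((co[a, ] - co[b, ])^2))
  expect_equal(unname(m["obstetric_conjugate"]), d("PS_SUP", "SACRAL_PROMONTORY"))
  expect_equal(unname(m["true_conjugate"]), d("PS_MID", "SACRAL_PROMONTORY"))
  expect_equal(unname(m["diagonal_conjugate"]), d("PS_INF", "SACRAL_PROMONTORY"))
  expect_equal(unname(m["straight_conjugate"]), d("PS_INF", "COCCYX_TIP"))
  expect_equal(unname(m["bis_ischiatic_diameter"]),
               d("ISCHIAL_TUBEROSITY_L", "ISCHIAL_TUBEROSITY_R"))
  expect_equal(unname(m["oblique_diameter"]),
               d("SACROILIAC_L", "ILIOPUB_EMINENCE_R"))
  expect_equal(unname(m["inlet_depth_ratio"]),
               unname(m["obstetric_conjugate"] / m["pelvic_depth"]))
  ## oblique side configuration
  m_r <- measures(computePelvimetry(lm, measureConfig(oblique_side = "right")))
  expect_equal(unname(m_r["oblique_diameter"]),
               d("SACROILIAC_R", "ILIOPUB_EMINENCE_L"))
})

test_that("measures are rigid-motion invariant (tilt/beta under vertical-axis rotations)", {
  lm <- femaleTemplate()$landmarks
  m0 <- measures(computePelvimetry(lm))
  frame_dep <- c("pelvic_tilt", "inlet_beta")
  set.seed(21)
  for (i in 1:5) {
    R <- randomRotation(); tr <- rnorm(3, sd = 200)
    m1 <- measures(computePelvimetry(transformLandmarks(lm, R, tr)))
    keep <- setdiff(names(m0), frame_dep)
    expect_equal(m1[keep], m0[keep], tolerance = 1e-9)
  }
  ## rotations about the vertical (anterior-posterior) axis + translations
  ## leave all 21 measures unchanged, including tilt and beta...
  for (ang in c(30, 123, 278)) {
    R <- axisRotation(c(0, 1, 0), ang)
    m1 <- measures(computePelvimetry(transformLandmarks(lm, R, c(5, -40, 12))))
    expect_equal(m1, m0, tolerance = 1e-9)
  }
  ## ...while a tilt about the left-right axis changes both
  mt <- measures(computePelvimetry(
    transformLandmarks(lm, axisRotation(c(1, 0, 0), 10))))
  expect_gt(abs(mt["pelvic_tilt"] - m0["pelvic_tilt"]), 1)
  expect_gt(abs(mt["inlet_beta"] - m0["inlet_beta"]), 1)
})

test_that("uniform scaling scales distances and preserves angles and the ratio", {
  lm <- femaleTemplate()$landmarks
  m0 <- measures(computePelvimetry(lm))
  s <- 1.7
  lm_s <- landmarkSet(landmarkCoords(lm) * s, validate = FALSE)
  m1 <- measures(computePelvimetry(lm_s))
  reg <- measureRegistry()
  dn <- reg$measure[reg$type == "distance"]
  an <- reg$measure[reg$type != "distance"]
  expect_equal(m1[dn], s * m0[dn], tolerance = 1e-12)
  expect_equal(m1[an], m0[an], tolerance = 1e-12)
})

test_that("sacral chain and inlet triangle are geometrically consistent", {
  for (tpl in list(femaleTemplate(), maleTemplate())) {
    m <- measures(computePelvimetry(tpl$landmarks))
    expect_lte(m[["promontory_to_coccyx"]],
               m[["promontory_to_S3S4"]] + m[["S3S4_to_coccyx"]] + 1e-9)
    ## angles of the PS_SUP / promontory / coccyx triangle sum to 180
    co <- landmarkCoords(tpl$landmarks)
    chi <- m[["angle_chi"]]
    at_ps <- threePointAngle(co["SACRAL_PROMONTORY", ], co["PS_SUP", ],
                             co["COCCYX_TIP", ])
    at_cx <- threePointAngle(co["PS_SUP", ], co["COCCYX_TIP", ],
                             co["SACRAL_PROMONTORY", ])
    expect_equal(chi + at_ps + at_cx, 180, tolerance = 1e-6)
  }
})

test_that("missing landmarks are reported by name", {
  co <- landmarkCoords(femaleTemplate()$landmarks)
  crippled <- landmarkSet(co[rownames(co) != "COCCYX_TIP", ],
                          validate = FALSE)
  expect_error(computePelvimetry(crippled), "COCCYX_TIP")
})
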