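## Pelvimetry geometry: the 21-measure suite computed from fiducials.

#' Euclidean distance between two points (mm)
#' @param a,b numeric length-3 points in mm.
#' @return non-negative scalar distance in mm.
#' @examples
#' pointDistance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
pointDistance <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("coordinates must be finite")
  vnorm(as.numeric(a) - as.numeric(b))
}

#' Interior angle at a vertex between two points (degrees)
#'
#' Computed as the arccosine of the normalized dot product, clamped to
#' \[-1, 1\] against rounding.
#'
#' @param a,b numeric length-3 points; must be distinct from `vertex`.
#' @param vertex numeric length-3 apex of the angle.
#' @return angle in degrees in \[0, 180\].
#' @examples
#' threePointAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
threePointAngle <- function(a, vertex, b) {
  u <- as.numeric(a) - as.numeric(vertex)
  v <- as.numeric(b) - as.numeric(vertex)
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-9 || nv < 1e-9)
    stop("angle undefined: point coincides with the vertex")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Angle between a line and the plane orthogonal to an axis (degrees)
#'
#' Returns the elevation of the line p->q out of the plane orthogonal to
#' `axis`, i.e. `asin(|d . axis| / |d|)`, folded into \[0, 90\]. Used for
#' pelvic tilt (axis = patient anterior-posterior direction, the vertical
#' of a supine subject) and the pelvic inlet angle (axis = superior axis,
#' plane = transverse).
#'
#' @param p,q numeric length-3 endpoints of the line (mm); must differ.
#' @param axis numeric length-3 unit vector.
#' @return angle in degrees in \[0, 90\].
#' @examples
#' lineAxisAngle(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))  # 0: in-plane line
#' @export
lineAxisAngle <- function(p, q, axis) {
  d <- as.numeric(q) - as.numeric(p)
  nd <- vnorm(d)
  if (nd < 1e-9) stop("zero-length line")
  axis <- as.numeric(axis)
  if (abs(vnorm(axis) - 1) > 1e-8) stop("'axis' must be a unit vector")
  asin(min(1, abs(sum(d * axis)) / nd)) * 180 / pi
}

#' Measurement configuration
#'
#' Choices the measurement definitions leave open: which conjugate defines
#' the pelvic-inlet midpoint (and hence pelvic depth and the inlet/depth
#' ratio), which side the oblique diameter is taken from, and the vertical
#' axis used by pelvic tilt. Defaults: obstetric conjugate; left
#' sacroiliac joint to right iliopubic eminence; patient
#' anterior-posterior axis (supine vertical) in LPS.
#'
#' @param inlet_conjugate "obstetric", "true" or "diagonal".
#' @param oblique_side "left" (SACROILIAC_L to ILIOPUB_EMINENCE_R),
#'   "right", or "mean" of both.
#' @param vertical_axis numeric length-3 unit vector in LPS; default
#'   `c(0, 1, 0)` (anterior-posterior).
#' @return list of class "MeasureConfig".
#' @export
measureConfig <- function(inlet_conjugate = c("obstetric", "true", "diagonal"),
                          oblique_side = c("left", "right", "mean"),
                          vertical_axis = c(0, 1, 0)) {
  inlet_conjugate <- match.arg(inlet_conjugate)
  oblique_side <- match.arg(oblique_side)
  vertical_axis <- as.numeric(vertical_axis)
  if (length(vertical_axis) != 3 || abs(vnorm(vertical_axis) - 1) > 1e-8)
    stop("'vertical_axis' must be a length-3 unit vector")
  structure(list(inlet_conjugate = inlet_conjugate,
                 oblique_side = oblique_side,
                 vertical_axis = vertical_axis),
            class = "MeasureConfig")
}

lmPoint <- function(coords, name) {
  if (!name %in% rownames(coords))
    stop("missing required landmark: ", name, call. = FALSE)
  coords[name, ]
}

#' Derived helper points used by the measurement suite
#'
#' @param landmarks a valid [LandmarkSet-class].
#' @param config a [measureConfig()].
#' @return list with `inlet_midpoint` (midpoint of the configured
#'   conjugate), `femoral_centre` (midpoint of the femoral head centres)
#'   and `sacral_platform` (`SACRAL_PLATFORM_CENTER`, defaulting to
#'   `SACRAL_PROMONTORY` when absent).
#' @export
derivedPoints <- function(landmarks, config = measureConfig()) {
  stopifnot(is(landmarks, "LandmarkSet"))
  co <- landmarks@coords
  ps_name <- switch(config$inlet_conjugate,
                    obstetric = "PS_SUP", true = "PS_MID", diagonal = "PS_INF")
  prom <- lmPoint(co, "SACRAL_PROMONTORY")
  inlet_mid <- (lmPoint(co, ps_name) + prom) / 2
  fem <- (lmPoint(co, "FEMORAL_HEAD_CENTER_L") +
          lmPoint(co, "FEMORAL_HEAD_CENTER_R")) / 2
  platform <- if ("SACRAL_PLATFORM_CENTER" %in% rownames(co))
    co["SACRAL_PLATFORM_CENTER", ] else prom
  list(inlet_midpoint = inlet_mid, femoral_centre = fem,
       sacral_platform = platform)
}

#' Compute the 21 pelvimetric measures for one subject
#'
#' Measure bindings (distances mm, angles degrees):
#' * obstetric/true/diagonal conjugate: superior/middle/inferior pubic
#'   symphysis point to the sacral promontory. Note this follows the source
#'   cohort's printed ordering (obstetric from the superior point), which
#'   differs from classical obstetric usage; only this ordering is
#'   consistent with obstetric > true in the published means.
#' * transverse diameter: widest inlet span between the iliopectineal
#'   lines; oblique diameter: sacroiliac joint to the contralateral
#'   iliopubic eminence (side per config).
#' * straight/median conjugate: inferior symphysis to the coccyx tip /
#'   lower sacrum; bis-ischiatic: between ischial tuberosities.
#' * pubic tubercle height: superior-inferior symphysis extent (a
#'   reconstruction; the term is not defined in the source).
#' * pelvic depth: configured inlet midpoint to the coccyx tip; the
#'   inlet/depth ratio uses the same configured conjugate (default
#'   obstetric).
#' * pelvic tilt: elevation of the sacral-platform to femoral-head-centre
#'   line out of the plane orthogonal to the vertical axis.
#' * offset alpha (reconstruction): angle at the promontory between the
#'   true-conjugate line and the promontory to S3/S4 sacral line.
#' * inlet beta (reconstruction): elevation of the obstetric-conjugate
#'   line out of the horizontal plane of the supine subject (the plane
#'   orthogonal to the configured vertical axis, i.e. the patient coronal
#'   plane by default). Sharing the vertical axis with pelvic tilt keeps
#'   both frame-dependent angles invariant under rotations about that
#'   axis.
#' * chi: angle at the promontory between the superior symphysis (inlet)
#'   and the coccyx; delta: angle at the coccyx between the promontory and
#'   the inferior symphysis (outlet); epsilon: angle at the S3/S4 disc
#'   between promontory and coccyx.
#'
#' @param landmarks a [LandmarkSet-class] passing schema validation.
#' @param config a [measureConfig()].
#' @return a [PelvimetryRecord-class] with the 21 registry measures.
#' @examples
#' rec <- computePelvimetry(buildTemplate()$landmarks)
#' measures(rec)["obstetric_conjugate"]
#' @export
computePelvimetry <- function(landmarks, config = measureConfig()) {
  stopifnot(is(landmarks, "LandmarkSet"))
  rep <- validateSchema(landmarks)
  ## completeness and uniqueness are hard requirements; orientation flags
  ## (e.g. side-swap relative to the frame) are not, because the measure
  ## suite must remain computable on rigidly re-oriented sets
  if (length(rep$missing) || length(rep$duplicates))
    stop(formatValidation(rep), call. = FALSE)
  if (any(!is.finite(landmarks@coords)))
    stop("landmark coordinates must be finite", call. = FALSE)
  m <- measuresFromCoords(landmarks@coords, config)
  new("PelvimetryRecord", subject = landmarks@subject, measures = m)
}

## Fast path shared with the template optimizer: no S4 construction, no
## schema validation (callers guarantee a complete coordinate matrix).
measuresFromCoords <- function(co, config = measureConfig()) {
  ps_name <- switch(config$inlet_conjugate,
                    obstetric = "PS_SUP", true = "PS_MID", diagonal = "PS_INF")
  prom0 <- lmPoint(co, "SACRAL_PROMONTORY")
  dp <- list(
    inlet_midpoint = (lmPoint(co, ps_name) + prom0) / 2,
    femoral_centre = (lmPoint(co, "FEMORAL_HEAD_CENTER_L") +
                      lmPoint(co, "FEMORAL_HEAD_CENTER_R")) / 2,
    sacral_platform = if ("SACRAL_PLATFORM_CENTER" %in% rownames(co))
      co["SACRAL_PLATFORM_CENTER", ] else prom0)
  P <- function(n) lmPoint(co, n)
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
  }

  prom <- P("SACRAL_PROMONTORY"); cocc <- P("COCCYX_TIP")
  s34 <- P("S3S4_DISC")
  oblique_l <- function() pointDistance(P("SACROILIAC_L"), P("ILIOPUB_EMINENCE_R"))
  oblique_r <- function() pointDistance(P("SACROILIAC_R"), P("ILIOPUB_EMINENCE_L"))

  m <- c(
    obstetric_conjugate = wrap("obstetric_conjugate",
      pointDistance(P("PS_SUP"), prom)),
    true_conjugate = wrap("true_conjugate",
      pointDistance(P("PS_MID"), prom)),
    diagonal_conjugate = wrap("diagonal_conjugate",
      pointDistance(P("PS_INF"), prom)),
    transverse_diameter = wrap("transverse_diameter",
      pointDistance(P("ILIOPECT_L"), P("ILIOPECT_R"))),
    oblique_diameter = wrap("oblique_diameter",
      switch(config$oblique_side, left = oblique_l(), right = oblique_r(),
             mean = (oblique_l() + oblique_r()) / 2)),
    straight_conjugate = wrap("straight_conjugate",
      pointDistance(P("PS_INF"), cocc)),
    median_conjugate = wrap("median_conjugate",
      pointDistance(P("PS_INF"), P("SACRUM_LOWER"))),
    bis_ischiatic_diameter = wrap("bis_ischiatic_diameter",
      pointDistance(P("ISCHIAL_TUBEROSITY_L"), P("ISCHIAL_TUBEROSITY_R"))),
    pubic_tubercle_height = wrap("pubic_tubercle_height",
      pointDistance(P("PS_SUP"), P("PS_INF"))),
    promontory_to_coccyx = wrap("promontory_to_coccyx",
      pointDistance(prom, cocc)),
    pelvic_depth = wrap("pelvic_depth",
      pointDistance(dp$inlet_midpoint, cocc)),
    promontory_to_S3S4 = wrap("promontory_to_S3S4",
      pointDistance(prom, s34)),
    S3S4_to_coccyx = wrap("S3S4_to_coccyx",
      pointDistance(s34, cocc)),
    ischial_spines_distance = wrap("ischial_spines_distance",
      pointDistance(P("ISCHIAL_SPINE_L"), P("ISCHIAL_SPINE_R"))),
    pelvic_tilt = wrap("pelvic_tilt",
      lineAxisAngle(dp$sacral_platform, dp$femoral_centre,
                    config$vertical_axis)),
    offset_alpha = wrap("offset_alpha",
      threePointAngle(P("PS_MID"), prom, s34)),
    inlet_beta = wrap("inlet_beta",
      lineAxisAngle(P("PS_SUP"), prom, config$vertical_axis)),
    angle_chi = wrap("angle_chi",
      threePointAngle(P("PS_SUP"), prom, cocc)),
    angle_delta = wrap("angle_delta",
      threePointAngle(prom, cocc, P("PS_INF"))),
    angle_epsilon = wrap("angle_epsilon",
      threePointAngle(prom, s34, cocc))
  )
  c(m, inlet_depth_ratio =
      unname(m[paste0(config$inlet_conjugate, "_conjugate")] /
             m["pelvic_depth"]))
}
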