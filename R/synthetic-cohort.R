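## Sex-dimorphic synthetic landmark cohorts.

#' Phantom generation parameters
#'
#' @param sex "female" or "male"; selects the default target table.
#' @param measure_targets target table (columns `measure`, `mean`, `sd`);
#'   defaults to the published per-sex means and SDs.
#' @param landmark_noise_scale dimensionless multiplier (>= 0) on the
#'   calibrated per-landmark noise; 1 reproduces the published SDs, 0
#'   yields exact template copies.
#' @param seed integer seed controlling every random draw downstream.
#' @return list of class "PhantomParams".
#' @export
phantomParams <- function(sex = c("female", "male"),
                          measure_targets = defaultMeasureTargets(sex),
                          landmark_noise_scale = 1, seed = 1L) {
  sex <- match.arg(sex)
  measure_targets <- force(measure_targets)
  if (!"sd" %in% names(measure_targets))
    stop("measure_targets needs an 'sd' column")
  targets <- normalizeTargets(measure_targets)
  if (any(targets$sd < 0)) stop("target SDs must be >= 0")
  stopifnot_scalar(landmark_noise_scale, "landmark_noise_scale")
  if (landmark_noise_scale < 0) stop("'landmark_noise_scale' must be >= 0")
  structure(list(sex = sex, measure_targets = targets,
                 landmark_noise_scale = landmark_noise_scale,
                 seed = as.integer(seed)),
            class = "PhantomParams")
}

## Distance-measure endpoint structure: which landmark "variance sites"
## (L/R pairs share one site) each distance loads on, with loading 1, or
## 0.25 for constituents of the inlet midpoint used by pelvic depth.
distanceNoiseDesign <- function() {
  sites <- c("PS_SUP", "PS_MID", "PS_INF", "SACRAL_PROMONTORY", "S3S4_DISC",
             "SACRUM_LOWER", "COCCYX_TIP", "ILIOPECT", "SACROILIAC",
             "ILIOPUB_EMINENCE", "ISCHIAL_SPINE", "ISCHIAL_TUBEROSITY",
             "SACRAL_PLATFORM_CENTER", "FEMORAL_HEAD_CENTER")
  rows <- list(
    obstetric_conjugate   = c(PS_SUP = 1, SACRAL_PROMONTORY = 1),
    true_conjugate        = c(PS_MID = 1, SACRAL_PROMONTORY = 1),
    diagonal_conjugate    = c(PS_INF = 1, SACRAL_PROMONTORY = 1),
    transverse_diameter   = c(ILIOPECT = 2),
    oblique_diameter      = c(SACROILIAC = 1, ILIOPUB_EMINENCE = 1),
    straight_conjugate    = c(PS_INF = 1, COCCYX_TIP = 1),
    median_conjugate      = c(PS_INF = 1, SACRUM_LOWER = 1),
    bis_ischiatic_diameter = c(ISCHIAL_TUBEROSITY = 2),
    pubic_tubercle_height = c(PS_SUP = 1, PS_INF = 1),
    promontory_to_coccyx  = c(SACRAL_PROMONTORY = 1, COCCYX_TIP = 1),
    pelvic_depth          = c(PS_SUP = 0.25, SACRAL_PROMONTORY = 0.25,
                              COCCYX_TIP = 1),
    promontory_to_S3S4    = c(SACRAL_PROMONTORY = 1, S3S4_DISC = 1),
    S3S4_to_coccyx        = c(S3S4_DISC = 1, COCCYX_TIP = 1),
    ischial_spines_distance = c(ISCHIAL_SPINE = 2))
  A <- matrix(0, length(rows), length(sites),
              dimnames = list(names(rows), sites))
  for (m in names(rows)) A[m, names(rows[[m]])] <- rows[[m]]
  A
}

## Solve per-site isotropic noise variances so that the variance induced
## along each distance (sum of endpoint variances, by isotropy) matches the
## target SD^2 in least squares, subject to non-negativity.
solveLandmarkNoise <- function(targets) {
  A <- distanceNoiseDesign()
  s2 <- targets$sd[match(rownames(A), targets$measure)]^2
  v <- pracma::lsqnonneg(A, s2)$x
  names(v) <- colnames(A)
  ## sites unconstrained by any distance get the median solved variance
  free <- colSums(A) == 0
  v[free] <- stats::median(v[!free & v > 0])
  v
}

siteOfLandmark <- function(names) sub("_[LR]$", "", names)

#' Sample a cohort of perturbed landmark sets
#'
#' Draws `n` subjects around the sex template: each landmark is displaced
#' by independent zero-mean isotropic Gaussian noise whose per-landmark
#' standard deviations are calibrated so that the realized SD of each
#' distance measure approximates its target SD (non-negative least squares
#' on the endpoint-variance equations, then one global per-sex factor from
#' a pilot Monte-Carlo run). The template itself is fitted to first-order
#' bias-corrected distance targets (`mean - sd^2/mean`) so that the
#' noise-induced positive bias of distances lands cohort means on the
#' targets. Fully reproducible given `params$seed`.
#'
#' @param params a [phantomParams()].
#' @param n cohort size (>= 1).
#' @param config a [measureConfig()].
#' @return list of `n` [LandmarkSet-class] objects; attributes `sex`
#'   (label, recycled per subject) and `template` (the fitted template).
#' @examples
#' cohort <- sampleLandmarkCohort(phantomParams("female", seed = 7), n = 3)
#' length(cohort)
#' @export
sampleLandmarkCohort <- function(params, n, config = measureConfig()) {
  stopifnot(inherits(params, "PhantomParams"), n >= 1)
  n <- as.integer(n)
  targets <- params$measure_targets
  scale <- params$landmark_noise_scale

  ## first-order bias correction of distance targets
  adj <- targets
  isd <- adj$type == "distance"
  adj$mean[isd] <- adj$mean[isd] - (scale * adj$sd[isd])^2 / adj$mean[isd]
  fit <- buildTemplate(adj, seed = params$seed, config = config)
  tco <- fit$landmarks@coords
  site_sd <- sqrt(solveLandmarkNoise(targets))[siteOfLandmark(rownames(tco))]

  if (scale == 0) {
    out <- lapply(seq_len(n), function(i)
      landmarkSet(tco, subject = sprintf("%s_%03d", params$sex, i)))
    attr(out, "sex") <- rep(params$sex, n)
    attr(out, "template") <- fit$landmarks
    return(out)
  }

  drawOne <- function(sd_vec, subject, validate = TRUE) {
    for (try in 1:10) {
      noise <- matrix(stats::rnorm(length(tco), 0, sd_vec), ncol = 3)
      co <- tco + noise
      if (min(stats::dist(co)) < 1) next   # coincident landmarks: resample
      s <- tryCatch(landmarkSet(co, subject = subject, validate = validate),
                    error = function(e) NULL)
      if (!is.null(s)) return(s)
    }
    stop("degenerate configuration persisted after 10 resamples")
  }

  withSeed(params$seed, {
    ## pilot run: one global factor aligning realized distance SDs with
    ## the targets (median ratio across the 14 distances)
    pilot <- vapply(seq_len(200), function(i) {
      s <- drawOne(scale * site_sd, "pilot", validate = FALSE)
      measuresFromCoords(s@coords, config)[targets$measure[isd]]
    }, numeric(sum(isd)))
    g <- stats::median(targets$sd[isd] / apply(pilot, 1, stats::sd))
    sd_final <- scale * g * site_sd
    out <- lapply(seq_len(n), function(i)
      drawOne(sd_final, sprintf("%s_%03d", params$sex, i)))
  })
  attr(out, "sex") <- rep(params$sex, n)
  attr(out, "template") <- fit$landmarks
  out
}
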