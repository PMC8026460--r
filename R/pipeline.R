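#' Phantom-to-smoothed-mesh pipeline with volume audit
#'
#' End-to-end convenience chain: fit the sex template, rasterize the bone
#' phantom, segment it by seeded level tracing (one suggested seed per
#' bone component per axial slice, tolerance at half the bone/background
#' contrast), extract the 0.5 iso-surface, smooth it with the default
#' umbrella filter, and audit the enclosed-volume change against the
#' budget.
#'
#' @param sex "female" or "male" template.
#' @param spacing voxel spacing in mm (isotropic scalar or length 3).
#' @param seed integer seed (template restarts and phantom noise).
#' @param noise_sd intensity noise SD of the phantom (0 = noiseless).
#' @param smoothing a [smoothingParams()].
#' @param budget_percent volume-change budget in percent (default 1).
#' @return list with `landmarks`, `volume`, `mask`, `mesh`, `smoothed`,
#'   and `audit` (see [checkVolumeBudget()]).
#' @examples
#' \donttest{
#' res <- phantomSmoothingAudit(spacing = 4)
#' res$audit$realized_percent
#' }
#' @export
phantomSmoothingAudit <- function(sex = c("female", "male"), spacing = 2,
                                  seed = 1L, noise_sd = 0,
                                  smoothing = smoothingParams(),
                                  budget_percent = 1.0) {
  sex <- match.arg(sex)
  fit <- buildTemplate(defaultMeasureTargets(sex), seed = seed)
  vol <- rasterizePhantom(fit$landmarks, spacing = spacing,
                          noise_sd = noise_sd, seed = seed)
  rng <- range(vol@intensities)
  thr <- mean(rng)
  seeds <- suggestBoneSeeds(vol, thr)
  mask <- segmentVolume(vol, seeds, tolerance = diff(rng) / 2)
  mesh <- extractSurface(mask)
  smoothed <- laplacianSmooth(mesh, smoothing)
  audit <- checkVolumeBudget(mesh, smoothed, budget_percent)
  list(landmarks = fit$landmarks, volume = vol, mask = mask, mesh = mesh,
       smoothed = smoothed, audit = audit)
}
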