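## Rasterized bone-like voxel phantoms.
##
## The bony pelvis is emulated as a union of capsules (tubes with
## hemispherical caps) sweeping along the anatomical ring structures of
## the landmark schema, plus spheres at every landmark (larger at the
## femoral heads). The phantom reproduces the property the slice-wise
## segmentation exploits: bone at high intensity against a low-intensity
## background.

## Segment chains traced with capsules. Each row: from, to.
phantomChains <- function() {
  rbind(
    ## pelvic inlet ring
    c("PS_SUP", "ILIOPECT_L"), c("ILIOPECT_L", "SACROILIAC_L"),
    c("SACROILIAC_L", "SACRAL_PROMONTORY"),
    c("SACRAL_PROMONTORY", "SACROILIAC_R"),
    c("SACROILIAC_R", "ILIOPECT_R"), c("ILIOPECT_R", "PS_SUP"),
    ## pubic symphysis
    c("PS_SUP", "PS_MID"), c("PS_MID", "PS_INF"),
    ## sacrum and coccyx
    c("SACRAL_PLATFORM_CENTER", "SACRAL_PROMONTORY"),
    c("SACRAL_PROMONTORY", "S3S4_DISC"), c("S3S4_DISC", "SACRUM_LOWER"),
    c("SACRUM_LOWER", "COCCYX_TIP"),
    ## superior pubic rami via the iliopubic eminences
    c("ILIOPECT_L", "ILIOPUB_EMINENCE_L"), c("ILIOPUB_EMINENCE_L", "PS_SUP"),
    c("ILIOPECT_R", "ILIOPUB_EMINENCE_R"), c("ILIOPUB_EMINENCE_R", "PS_SUP"),
    ## posterior columns: sacroiliac joint -> spine -> tuberosity -> ramus
    c("SACROILIAC_L", "ISCHIAL_SPINE_L"),
    c("ISCHIAL_SPINE_L", "ISCHIAL_TUBEROSITY_L"),
    c("ISCHIAL_TUBEROSITY_L", "PS_INF"),
    c("SACROILIAC_R", "ISCHIAL_SPINE_R"),
    c("ISCHIAL_SPINE_R", "ISCHIAL_TUBEROSITY_R"),
    c("ISCHIAL_TUBEROSITY_R", "PS_INF"),
    ## acetabular attachment of the femoral heads
    c("ILIOPUB_EMINENCE_L", "FEMORAL_HEAD_CENTER_L"),
    c("ILIOPUB_EMINENCE_R", "FEMORAL_HEAD_CENTER_R"))
}

## Geometric primitives of the phantom solid.
phantomPrimitives <- function(landmarks, bone_radius = 8,
                              femoral_radius = 22) {
  co <- landmarks@coords
  if (!"SACRAL_PLATFORM_CENTER" %in% rownames(co))
    co <- rbind(co, SACRAL_PLATFORM_CENTER = co["SACRAL_PROMONTORY", ])
  ch <- phantomChains()
  segs <- lapply(seq_len(nrow(ch)), function(i)
    list(a = co[ch[i, 1], ], b = co[ch[i, 2], ], r = bone_radius))
  sph <- lapply(rownames(co), function(nm)
    list(c = co[nm, ],
         r = if (grepl("^FEMORAL_HEAD_CENTER", nm)) femoral_radius
             else bone_radius))
  list(segments = segs, spheres = sph,
       bone_radius = bone_radius, femoral_radius = femoral_radius)
}

## Membership of arbitrary points (n x 3) in the phantom solid.
pointsInSolid <- function(pts, prims) {
  inside <- rep(FALSE, nrow(pts))
  for (s in prims$segments) {
    d <- s$b - s$a
    dd <- sum(d * d)
    px <- pts[, 1] - s$a[1]; py <- pts[, 2] - s$a[2]; pz <- pts[, 3] - s$a[3]
    t <- if (dd > 0) pmin(1, pmax(0, (px * d[1] + py * d[2] + pz * d[3]) / dd)) else 0
    dx <- px - t * d[1]; dy <- py - t * d[2]; dz <- pz - t * d[3]
    inside <- inside | (dx * dx + dy * dy + dz * dz <= s$r^2)
  }
  for (s in prims$spheres) {
    dx <- pts[, 1] - s$c[1]; dy <- pts[, 2] - s$c[2]; dz <- pts[, 3] - s$c[3]
    inside <- inside | (dx * dx + dy * dy + dz * dz <= s$r^2)
  }
  inside
}

#' Rasterize a landmark set into a bone-like voxel phantom
#'
#' @param landmarks a valid [LandmarkSet-class].
#' @param spacing voxel spacing in mm (scalar for isotropic, or length 3).
#' @param bone_intensity,background_intensity intensities of the bone
#'   solid and of everything else; bone must exceed background (the
#'   contrast the seeded segmentation exploits).
#' @param noise_sd SD of additive Gaussian intensity noise (0 = noiseless).
#' @param seed integer seed for the noise.
#' @param bone_radius capsule/sphere radius of the bony wireframe (mm).
#' @param femoral_radius sphere radius at the femoral head centres (mm).
#' @param margin_voxels background margin beyond the landmark bounding box
#'   and solid extent (>= 10).
#' @return a [VoxelVolume-class]; axial slices are the third index.
#' @examples
#' lm <- buildTemplate()$landmarks
#' vol <- rasterizePhantom(lm, spacing = 4)
#' @export
rasterizePhantom <- function(landmarks, spacing = 2, bone_intensity = 1000,
                             background_intensity = 0, noise_sd = 0,
                             seed = 1L, bone_radius = 8, femoral_radius = 22,
                             margin_voxels = 10L) {
  stopifnot(is(landmarks, "LandmarkSet"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 1 or 3 positive values (mm)")
  if (bone_intensity <= background_intensity)
    stop("'bone_intensity' must exceed 'background_intensity'")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (margin_voxels < 10L) stop("'margin_voxels' must be >= 10")
  if (2 * bone_radius < 2 * max(spacing))
    stop(sprintf(paste0("spacing too coarse: the %.1f mm bone shell would be ",
                        "thinner than 2 voxels at %.1f mm spacing; ",
                        "use finer spacing"), 2 * bone_radius, max(spacing)))

  prims <- phantomPrimitives(landmarks, bone_radius, femoral_radius)
  co <- landmarks@coords
  pad <- max(bone_radius, femoral_radius) + margin_voxels * spacing
  lo <- apply(co, 2, min) - pad
  hi <- apply(co, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)

  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing[3]
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  solid <- pointsInSolid(pts, prims)
  vox <- array(ifelse(solid, bone_intensity, background_intensity), dim = dims)
  if (noise_sd > 0)
    vox <- vox + withSeed(seed, array(stats::rnorm(length(vox), 0, noise_sd),
                                      dim = dims))
  new("VoxelVolume", intensities = vox, spacing = as.numeric(spacing),
      origin = as.numeric(lo), frame = "LPS")
}

#' Monte-Carlo volume of the phantom generating solid
#'
#' Estimates the volume (mm^3) of the exact capsule/sphere union that
#' [rasterizePhantom()] samples, by uniform rejection sampling in its
#' bounding box. Independent of any voxel grid; serves as the reference
#' for rasterization accuracy.
#'
#' @param landmarks a valid [LandmarkSet-class].
#' @param bone_radius,femoral_radius as in [rasterizePhantom()].
#' @param n number of sample points.
#' @param seed integer seed.
#' @return volume estimate in mm^3 (attribute `se`: its standard error).
#' @export
phantomSolidVolume <- function(landmarks, bone_radius = 8,
                               femoral_radius = 22, n = 2e5, seed = 1L) {
  prims <- phantomPrimitives(landmarks, bone_radius, femoral_radius)
  co <- landmarks@coords
  pad <- max(bone_radius, femoral_radius)
  lo <- apply(co, 2, min) - pad
  hi <- apply(co, 2, max) + pad
  vbox <- prod(hi - lo)
  withSeed(seed, {
    pts <- cbind(stats::runif(n, lo[1], hi[1]),
                 stats::runif(n, lo[2], hi[2]),
                 stats::runif(n, lo[3], hi[3]))
    p <- mean(pointsInSolid(pts, prims))
  })
  structure(p * vbox, se = vbox * sqrt(p * (1 - p) / n))
}
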