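#' The 21-measure pelvimetry registry
#'
#' Fixed, ordered registry of the scalar measures computed per subject:
#' five pelvic-inlet measures (obstetric/true/diagonal conjugates,
#' transverse and oblique diameters), three outlet measures (straight and
#' median conjugates, bis-ischiatic diameter), six other distances
#' (pubic tubercle height, promontory-coccyx, pelvic depth,
#' promontory-S3/S4, S3/S4-coccyx, inter-spinous distance), six angles
#' (pelvic tilt, offset alpha, inlet beta, chi, delta, epsilon) and the
#' pelvic inlet to pelvic depth ratio. Every cohort-level routine iterates
#' this registry in this order.
#'
#' @return data.frame with columns `measure`, `type`
#'   (distance/angle/ratio), `units` (mm/deg/1) and `group`
#'   (inlet/outlet/other/angle/ratio); 21 rows.
#' @examples
#' measureRegistry()
#' @export
measureRegistry <- function() {
  data.frame(
    measure = c("obstetric_conjugate", "true_conjugate", "diagonal_conjugate",
                "transverse_diameter", "oblique_diameter",
                "straight_conjugate", "median_conjugate",
                "bis_ischiatic_diameter",
                "pubic_tubercle_height", "promontory_to_coccyx",
                "pelvic_depth", "promontory_to_S3S4", "S3S4_to_coccyx",
                "ischial_spines_distance",
                "pelvic_tilt", "offset_alpha", "inlet_beta",
                "angle_chi", "angle_delta", "angle_epsilon",
                "inlet_depth_ratio"),
    type = c(rep("distance", 14), rep("angle", 6), "ratio"),
    units = c(rep("mm", 14), rep("deg", 6), "1"),
    group = c(rep("inlet", 5), rep("outlet", 3), rep("other", 6),
              rep("angle", 6), "ratio"),
    stringsAsFactors = FALSE
  )
}

#' Published sex-stratified calibration targets for the 21 measures
#'
#' Per-sex mean and SD of every registry measure in a reference CT cohort
#' of 100 female and 100 male adults, used as the default calibration
#' targets of the synthetic-phantom generator and as printed-input material
#' for the summary-statistics t-test. Distances in mm, angles in degrees,
#' the ratio dimensionless.
#'
#' @param sex "female" or "male"; if omitted, the full two-sex table.
#' @return If `sex` is given, a data.frame with columns `measure`, `type`,
#'   `mean`, `sd` (21 rows); otherwise the full table with per-sex columns.
#' @examples
#' defaultMeasureTargets("female")
#' @export
defaultMeasureTargets <- function(sex = c("both", "female", "male")) {
  sex <- match.arg(sex)
  reg <- measureRegistry()
  tab <- data.frame(
    reg[, c("measure", "type")],
    female_mean = c(126.2, 122.1, 131.8, 133.8, 130.0,
                    99.9, 112.3, 118.0,
                    30.7, 119.0, 102.8, 77.2, 63.4, 116.7,
                    64.7, 32.1, 47.1, 59.0, 72.7, 116.4,
                    1.2),
    female_sd   = c(8.6, 8.8, 8.8, 7.7, 7.2,
                    10.6, 9.9, 10.1,
                    3.7, 12.3, 9.8, 6.7, 7.7, 9.3,
                    7.7, 3.5, 8.2, 7.1, 8.9, 11.8,
                    0.1),
    male_mean   = c(119.4, 114.0, 127.9, 128.2, 125.7,
                    97.4, 109.7, 102.2,
                    34.8, 128.7, 111.5, 80.6, 69.6, 100.5,
                    61.0, 27.5, 52.9, 60.1, 67.6, 118.5,
                    1.1),
    male_sd     = c(9.9, 10.0, 10.3, 8.0, 6.3,
                    8.4, 8.4, 10.4,
                    4.0, 11.8, 8.8, 7.8, 8.6, 8.6,
                    9.0, 3.2, 8.1, 5.9, 6.9, 10.0,
                    0.1),
    stringsAsFactors = FALSE
  )
  if (sex == "both") return(tab)
  out <- data.frame(measure = tab$measure, type = tab$type,
                    mean = tab[[paste0(sex, "_mean")]],
                    sd = tab[[paste0(sex, "_sd")]],
                    stringsAsFactors = FALSE)
  out
}
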