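#' The fiducial landmark schema
#'
#' Nineteen named bony landmarks are sufficient to reconstruct all 21
#' registry measures: three points on the pubic symphysis (superior,
#' middle, inferior), five midline sacro-coccygeal points, and five
#' left/right pairs plus the femoral head centres. `SACRAL_PLATFORM_CENTER`
#' is optional: when absent it defaults to `SACRAL_PROMONTORY`, in which
#' case 18 distinct markers suffice.
#'
#' @return data.frame with columns `name`, `required` (logical), `side`
#'   ("L", "R" or "M" for midline) and `pair` (name of the contralateral
#'   landmark, or NA).
#' @examples
#' landmarkSchema()
#' @export
landmarkSchema <- function() {
  nm <- c("PS_SUP", "PS_MID", "PS_INF",
          "SACRAL_PROMONTORY", "SACRAL_PLATFORM_CENTER",
          "S3S4_DISC", "SACRUM_LOWER", "COCCYX_TIP",
          "ILIOPECT_L", "ILIOPECT_R",
          "SACROILIAC_L", "SACROILIAC_R",
          "ILIOPUB_EMINENCE_L", "ILIOPUB_EMINENCE_R",
          "ISCHIAL_SPINE_L", "ISCHIAL_SPINE_R",
          "ISCHIAL_TUBEROSITY_L", "ISCHIAL_TUBEROSITY_R",
          "FEMORAL_HEAD_CENTER_L", "FEMORAL_HEAD_CENTER_R")
  side <- ifelse(grepl("_L$", nm), "L", ifelse(grepl("_R$", nm), "R", "M"))
  pair <- rep(NA_character_, length(nm))
  pair[side == "L"] <- sub("_L$", "_R", nm[side == "L"])
  pair[side == "R"] <- sub("_R$", "_L", nm[side == "R"])
  data.frame(name = nm,
             required = nm != "SACRAL_PLATFORM_CENTER",
             side = side, pair = pair, stringsAsFactors = FALSE)
}

#' Construct a LandmarkSet from a named coordinate matrix
#'
#' @param coords numeric matrix with one named row per landmark and columns
#'   (x, y, z) in mm; names must be schema names (see [landmarkSchema()]).
#' @param subject subject identifier.
#' @param frame coordinate frame label; only "LPS" is accepted.
#' @param validate if TRUE (default), fail unless [validateSchema()] passes.
#' @return a [LandmarkSet-class] object.
#' @examples
#' lm <- buildTemplate()$landmarks
#' landmarkSet(landmarkCoords(lm), subject = "copy")
#' @export
landmarkSet <- function(coords, subject = "unknown", frame = "LPS",
                        validate = TRUE) {
  if (!identical(frame, "LPS"))
    stop("internal landmark frame must be 'LPS'")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  obj <- new("LandmarkSet", subject = as.character(subject), frame = frame,
             coords = coords)
  if (validate) {
    rep <- validateSchema(obj)
    if (!rep$pass)
      stop(formatValidation(rep), call. = FALSE)
  }
  obj
}

#' Validate a LandmarkSet against the schema
#'
#' Checks that every required landmark is present exactly once, that no
#' left/right pair is degenerate (closer than 1 mm) and that sides are not
#' swapped relative to the LPS frame (a pair with the `_L` member at a
#' smaller left-coordinate than its `_R` partner is flagged). Absence of
#' the derivable `SACRAL_PLATFORM_CENTER` is a warning, not a failure.
#'
#' @param set a [LandmarkSet-class].
#' @return list with elements `missing`, `duplicates`, `flags` (character
#'   vectors), `warnings` and logical `pass` (TRUE iff the first three are
#'   empty).
#' @examples
#' validateSchema(buildTemplate()$landmarks)$pass
#' @export
validateSchema <- function(set) {
  stopifnot(is(set, "LandmarkSet"))
  schema <- landmarkSchema()
  nm <- rownames(set@coords)
  missing <- setdiff(schema$name[schema$required], nm)
  warnings <- character()
  if (!"SACRAL_PLATFORM_CENTER" %in% nm)
    warnings <- "SACRAL_PLATFORM_CENTER absent; defaulting to SACRAL_PROMONTORY"
  duplicates <- unique(nm[duplicated(nm)])
  flags <- character()
  unknown <- setdiff(nm, schema$name)
  if (length(unknown))
    flags <- c(flags, paste0("unknown landmark: ", unknown))
  if (any(!is.finite(set@coords)))
    flags <- c(flags, "non-finite coordinates")
  lefts <- schema$name[schema$side == "L"]
  for (l in lefts) {
    r <- sub("_L$", "_R", l)
    if (l %in% nm && r %in% nm && !(l %in% duplicates) && !(r %in% duplicates)) {
      pl <- set@coords[l, ]; pr <- set@coords[r, ]
      if (vnorm(pl - pr) < 1)
        flags <- c(flags, sprintf("pair %s/%s closer than 1 mm", l, r))
      if (pl[1] < pr[1])
        flags <- c(flags, sprintf("sides swapped: %s left of %s in LPS", r, l))
    }
  }
  list(missing = missing, duplicates = duplicates, flags = flags,
       warnings = warnings,
       pass = !length(missing) && !length(duplicates) && !length(flags))
}

formatValidation <- function(rep) {
  parts <- c(
    if (length(rep$missing)) paste0("missing: ", paste(rep$missing, collapse = ", ")),
    if (length(rep$duplicates)) paste0("duplicated: ", paste(rep$duplicates, collapse = ", ")),
    if (length(rep$flags)) paste0("flags: ", paste(rep$flags, collapse = "; ")))
  paste0("landmark set fails schema validation (",
         paste(parts, collapse = "; "), ")")
}
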