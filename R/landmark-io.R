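#' Read a landmark file
#'
#' Two dialects are supported: `slicer_fcsv`, the 3D Slicer Markups
#' fiducial CSV (`# Markups fiducial file ...` header, coordinates in RAS),
#' and `plain_csv`, a `name,x,y,z,frame` table in LPS millimetres. Slicer
#' RAS coordinates are converted to the internal LPS frame by negating the
#' first two coordinates. Landmark names may be mapped to schema names via
#' an alias table.
#'
#' @param path file to read.
#' @param dialect "slicer_fcsv" or "plain_csv".
#' @param aliases named character vector mapping file names to schema names
#'   (e.g. `c("promontory" = "SACRAL_PROMONTORY")`).
#' @param subject subject id; defaults to the file name without extension.
#' @param validate passed to [landmarkSet()].
#' @return a [LandmarkSet-class] in the LPS frame.
#' @seealso [writeLandmarks()]
#' @export
readLandmarks <- function(path, dialect = c("slicer_fcsv", "plain_csv"),
                          aliases = character(), subject = NULL,
                          validate = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject)) subject <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "slicer_fcsv") {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (!length(body)) stop("no fiducial rows in ", path)
    tab <- tryCatch(
      utils::read.csv(text = body, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("malformed fcsv: ", conditionMessage(e)))
    if (ncol(tab) < 12)
      stop("malformed fcsv row(s): expected >= 12 columns, got ", ncol(tab))
    xyz <- suppressWarnings(
      matrix(as.numeric(as.matrix(tab[, 2:4])), ncol = 3))
    if (any(!is.finite(xyz))) {
      bad <- which(rowSums(!is.finite(xyz)) > 0)[1L]
      stop("malformed coordinate in fcsv data row ", bad)
    }
    ras_lps <- any(grepl("CoordinateSystem\\s*=\\s*(RAS|0)", lines))
    lps_declared <- any(grepl("CoordinateSystem\\s*=\\s*(LPS|1)", lines))
    if (ras_lps || !lps_declared) {          # Slicer default is RAS
      xyz[, 1] <- -xyz[, 1]
      xyz[, 2] <- -xyz[, 2]
    }
    nm <- as.character(tab[[12]])
  } else {
    tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) stop("malformed csv: ", conditionMessage(e)))
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("plain_csv needs columns name,x,y,z[,frame]")
    if ("frame" %in% names(tab) && any(tab$frame != "LPS"))
      stop("plain_csv frame column must be 'LPS'")
    xyz <- suppressWarnings(
      matrix(as.numeric(as.matrix(tab[, c("x", "y", "z")])), ncol = 3))
    bad <- which(rowSums(!is.finite(xyz)) > 0)
    if (length(bad))
      stop("malformed coordinate in csv line ", bad[1L] + 1L)
    nm <- as.character(tab$name)
  }
  mapped <- ifelse(nm %in% names(aliases), unname(aliases[nm]), nm)
  schema <- landmarkSchema()
  unknown <- setdiff(mapped, schema$name)
  if (length(unknown))
    stop("unknown landmark name(s) with no alias: ",
         paste(unknown, collapse = ", "))
  rownames(xyz) <- mapped
  landmarkSet(xyz, subject = subject, validate = validate)
}

#' Write a landmark file
#'
#' Writes in either supported dialect (see [readLandmarks()]); coordinates
#' round-trip to at least 1e-6 mm. The set must pass schema validation.
#'
#' @param set a [LandmarkSet-class].
#' @param path output file.
#' @param dialect "slicer_fcsv" (written in RAS, the Slicer default) or
#'   "plain_csv" (LPS).
#' @return invisibly, `path`.
#' @export
writeLandmarks <- function(set, path, dialect = c("slicer_fcsv", "plain_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(set, "LandmarkSet"))
  rep <- validateSchema(set)
  if (!rep$pass) stop(formatValidation(rep), call. = FALSE)
  co <- set@coords
  if (dialect == "slicer_fcsv") {
    hdr <- c("# Markups fiducial file version = 4.11",
             "# CoordinateSystem = RAS",
             "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
    rows <- sprintf("vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,%s,,",
                    seq_len(nrow(co)) - 1L,
                    formatC(-co[, 1], format = "f", digits = 8),
                    formatC(-co[, 2], format = "f", digits = 8),
                    formatC(co[, 3], format = "f", digits = 8),
                    rownames(co))
    writeLines(c(hdr, rows), path)
  } else {
    rows <- sprintf("%s,%s,%s,%s,LPS", rownames(co),
                    formatC(co[, 1], format = "f", digits = 8),
                    formatC(co[, 2], format = "f", digits = 8),
                    formatC(co[, 3], format = "f", digits = 8))
    writeLines(c("name,x,y,z,frame", rows), path)
  }
  invisible(path)
}
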