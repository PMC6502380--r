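#' Landmark configuration for one specimen
#'
#' Holds the six head landmarks used for Procrustes alignment, in fixed
#' conventional order: (1) apex of the upper jaw, (2) most dorsal point of
#' the gill plate, (3) most ventral point of the gill plate, (4) most
#' posterior point of the gill plate, (5) maxillary bone, (6) eye.
#' Optionally carries four additional kype-measurement points that are
#' excluded from alignment (mouth opening perturbs them): (k1) most anterior
#' point of the lower jaw, (k2) bottom of the gill plate, (k3) dorsal peak of
#' the kype hook, (k4) ventral point on the lower jaw where curvature begins
#' (may be `NA` when no curvature point exists or the mouth was closed).
#'
#' @param specimen_id character scalar
#' @param landmarks 6 x 2 numeric matrix of (x, y) coordinates in cm
#' @param kype_points optional 4 x 2 numeric matrix (cm); rows 3-4 may be NA
#' @param scale optional cm-per-pixel factor already applied to coordinates
#' @param sex optional `"male"` or `"female"`
#' @param sea_winters optional integer 1..3
#' @return an object of class `landmark_config`
#' @export
landmark_config <- function(specimen_id, landmarks, kype_points = NULL,
                            scale = NULL, sex = NA_character_,
                            sea_winters = NA_integer_) {
  landmarks <- as.matrix(landmarks)
  if (!is.numeric(landmarks) || nrow(landmarks) != 6L || ncol(landmarks) != 2L)
    stop_ctx("specimen '%s': expected a 6 x 2 landmark matrix", specimen_id)
  if (!all(is.finite(landmarks)))
    stop_ctx("specimen '%s': non-finite landmark coordinates", specimen_id)
  if (!is.null(kype_points)) {
    kype_points <- as.matrix(kype_points)
    if (nrow(kype_points) != 4L || ncol(kype_points) != 2L)
      stop_ctx("specimen '%s': kype_points must be 4 x 2", specimen_id)
    if (!all(is.finite(kype_points[1:2, ])))
      stop_ctx("specimen '%s': kype length endpoints must be finite",
               specimen_id)
  }
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
        scale <= 0)
      stop_ctx("specimen '%s': scale must be a positive number", specimen_id)
  }
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop_ctx("specimen '%s': sex must be 'male' or 'female'", specimen_id)
  structure(list(specimen_id = as.character(specimen_id),
                 landmarks = unname(landmarks),
                 kype_points = if (is.null(kype_points)) NULL else
                   unname(kype_points),
                 scale = scale, sex = sex,
                 sea_winters = as.integer(sea_winters)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: 6 landmarks%s%s\n", x$specimen_id,
              if (is.null(x$kype_points)) "" else " + 4 kype points",
              if (is.null(x$scale)) "" else sprintf(", scale=%g", x$scale)))
  invisible(x)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig dialect: records start with `LM=<n>`, followed by `n`
#' whitespace-separated coordinate lines, then optional `SCALE=`, `ID=` and
#' `IMAGE=` keys. Coordinates are multiplied by `SCALE` when present, so the
#' returned coordinates are in cm. Records with `LM=6` carry the six
#' alignment landmarks only; `LM=10` additionally carries the four
#' kype-measurement points (rows 7-10). Any other landmark count is an
#' error, as is a mismatch between `LM=` and the number of coordinate lines.
#' Unknown `KEY=value` lines are ignored with a warning.
#'
#' @param path path to a TPS file
#' @return a list of [landmark_config] objects, in file order
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop_ctx("TPS file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop_ctx("record %d: expected 'LM=' at line '%s'", rec + 1L, lines[i])
    rec <- rec + 1L
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                            ignore.case = TRUE)))
    if (is.na(n_lm)) stop_ctx("record %d: unparseable LM= value", rec)
    if (!n_lm %in% c(6L, 10L))
      stop_ctx("record %d: LM=%d but 6 (landmarks) or 10 (landmarks + kype points) expected",
               rec, n_lm)
    i <- i + 1L
    coords <- matrix(NA_real_, n_lm, 2L)
    for (k in seq_len(n_lm)) {
      if (i > length(lines) || grepl("=", lines[i], fixed = TRUE))
        stop_ctx("record %d: LM=%d but only %d coordinate line(s) found",
                 rec, n_lm, k - 1L)
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop_ctx("record %d: malformed coordinate line '%s'", rec, lines[i])
      coords[k, ] <- xy
      i <- i + 1L
    }
    id <- sprintf("specimen_%d", rec)
    scale <- NULL
    while (i <= length(lines) && grepl("=", lines[i], fixed = TRUE) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[^=]*=\\s*", "", lines[i])
      if (key == "SCALE") {
        scale <- as.numeric(val)
        if (!is.finite(scale) || scale <= 0)
          stop_ctx("record %d: invalid SCALE= value '%s'", rec, val)
      } else if (key == "ID") {
        id <- val
      } else if (key == "IMAGE") {
        # ignored: image path is digitizer bookkeeping
      } else {
        warning(sprintf("record %d: ignoring unknown TPS key '%s'", rec, key),
                call. = FALSE)
      }
      i <- i + 1L
    }
    if (!is.null(scale)) coords <- coords * scale
    configs[[rec]] <- landmark_config(
      specimen_id = id,
      landmarks = coords[1:6, , drop = FALSE],
      kype_points = if (n_lm == 10L) coords[7:10, , drop = FALSE] else NULL,
      scale = scale)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps]: coordinates are written in digitizer units
#' (cm / scale) at six decimal places together with a `SCALE=` line, so a
#' read/write round trip reproduces the cm coordinates to that precision.
#'
#' @param configs non-empty list of [landmark_config] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) stop_ctx("write_tps: empty configuration list")
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    stopifnot(inherits(cfg, "landmark_config"))
    coords <- cfg$landmarks
    if (!is.null(cfg$kype_points)) coords <- rbind(coords, cfg$kype_points)
    if (!all(is.finite(coords)))
      stop_ctx("write_tps: specimen '%s' has non-finite points; TPS cannot encode missing coordinates",
               cfg$specimen_id)
    sc <- cfg$scale %||% 1
    writeLines(sprintf("LM=%d", nrow(coords)), con)
    writeLines(sprintf("%.6f %.6f", coords[, 1] / sc, coords[, 2] / sc), con)
    writeLines(sprintf("ID=%s", cfg$specimen_id), con)
    writeLines(sprintf("SCALE=%.10g", sc), con)
  }
  invisible(path)
}
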