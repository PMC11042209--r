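#' Write a camera calibration file
#'
#' Serializes a set of camera models to a TOML file with one table per view:
#'
#' ```
#' [views.front]
#' mirrored = false
#' image_size = [1440, 1080]
#' P = [p11, p12, ..., p34]   # 12 entries, row-major, pixels <- mm
#' ```
#'
#' Matrices are written with 17 significant digits so that a write/read
#' roundtrip reproduces the projection matrices to machine precision (equal
#' up to the overall projective scale).
#'
#' @param cams named list of [camera_model()]s; names are the view ids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cams, path) {
  stopifnot(is.list(cams), !is.null(names(cams)), all(nzchar(names(cams))))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- character(0)
  for (v in names(cams)) {
    cam <- cams[[v]]
    lines <- c(lines,
      sprintf("[views.%s]", v),
      sprintf("mirrored = %s", if (cam$mirrored) "true" else "false"),
      sprintf("image_size = [%s]",
              paste(fmt(cam$image_size), collapse = ", ")),
      sprintf("P = [%s]", paste(fmt(t(cam$P)), collapse = ", ")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a camera calibration file
#'
#' Parses the restricted TOML dialect written by [write_calibration()]. Parse
#' failures report the offending line number; a view requested via `views`
#' but absent from the file raises an error naming it.
#'
#' @param path calibration file path.
#' @param views optional character vector of view ids that must be present.
#' @return Named list of [camera_model()]s.
#' @export
read_calibration <- function(path, views = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  cams <- list()
  cur <- NULL
  fields <- list()
  flush <- function(cams, cur, fields) {
    if (is.null(cur)) return(cams)
    for (k in c("mirrored", "image_size", "P")) {
      if (is.null(fields[[k]])) {
        stop(sprintf("view '%s' is missing key '%s'", cur, k), call. = FALSE)
      }
    }
    if (length(fields$P) != 12L) {
      stop(sprintf("view '%s': P must have 12 entries, got %d",
                   cur, length(fields$P)), call. = FALSE)
    }
    cams[[cur]] <- camera_model(matrix(fields$P, 3, 4, byrow = TRUE),
                                mirrored = fields$mirrored,
                                image_size = fields$image_size)
    cams
  }
  for (i in seq_along(raw)) {
    line <- sub("#.*$", "", raw[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[views\\.[A-Za-z0-9_]+\\]$", line)) {
      cams <- flush(cams, cur, fields)
      cur <- sub("^\\[views\\.([A-Za-z0-9_]+)\\]$", "\\1", line)
      fields <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3L || is.null(cur)) {
      stop(sprintf("%s: malformed TOML at line %d: '%s'", path, i, raw[i]),
           call. = FALSE)
    }
    key <- m[2]
    val <- m[3]
    parsed <- if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl("^\\[.*\\]$", val)) {
      items <- trimws(strsplit(sub("^\\[(.*)\\]$", "\\1", val), ",")[[1]])
      nums <- suppressWarnings(as.numeric(items))
      if (anyNA(nums)) {
        stop(sprintf("%s: non-numeric array entry at line %d", path, i),
             call. = FALSE)
      }
      nums
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        stop(sprintf("%s: unparseable value at line %d: '%s'", path, i, val),
             call. = FALSE)
      }
      num
    }
    fields[[key]] <- parsed
  }
  cams <- flush(cams, cur, fields)
  if (!length(cams)) stop("calibration file defines no views", call. = FALSE)
  if (!is.null(views)) {
    miss <- setdiff(views, names(cams))
    if (length(miss)) {
      stop(sprintf("calibration file is missing view(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  cams
}
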