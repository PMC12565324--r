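#' Landmark configurations
#'
#' A `landmark_config` holds one specimen's ordered landmark coordinates:
#' fixed anatomical landmarks first (patch id 0), then the sliding
#' semi-landmarks tagged with their patch id. Row order must be identical
#' across all specimens of a study.
#'
#' @param coordinates k x 3 numeric matrix (mm).
#' @param patch_ids integer vector of length k; 0 for fixed landmarks
#'   and the (positive) patch number for semi-landmarks.
#' @param specimen_id specimen identifier.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(coordinates, patch_ids = rep(0L, nrow(coordinates)),
                            specimen_id = "specimen") {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  if (ncol(coordinates) != 3L)
    .mc_stop("coordinates must have 3 columns", class = "validation_error")
  if (!all(is.finite(coordinates)))
    .mc_stop("non-finite landmark coordinates in '%s'", specimen_id,
             class = "validation_error")
  patch_ids <- as.integer(patch_ids)
  if (length(patch_ids) != nrow(coordinates))
    .mc_stop("patch_ids length mismatch", class = "validation_error")
  fixed <- which(patch_ids == 0L)
  if (length(fixed) && !identical(fixed, seq_along(fixed)))
    .mc_stop("fixed landmarks must come first", class = "validation_error")
  structure(list(specimen_id = as.character(specimen_id),
                 coordinates = coordinates, patch_ids = patch_ids),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config '%s': %d fixed + %d semi-landmarks>\n",
              x$specimen_id, sum(x$patch_ids == 0L), sum(x$patch_ids > 0L)))
  invisible(x)
}

n_landmarks <- function(config) nrow(config$coordinates)

#' Write a landmark configuration to disk
#'
#' Two dialects are supported. `"csv"` (canonical; keeps patch ids) writes
#' columns `id,patch,x,y,z`. `"tps"` writes a classic morphometrics LM3
#' block: `LM3=<k>`, one `x y z` line per point, then `ID=<specimen_id>`.
#' Coordinates are printed with full double precision so a round trip
#' through [read_landmarks()] is lossless.
#'
#' @param config a [landmark_config()].
#' @param path output file.
#' @param dialect `"csv"` or `"tps"`.
#' @export
write_landmarks <- function(config, path, dialect = c("csv", "tps")) {
  dialect <- match.arg(dialect)
  if (!all(is.finite(config$coordinates)))
    .mc_stop("refusing to write non-finite coordinates",
             class = "validation_error")
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "csv") {
    lines <- c("id,patch,x,y,z",
               paste(seq_len(nrow(config$coordinates)) - 1L,
                     config$patch_ids,
                     fmt(config$coordinates[, 1]),
                     fmt(config$coordinates[, 2]),
                     fmt(config$coordinates[, 3]), sep = ","))
  } else {
    lines <- c(sprintf("LM3=%d", nrow(config$coordinates)),
               paste(fmt(config$coordinates[, 1]),
                     fmt(config$coordinates[, 2]),
                     fmt(config$coordinates[, 3])),
               sprintf("ID=%s", config$specimen_id))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .mc_stop("cannot write landmarks to %s", path, class = "io_error")
  invisible(path)
}

#' Read a landmark configuration
#'
#' Inverse of [write_landmarks()]. CSV parsing is header-driven, so column
#' order is free as long as `id,patch,x,y,z` are present; rows are sorted
#' by `id`. The TPS dialect has no patch information, so all points read
#' as patch 0.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"tps"`.
#' @param specimen_id identifier for CSV reads (TPS carries its own `ID=`).
#' @return a [landmark_config()].
#' @export
read_landmarks <- function(path, dialect = c("csv", "tps"),
                           specimen_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    .mc_stop("landmark file not found: %s", path, class = "io_error")
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "patch", "x", "y", "z")
    if (!all(need %in% names(df)))
      .mc_stop("landmark CSV must have columns id,patch,x,y,z: %s", path,
               class = "parse_error")
    df <- df[order(df$id), , drop = FALSE]
    landmark_config(cbind(df$x, df$y, df$z), df$patch,
                    specimen_id %||% sub("\\.[^.]*$", "", basename(path)))
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!grepl("^LM3=\\d+$", lines[1]))
      .mc_stop("TPS file must start with LM3=<count>: %s", path,
               class = "parse_error")
    k <- as.integer(sub("^LM3=", "", lines[1]))
    coord_lines <- lines[-1][!grepl("^[A-Za-z]+=", lines[-1])]
    if (length(coord_lines) != k)
      .mc_stop("LM3=%d but %d coordinate lines in %s", k,
               length(coord_lines), path, class = "parse_error")
    xyz <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"),
                                 function(v) as.numeric(v[1:3])))
    idl <- grep("^ID=", lines, value = TRUE)
    landmark_config(xyz, rep(0L, k),
                    if (length(idl)) sub("^ID=", "", idl[1])
                    else specimen_id %||% "specimen")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
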