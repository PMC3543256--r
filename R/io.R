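#' Read and write eye frames
#'
#' Frames are stored as 8-bit grayscale rasters, either PNG (via the
#' \pkg{png} package) or plain-text PGM (`P2`). Intensities are rounded to
#' integers on write.
#'
#' @param frame An `eye_frame`.
#' @param path Output path; format chosen by extension (`.png` or `.pgm`).
#' @return `write_frame` returns `path` invisibly; `read_frame` returns an
#'   `eye_frame`.
#' @export
write_frame <- function(frame, path) {
  px <- round(pmin(pmax(frame$pixels, 0), 255))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(px / 255, path)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)), "255"), con)
    utils::write.table(px, con, row.names = FALSE, col.names = FALSE)
  } else stop("unsupported frame format: ", path)
  invisible(path)
}

#' @rdname write_frame
#' @param index Frame index to store in the result.
#' @export
read_frame <- function(path, index = 0L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    px <- round(px * 255)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    txt <- readLines(path)
    txt <- txt[!grepl("^#", txt)]
    if (txt[1] != "P2") stop("only plain (P2) PGM is supported")
    dims <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
    vals <- as.numeric(unlist(strsplit(trimws(txt[-(1:3)]), "\\s+")))
    px <- matrix(vals, nrow = dims[2], byrow = TRUE)
  } else stop("unsupported frame format: ", path)
  structure(list(pixels = px, width_px = ncol(px), height_px = nrow(px),
                 index = as.integer(index)), class = "eye_frame")
}

#' Write a simulated session to CSV
#'
#' One row per frame: frame index, true POG and the eight feature
#' coordinates, with the phase and setting tags stored in leading comment
#' lines.
#'
#' @param session A `gaze_session`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "gaze_session"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phase: %s", attr(session, "phase")), con)
  writeLines(sprintf("# setting: %s", attr(session, "setting")), con)
  utils::write.csv(as.data.frame(session), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[grepl("^#", hdr)]
  df <- utils::read.csv(path, comment.char = "#")
  tag <- function(name) {
    m <- meta[grepl(paste0("^# ", name, ":"), meta)]
    if (length(m)) trimws(sub(paste0("^# ", name, ":"), "", m[1])) else NA
  }
  attr(df, "phase") <- tag("phase")
  attr(df, "setting") <- tag("setting")
  class(df) <- c("gaze_session", "data.frame")
  df
}
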