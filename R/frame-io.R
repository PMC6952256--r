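#' Read and write image frames
#'
#' Single-frame readers/writers for PNG and TIFF (8- or 16-bit input; both
#' are mapped to the unit interval on load). Grayscale input is replicated
#' to three channels; an alpha channel is dropped.
#'
#' @param path file path; format is chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_frame()` returns an RGB frame array; `write_frame()`
#'   returns `path` invisibly.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: .", ext, call. = FALSE)
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  validate_frame(x)
  x
}

#' @rdname read_frame
#' @param frame RGB frame array to write (8-bit output for PNG; TIFF honours
#'   `bits`).
#' @param bits bits per sample for TIFF output (8 or 16).
#' @export
write_frame <- function(frame, path, bits = 8L) {
  if (length(dim(frame)) == 3L) validate_frame(frame)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(frame, path),
    tif  = ,
    tiff = tiff::writeTIFF(frame, path, bits.per.sample = as.integer(bits)),
    stop("unsupported frame format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read or write a numbered frame sequence
#'
#' A sequence is a directory of PNG/TIFF files, ordered lexicographically.
#'
#' @param dir directory containing (or to receive) the frames.
#' @param pattern filename regexp used when reading.
#' @return `read_frames()` returns a named list of frames (unreadable files
#'   are skipped with a warning); `write_frames()` writes `frame_0001.png`,
#'   ... and returns the paths invisibly.
#' @export
read_frames <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no frames found in ", dir, call. = FALSE)
  frames <- list()
  for (f in files) {
    fr <- tryCatch(read_frame(f), error = function(e) {
      warning("skipping unreadable frame ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(fr)) frames[[basename(f)]] <- fr
  }
  frames
}

#' @rdname read_frames
#' @param frames list of RGB frame arrays.
#' @param format output format, `"png"` or `"tiff"`.
#' @export
write_frames <- function(frames, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.%s", seq_along(frames), format))
  for (i in seq_along(frames)) write_frame(frames[[i]], paths[i])
  invisible(paths)
}

#' Decode or encode video through an external codec
#'
#' The library's contract is frame sequences; video containers (MP4/AVI)
#' are handled by shelling out to an `ffmpeg` executable when one is on the
#' PATH. `video_to_frames()` decodes into a directory of PNG frames and
#' reads them; `frames_to_video()` encodes a written sequence.
#'
#' @param video path to a video container.
#' @param dir working directory for the decoded/encoded frames.
#' @param fps frame rate used when encoding.
#' @return `video_to_frames()` returns a list of frames;
#'   `frames_to_video()` returns `video` invisibly.
#' @export
video_to_frames <- function(video, dir = tempfile("frames")) {
  ff <- Sys.which("ffmpeg")
  if (!nzchar(ff))
    stop("video decoding requires an ffmpeg executable on the PATH; ",
         "decode to a PNG/TIFF frame directory and use read_frames()",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  status <- system2(ff, c("-y", "-loglevel", "error", "-i", shQuote(video),
                          shQuote(file.path(dir, "frame_%06d.png"))))
  if (status != 0L) stop("ffmpeg decode failed for ", video, call. = FALSE)
  read_frames(dir)
}

#' @rdname video_to_frames
#' @param frames list of RGB frame arrays to encode.
#' @export
frames_to_video <- function(frames, video, fps = 25, dir = tempfile("frames")) {
  ff <- Sys.which("ffmpeg")
  if (!nzchar(ff))
    stop("video encoding requires an ffmpeg executable on the PATH; ",
         "use write_frames() to emit a PNG sequence instead", call. = FALSE)
  write_frames(frames, dir)
  status <- system2(ff, c("-y", "-loglevel", "error", "-framerate", fps,
                          "-i", shQuote(file.path(dir, "frame_%04d.png")),
                          shQuote(video)))
  if (status != 0L) stop("ffmpeg encode failed for ", video, call. = FALSE)
  invisible(video)
}
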