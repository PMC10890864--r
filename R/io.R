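# Reading and writing grayscale image stacks. The canonical on-disk format
# is 16-bit grayscale TIFF (lossless, diffable); 8/16-bit PNG and 8-bit TIFF
# are also read. In memory every frame lives on the [-1, 1] scale, matching
# the generator's tanh output range.

#' Read a single grayscale frame to a [-1, 1] matrix
#'
#' @param path a `.png`, `.tif` or `.tiff` file
#' @return `(H, W)` matrix; 16-bit value 65535 maps to +1, 0 to -1
#' @export
readFrameImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext))
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x * 2 - 1
}

#' Write a grayscale frame from the [-1, 1] scale
#'
#' Values outside [-1, 1] are clipped with a warning. TIFF files are written
#' at `bitDepth` (8 or 16); PNG files are 8-bit (the installed png writer has
#' no 16-bit mode).
#'
#' @param m `(H, W)` matrix in [-1, 1]
#' @param path output file, extension selects the format
#' @param bitDepth 8 or 16 (TIFF only)
#' @export
writeFrameImage <- function(m, path, bitDepth = 16L) {
  if (min(m) < -1 - 1e-9 || max(m) > 1 + 1e-9) {
    warning("frame values outside [-1, 1] were clipped on write")
    m <- clamp(m, -1, 1)
  }
  x <- (m + 1) / 2
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = as.integer(bitDepth),
                           compression = "none"),
    stop("unsupported image extension: ", ext))
  invisible(path)
}

#' Load a frame directory as a VideoSequence
#'
#' Frames are read in lexicographic filename order; all frames must share
#' one size.
#'
#' @param dir directory containing PNG/TIFF frames
#' @return a [VideoSequence-class]
#' @export
loadSequence <- function(dir) {
  fs <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                        ignore.case = TRUE))
  if (!length(fs)) stop("no frames found in ", dir)
  frames <- lapply(fs, readFrameImage)
  d1 <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) all(dim(f) == d1), logical(1))))
    stop("frames in ", dir, " have mixed dimensions")
  VideoSequence(frames)
}

#' Save a VideoSequence as zero-padded frame files
#'
#' @param seq a [VideoSequence-class]
#' @param dir output directory (created)
#' @param bitDepth 8 or 16
#' @param format "tiff" (default, supports 16-bit) or "png" (8-bit)
#' @return character vector of written paths, invisibly
#' @export
saveSequence <- function(seq, dir, bitDepth = 16L, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T <- nFrames(seq)
  paths <- file.path(dir, sprintf("frame_%03d.%s", seq_len(T) - 1L, ext))
  for (t in seq_len(T)) writeFrameImage(getFrame(seq, t), paths[t], bitDepth)
  invisible(paths)
}

#' Read a dataset manifest written by [buildPhantomDataset()]
#' @param dir dataset directory
#' @export
readManifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"))
}

#' List all loose frame images under a directory (recursively)
#' @keywords internal
list_frame_files <- function(dir) {
  sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                  recursive = TRUE, ignore.case = TRUE))
}

#' Load every image under a directory as a list of [-1, 1] matrices
#' @param dir directory searched recursively for PNG/TIFF files
#' @export
loadImageSet <- function(dir) {
  fs <- list_frame_files(dir)
  if (!length(fs)) stop("no images found in ", dir)
  out <- lapply(fs, readFrameImage)
  names(out) <- substring(fs, nchar(dir) + 2L)
  out
}
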