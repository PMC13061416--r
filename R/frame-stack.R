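#' Construct a frame stack
#'
#' A frame stack is a T-frame grayscale video held as an `H x W x T` numeric
#' array of 8-bit intensities (0–255), with the acquisition frame rate and
#' optional optical calibration attached. Pixel coordinates are 0-based,
#' `(row, col)` order, origin at the top-left; intervals elsewhere in the
#' package are half-open.
#'
#' @param frames `H x W x T` numeric array, all values in `[0, 255]`.
#' @param fps Frame rate, frames/s.
#' @param pixel_size_mm mm per pixel, or `NA` when the optics are
#'   uncalibrated (distances then degrade to px; see [track_centroids()]).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 0.87, pixel_size_mm = NA_real_) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be an H x W x T array.",
          class = "larvasleep_format_error")
  }
  assert_scalar_num(fps, "fps", min = 0, strict_min = TRUE)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("Frame intensities must lie in [0, 255].",
          class = "larvasleep_format_error")
  }
  structure(frames, fps = fps, pixel_size_mm = pixel_size_mm,
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %.3g fps, %s\n",
              d[1], d[2], d[3], attr(x, "fps"),
              if (is.na(attr(x, "pixel_size_mm"))) "uncalibrated" else
                sprintf("%.4g mm/px", attr(x, "pixel_size_mm"))))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(unclass(x))

n_frames <- function(stack) dim(stack)[3]

rgb_to_gray <- function(arr) {
  # Rec. 601 luminance
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Read a frame stack from disk
#'
#' Accepts either a multi-page TIFF file or a directory of single-frame
#' PNG/TIFF images; directory frames are loaded in lexical filename order
#' (zero-padded numbering preserves acquisition order). RGB input is
#' converted to grayscale by Rec. 601 luminance.
#'
#' @param path Path to a multi-page TIFF or a directory of frames.
#' @param fps Frame rate to attach (frames/s).
#' @param pixel_size_mm Optional optical calibration, mm per pixel.
#' @return A [frame_stack].
#' @export
read_frame_stack <- function(path, fps = 0.87, pixel_size_mm = NA_real_) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      abort(sprintf("No PNG/TIFF frames found in '%s'.", path),
            class = "larvasleep_not_found")
    }
    mats <- map(files, read_one_frame)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- map(pages, as_gray_255)
  } else {
    abort(sprintf("'%s' does not exist.", path),
          class = "larvasleep_not_found")
  }
  dims <- vapply(mats, function(m) dim(m)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("Frames have mixed dimensions.", class = "larvasleep_format_error")
  }
  arr <- array(unlist(mats, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(mats)))
  frame_stack(arr, fps = fps, pixel_size_mm = pixel_size_mm)
}

read_one_frame <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  as_gray_255(img)
}

as_gray_255 <- function(img) {
  if (length(dim(img)) == 3L) img <- rgb_to_gray(img)
  round(img * 255)
}

#' Write a frame stack as a multi-page 8-bit TIFF
#'
#' @param stack A [frame_stack].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  mats <- map(seq_len(n_frames(stack)),
              function(t) unclass(stack)[, , t] / 255)
  tiff::writeTIFF(mats, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
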