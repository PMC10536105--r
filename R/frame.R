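#' Construct a photometric frame
#'
#' A photometric frame is one grayscale CCD capture together with its
#' acquisition metadata: the thickness of the scattering sample, the laser
#' power, whether the capture is of transmitted (forward-scattered) or
#' reflected (backscattered) light, and the replicate indices (measurement
#' site on the sample perimeter, capture number at that site).
#'
#' Pixels are held as a numeric (double) matrix of digital numbers (DN) so
#' that downstream statistics are never truncated; files on disk remain
#' integer-valued. The coordinate convention is (row, col), 0-based, row 0 at
#' the top; pixel (r, c) has its center at (r + 0.5, c + 0.5) in continuous
#' coordinates.
#'
#' @param pixels numeric matrix of pixel values in `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, 8 or 16.
#' @param thickness_mm sample thickness in mm, > 0.
#' @param power_mW laser power in mW, > 0.
#' @param mode `"transmitted"` or `"reflected"`.
#' @param site_index,capture_index positive integer replicate indices.
#' @return An object of class `photometric_frame`.
#' @export
photometric_frame <- function(pixels, bit_depth = 8L, thickness_mm, power_mW,
                              mode = c("transmitted", "reflected"),
                              site_index = 1L, capture_index = 1L) {
  mode <- match.arg(mode)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  maxdn <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxdn)
    stop(sprintf("pixel values must lie in [0, %d]", maxdn))
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L || thickness_mm <= 0)
    stop("`thickness_mm` must be a single positive number")
  if (!is.numeric(power_mW) || length(power_mW) != 1L || power_mW <= 0)
    stop("`power_mW` must be a single positive number")
  site_index <- as.integer(site_index)
  capture_index <- as.integer(capture_index)
  if (site_index < 1L || capture_index < 1L)
    stop("replicate indices must be >= 1")
  structure(
    list(pixels = pixels, bit_depth = bit_depth,
         thickness_mm = as.numeric(thickness_mm),
         power_mW = as.numeric(power_mW), mode = mode,
         site_index = site_index, capture_index = capture_index),
    class = "photometric_frame")
}

#' @export
print.photometric_frame <- function(x, ...) {
  cat(sprintf(
    "<photometric_frame> %d x %d px, %d-bit, %s light\n  d = %g mm, P = %g mW, site %d, capture %d, DN range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$mode, x$thickness_mm,
    x$power_mW, x$site_index, x$capture_index, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a frame set
#'
#' An ordered collection of [photometric_frame] objects sharing one pixel
#' grid shape and bit depth, with a free-text provenance tag.
#'
#' @param frames list of `photometric_frame` objects.
#' @param provenance free-text source tag.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(frames, provenance = "") {
  if (!length(frames)) stop("`frames` must be non-empty")
  ok <- vapply(frames, inherits, logical(1), "photometric_frame")
  if (!all(ok)) stop("all elements must be photometric_frame objects")
  shp <- dim(frames[[1]]$pixels)
  bd <- frames[[1]]$bit_depth
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), shp))
      stop(sprintf("frame %d has shape %s, expected %s", i,
                   paste(dim(frames[[i]]$pixels), collapse = "x"),
                   paste(shp, collapse = "x")))
    if (frames[[i]]$bit_depth != bd)
      stop(sprintf("frame %d has bit depth %d, expected %d", i,
                   frames[[i]]$bit_depth, bd))
  }
  structure(list(frames = frames, provenance = provenance),
            class = "frame_set")
}

#' @export
length.frame_set <- function(x) length(x$frames)

#' @export
print.frame_set <- function(x, ...) {
  shp <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<frame_set> %d frames, %d x %d px, %d-bit%s\n",
              length(x$frames), shp[1], shp[2], x$frames[[1]]$bit_depth,
              if (nzchar(x$provenance)) paste0(" (", x$provenance, ")") else ""))
  invisible(x)
}

#' Frame metadata as a one-row data frame
#' @param frame a [photometric_frame].
#' @return data.frame with thickness_mm, power_mW, mode, site_index,
#'   capture_index.
#' @export
frame_metadata <- function(frame) {
  data.frame(thickness_mm = frame$thickness_mm, power_mW = frame$power_mW,
             mode = frame$mode, site_index = frame$site_index,
             capture_index = frame$capture_index,
             stringsAsFactors = FALSE)
}
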