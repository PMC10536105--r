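#' Read a photometric frame from an image file
#'
#' Reads a grayscale PNG, TIFF or binary PGM (P5) file and attaches the
#' acquisition metadata supplied in `sidecar`. Image formats carry no
#' standard fields for sample thickness or laser power, so metadata always
#' travels in a sidecar record (one manifest row, see [load_frameset]).
#'
#' @param path image file; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @param sidecar list or one-row data.frame with `thickness_mm`, `power_mW`,
#'   `mode`, and optionally `site_index`, `capture_index` (default 1).
#' @return A [photometric_frame] whose pixels match the file bit-exactly.
#' @export
read_frame <- function(path, sidecar) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  sidecar <- as.list(sidecar)
  for (f in c("thickness_mm", "power_mW", "mode"))
    if (is.null(sidecar[[f]])) stop("sidecar is missing field: ", f)
  img <- read_gray_image(path)
  photometric_frame(img$pixels, bit_depth = img$bit_depth,
                    thickness_mm = sidecar$thickness_mm,
                    power_mW = sidecar$power_mW, mode = sidecar$mode,
                    site_index = sidecar$site_index %||% 1L,
                    capture_index = sidecar$capture_index %||% 1L)
}

#' Write a photometric frame to an image file
#'
#' Pixels are rounded to integer DN and written losslessly, so
#' `read_frame(write_frame(frame))` round-trips bit-exactly when the frame
#' holds integer DN. 16-bit frames must go to TIFF or PGM: the PNG writer
#' available to this package emits 8-bit files only (16-bit PNG is still
#' readable).
#'
#' @param frame a [photometric_frame].
#' @param path output file; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "photometric_frame"))
  fmt <- image_format(path)
  maxdn <- 2^frame$bit_depth - 1
  px <- pmin(pmax(round(frame$pixels), 0), maxdn)
  ok <- switch(fmt,
    png = {
      if (frame$bit_depth != 8L)
        stop("16-bit PNG output is not supported; write TIFF or PGM instead")
      png::writePNG(px / maxdn, path)
      TRUE
    },
    tiff = {
      tiff::writeTIFF(px / maxdn, path, bits.per.sample = frame$bit_depth,
                      compression = "none")
      TRUE
    },
    pgm = {
      write_pgm(px, path, maxval = maxdn)
      TRUE
    })
  if (!isTRUE(ok) || !file.exists(path)) stop("failed to write: ", path)
  invisible(path)
}

#' Load a frame set from a manifest
#'
#' The manifest is a UTF-8 CSV with a header row and columns `path`,
#' `thickness_mm`, `power_mW`, `mode`, `site_index`, `capture_index`; each
#' row references one image file. Relative image paths resolve against the
#' manifest's own directory. Frames are returned in manifest order; all must
#' share one pixel-grid shape and bit depth, and the metadata key
#' (thickness, power, mode, site, capture) must be unique per row.
#'
#' @param manifest path to the manifest CSV.
#' @return A [frame_set] tagged with the manifest path as provenance.
#' @export
load_frameset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "thickness_mm", "power_mW", "mode", "site_index",
            "capture_index")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(tab)) stop("manifest has no rows")
  key <- do.call(paste, c(tab[c("thickness_mm", "power_mW", "mode",
                                "site_index", "capture_index")], sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate metadata key in manifest row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  base <- dirname(manifest)
  frames <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, tab$path[i])
    if (!file.exists(p))
      stop(sprintf("manifest row %d references missing file: %s", i,
                   tab$path[i]))
    frames[[i]] <- read_frame(p, tab[i, ])
  }
  frame_set(frames, provenance = manifest)
}

#' Write a frame set and matching manifest to a directory
#'
#' @param fs a [frame_set].
#' @param dir output directory (created if needed).
#' @param format `"pgm"`, `"png"` or `"tiff"`.
#' @return Path to the written manifest CSV, invisibly.
#' @export
write_frameset <- function(fs, dir, format = c("pgm", "png", "tiff")) {
  stopifnot(inherits(fs, "frame_set"))
  format <- match.arg(format)
  ext <- c(pgm = "pgm", png = "png", tiff = "tif")[[format]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(fs$frames))
  for (i in seq_along(fs$frames)) {
    fr <- fs$frames[[i]]
    fn <- sprintf("frame_%04d.%s", i, ext)
    write_frame(fr, file.path(dir, fn))
    rows[[i]] <- cbind(data.frame(path = fn, stringsAsFactors = FALSE),
                       frame_metadata(fr))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png", tif = "tiff", tiff = "tiff", pgm = "pgm",
         stop("unsupported image extension: .", ext,
              " (expected png, tif/tiff, or pgm)"))
}

# Returns list(pixels = integer-valued double matrix of DN, bit_depth).
read_gray_image <- function(path) {
  fmt <- image_format(path)
  if (fmt == "pgm") return(read_pgm(path))
  arr <- if (fmt == "png") png::readPNG(path, info = TRUE)
         else tiff::readTIFF(path, info = TRUE)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L) stop("color/multichannel image rejected: ", path)
    arr <- arr[, , 1L]
  }
  bd <- attr(arr, "info")$bit.depth %||%
    attr(arr, "bits.per.sample") %||% 8L
  bd <- if (bd > 8L) 16L else 8L
  maxdn <- 2^bd - 1
  # readers normalize to [0,1]; undo to integer DN (and drop reader attrs)
  px <- round(unclass(arr) * maxdn)
  attributes(px) <- list(dim = dim(arr))
  list(pixels = px, bit_depth = as.integer(bd))
}

# Binary PGM (P5), maxval <= 255 one byte/pixel big-endian, else two bytes.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokens(con, 4L)
  if (tok[1] != "P5") stop("not a binary PGM (P5) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.integer(tok[4])
  if (anyNA(c(w, h, mx)) || w < 1L || h < 1L || mx < 1L || mx > 65535L)
    stop("malformed PGM header: ", path)
  bytes <- if (mx > 255L) 2L else 1L
  vals <- readBin(con, "integer", n = w * h, size = bytes, signed = FALSE,
                  endian = "big")
  if (length(vals) != w * h) stop("truncated PGM pixel data: ", path)
  list(pixels = matrix(as.double(vals), nrow = h, ncol = w, byrow = TRUE),
       bit_depth = if (mx > 255L) 16L else 8L)
}

write_pgm <- function(px, path, maxval) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(px), nrow(px), as.integer(maxval)),
            con, eos = NULL)
  vals <- as.integer(t(px))
  writeBin(vals, con, size = if (maxval > 255L) 2L else 1L, endian = "big")
  invisible(path)
}

# Whitespace/comment-aware header tokenizer for PGM.
pgm_tokens <- function(con, n) {
  tok <- character(0)
  cur <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch)) break
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(cur)) { tok <- c(tok, cur); cur <- "" }
      if (length(tok) == n) break
    } else cur <- paste0(cur, ch)
  }
  if (length(tok) < n) stop("unexpected end of PGM header")
  tok
}
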