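#' Detect the bright region of interest
#'
#' Line-by-line scan for the bright area: pixels at or above a sensitivity
#' threshold (a fraction `tau` of the frame's maximum DN) are collected and
#' their bounding box formed. The box is accepted when the form objective
#' function -- the ratio of the box's sides (rows / cols) -- lies within
#' `form_limits`; otherwise the threshold is lowered by `tau_step` and the
#' scan repeated, down to `tau_min`. An accepted box is expanded to a square
#' about its own center (clipped to the frame) so the downstream symmetry
#' point has the parity the ring analysis expects.
#'
#' @param frame a [photometric_frame] with at least one nonzero pixel.
#' @param tau0 initial threshold fraction of the maximum DN.
#' @param tau_step decrement applied when the form test fails.
#' @param tau_min smallest threshold fraction attempted.
#' @param form_limits `c(lo, hi)` acceptance band for the side ratio,
#'   `lo <= 1 <= hi`.
#' @return An object of class `region_of_interest` with half-open 0-based
#'   bounds `row0, col0, row1, col1`, the accepted `threshold_used` and the
#'   final `form_value`.
#' @export
detect_roi <- function(frame, tau0 = 0.5, tau_step = 0.05, tau_min = 0.05,
                       form_limits = c(0.8, 1.25)) {
  stopifnot(inherits(frame, "photometric_frame"))
  if (!(tau_min > 0 && tau_min <= tau0 && tau0 <= 1))
    stop("need 0 < tau_min <= tau0 <= 1")
  if (!(form_limits[1] <= 1 && 1 <= form_limits[2]))
    stop("`form_limits` must bracket 1")
  px <- frame$pixels
  mx <- max(px)
  if (mx <= 0) stop("no bright area: frame is all zero")
  tau <- tau0
  form <- NA_real_
  repeat {
    bright <- px >= tau * mx
    rows <- which(rowSums(bright) > 0L)
    cols <- which(colSums(bright) > 0L)
    if (length(rows)) {
      r0 <- rows[1] - 1L; r1 <- rows[length(rows)]     # half-open, 0-based
      c0 <- cols[1] - 1L; c1 <- cols[length(cols)]
      form <- (r1 - r0) / (c1 - c0)
      if (form >= form_limits[1] && form <= form_limits[2]) {
        sq <- squarify_box(r0, c0, r1, c1, dim(px))
        return(structure(list(row0 = sq[1], col0 = sq[2], row1 = sq[3],
                              col1 = sq[4], threshold_used = tau,
                              form_value = form),
                         class = "region_of_interest"))
      }
    }
    tau <- tau - tau_step
    if (tau < tau_min - 1e-12)
      stop(sprintf(
        "no threshold in [%g, %g] gives an acceptable bright-area form (last form_value = %g)",
        tau_min, tau0, form))
  }
}

# Expand a half-open box to a square about its own center, clipped to the
# frame (clipping can leave it non-square at the frame edge).
squarify_box <- function(r0, c0, r1, c1, shape) {
  side <- max(r1 - r0, c1 - c0)
  ctr_r <- (r0 + r1) / 2
  ctr_c <- (c0 + c1) / 2
  nr0 <- round(ctr_r - side / 2); nc0 <- round(ctr_c - side / 2)
  nr0 <- max(0L, min(nr0, shape[1] - side))
  nc0 <- max(0L, min(nc0, shape[2] - side))
  if (nr0 < 0L) { nr0 <- 0L }  # side wider than frame: clip
  if (nc0 < 0L) { nc0 <- 0L }
  c(as.integer(nr0), as.integer(nc0),
    as.integer(min(nr0 + side, shape[1])),
    as.integer(min(nc0 + side, shape[2])))
}

#' Radial symmetry point of a region of interest
#'
#' For an ROI whose side contains an odd number of pixel rows, the symmetry
#' point is the center of the central pixel; for an even side it is the
#' common corner of the four central pixels. Rows and columns are handled
#' independently, so a clipped (non-square) ROI still gets a well-defined
#' point; parity is reported as `"odd"` only when both sides are odd.
#'
#' @param roi a `region_of_interest`.
#' @return An object of class `symmetry_point` with continuous `rc`
#'   (row, col) and `parity`.
#' @export
symmetry_point <- function(roi) {
  stopifnot(inherits(roi, "region_of_interest"))
  axis_center <- function(lo, hi) {
    s <- hi - lo
    if (s %% 2L == 1L) lo + (s - 1L) / 2 + 0.5 else lo + s / 2
  }
  sr <- roi$row1 - roi$row0
  sc <- roi$col1 - roi$col0
  structure(list(rc = c(axis_center(roi$row0, roi$row1),
                        axis_center(roi$col0, roi$col1)),
                 parity = if (sr %% 2L == 1L && sc %% 2L == 1L) "odd"
                          else "even"),
            class = "symmetry_point")
}

#' Zone geometry: symmetry point plus ring radii
#'
#' @param center a `symmetry_point`, or a length-2 numeric (row, col).
#' @param R1_px,R2_px,R3_px radii in px, `0 < R1 < R2 < R3`. R1 bounds the
#'   central circle A1 (nominally the collimated-beam image); A2 is the
#'   middle ring R1--R2 and A3 the external ring R2--R3. R2 and R3 are held
#'   fixed across all frames of a batch so ring illuminances are comparable.
#' @return An object of class `zone_geometry`.
#' @export
zone_geometry <- function(center, R1_px, R2_px, R3_px) {
  rc <- if (inherits(center, "symmetry_point")) center$rc else as.numeric(center)
  if (length(rc) != 2L || anyNA(rc)) stop("`center` must be (row, col)")
  if (!(R1_px > 0 && R1_px < R2_px && R2_px < R3_px))
    stop("radii must satisfy 0 < R1 < R2 < R3")
  structure(list(center = rc, R1_px = R1_px, R2_px = R2_px, R3_px = R3_px),
            class = "zone_geometry")
}

#' Detect zone geometry for one frame
#'
#' Convenience wrapper: [detect_roi], then [symmetry_point], then
#' [zone_geometry] with the batch radii.
#'
#' @param frame a [photometric_frame].
#' @param R1_px,R2_px,R3_px batch ring radii, px.
#' @param ... passed to [detect_roi].
#' @return A `zone_geometry`.
#' @export
detect_geometry <- function(frame, R1_px, R2_px, R3_px, ...) {
  zone_geometry(symmetry_point(detect_roi(frame, ...)),
                R1_px, R2_px, R3_px)
}

#' Zone membership masks
#'
#' Classifies every pixel of a frame by the Euclidean distance from its
#' center to the zone center, with half-open radius intervals so the three
#' zones partition the R3 disk exactly: A1 is distance < R1, A2 is
#' R1 <= distance < R2, A3 is R2 <= distance < R3. Membership is by pixel
#' center (no subpixel area weighting); a zone's area is its pixel count.
#'
#' @param geom a [zone_geometry].
#' @param shape `c(rows, cols)` of the frame.
#' @return List of logical matrices `A1`, `A2`, `A3`.
#' @export
zone_masks <- function(geom, shape) {
  stopifnot(inherits(geom, "zone_geometry"))
  nr <- shape[1]; nc <- shape[2]
  ctr <- geom$center
  if (ctr[1] - geom$R3_px < 0 || ctr[1] + geom$R3_px > nr ||
      ctr[2] - geom$R3_px < 0 || ctr[2] + geom$R3_px > nc)
    stop("R3 circle exceeds frame bounds")
  dr <- (seq_len(nr) - 0.5) - ctr[1]
  dc <- (seq_len(nc) - 0.5) - ctr[2]
  dist <- sqrt(outer(dr^2, dc^2, "+"))
  list(A1 = dist < geom$R1_px,
       A2 = dist >= geom$R1_px & dist < geom$R2_px,
       A3 = dist >= geom$R2_px & dist < geom$R3_px)
}

#' Zone illuminance of one frame
#'
#' The illuminance of a zone is the sum of its pixel DN divided by the
#' zone's area in pixels -- i.e., the mean DN over the zone. Pixels inside
#' `exclude` rectangles are dropped from both the sum and the area; by
#' default nothing is excluded (the shadow of the delivery optics is
#' systematic and averages out of ring comparisons, but exclusion is
#' available for sensitivity analysis).
#'
#' @param frame a [photometric_frame].
#' @param geom a [zone_geometry] that fits inside the frame.
#' @param exclude an [occlusion_spec] whose rectangles are excluded, or
#'   `NULL`.
#' @return A one-row data.frame of class `zone_illuminance` with `E_A1`,
#'   `E_A2`, `E_A3`, the included pixel areas, and the frame metadata.
#' @export
zone_illuminance <- function(frame, geom, exclude = NULL) {
  stopifnot(inherits(frame, "photometric_frame"))
  masks <- zone_masks(geom, dim(frame$pixels))
  keep <- matrix(TRUE, nrow(frame$pixels), ncol(frame$pixels))
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "occlusion_spec"))
    for (r in exclude$rectangles)
      keep[(r[1] + 1):r[3], (r[2] + 1):r[4]] <- FALSE
  }
  zs <- lapply(masks, function(m) {
    inc <- m & keep
    n <- sum(inc)
    if (n == 0L) stop("a zone has zero included pixels")
    c(E = sum(frame$pixels[inc]) / n, area = n)
  })
  out <- data.frame(E_A1 = zs$A1[["E"]], E_A2 = zs$A2[["E"]],
                    E_A3 = zs$A3[["E"]], area_A1 = zs$A1[["area"]],
                    area_A2 = zs$A2[["area"]], area_A3 = zs$A3[["area"]],
                    stringsAsFactors = FALSE)
  out <- cbind(out, frame_metadata(frame))
  class(out) <- c("zone_illuminance", class(out))
  out
}

#' Zone illuminances for a whole frame set
#'
#' Detects the symmetry point per frame (batch radii fixed) unless a fixed
#' `geometry` is supplied, and computes [zone_illuminance] for every frame.
#' Frames whose ROI detection fails are reported with a warning and skipped
#' rather than aborting the batch.
#'
#' @param fs a [frame_set].
#' @param R1_px,R2_px,R3_px batch ring radii (used when detecting).
#' @param geometry optional fixed [zone_geometry] applied to every frame.
#' @param exclude optional [occlusion_spec] of pixels to exclude.
#' @param ... passed to [detect_roi].
#' @return data.frame, one row per analyzed frame, plus columns
#'   `center_row`, `center_col`, `threshold_used`, `form_value`.
#' @export
analyze_frameset <- function(fs, R1_px = 30, R2_px = 90, R3_px = 150,
                             geometry = NULL, exclude = NULL, ...) {
  stopifnot(inherits(fs, "frame_set"))
  rows <- list()
  for (i in seq_along(fs$frames)) {
    fr <- fs$frames[[i]]
    res <- tryCatch({
      if (is.null(geometry)) {
        roi <- detect_roi(fr, ...)
        geom <- zone_geometry(symmetry_point(roi), R1_px, R2_px, R3_px)
        diag <- c(roi$threshold_used, roi$form_value)
      } else {
        geom <- geometry
        diag <- c(NA_real_, NA_real_)
      }
      zi <- zone_illuminance(fr, geom, exclude)
      zi$center_row <- geom$center[1]
      zi$center_col <- geom$center[2]
      zi$threshold_used <- diag[1]
      zi$form_value <- diag[2]
      zi
    }, error = function(e) {
      warning(sprintf("frame %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no frame could be analyzed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average replicate measurements
#'
#' Averages zone illuminances over all sites and captures sharing one
#' (thickness, power, mode) condition -- the replicate protocol of repeated
#' captures at several points on the sample perimeter.
#'
#' @param measurements data.frame of [zone_illuminance] rows (e.g. from
#'   [analyze_frameset]).
#' @return data.frame with one row per (thickness_mm, power_mW, mode) and
#'   mean `E_A1`, `E_A2`, `E_A3`, plus `n_frames`.
#' @export
average_replicates <- function(measurements) {
  need <- c("thickness_mm", "power_mW", "mode", "E_A1", "E_A2", "E_A3")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements are missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(measurements)) stop("empty measurement group")
  agg <- stats::aggregate(
    measurements[c("E_A1", "E_A2", "E_A3")],
    by = measurements[c("thickness_mm", "power_mW", "mode")],
    FUN = mean)
  cnt <- stats::aggregate(list(n_frames = measurements$E_A1),
                          by = measurements[c("thickness_mm", "power_mW",
                                              "mode")],
                          FUN = length)
  out <- merge(agg, cnt, sort = TRUE)
  out[order(out$mode, out$power_mW, out$thickness_mm), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}
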