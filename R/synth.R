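#' Spot model for synthetic photometric frames
#'
#' Describes one synthetic scattering spot: a bright central circle of
#' radius `R1_px` (the collimated-beam image), a middle ring out to `R2_px`
#' and an external ring out to `R3_px`, each rendered at a flat target mean
#' DN, over a flat background, with optional Gaussian read noise.
#'
#' @param center_rc continuous (row, col) of the spot symmetry point, px.
#' @param R1_px,R2_px,R3_px zone radii in px, `0 < R1 < R2 < R3`.
#' @param level_A1,level_A2,level_A3 target mean DN of circle A1 and rings
#'   A2, A3.
#' @param background mean DN outside R3.
#' @param noise_sd Gaussian read-noise standard deviation, DN (>= 0).
#' @param seed integer seed for the noise draw.
#' @return An object of class `spot_model`.
#' @export
spot_model <- function(center_rc, R1_px, R2_px, R3_px,
                       level_A1, level_A2, level_A3,
                       background = 0, noise_sd = 0, seed = 1L) {
  if (!(R1_px > 0 && R1_px < R2_px && R2_px < R3_px))
    stop("radii must satisfy 0 < R1 < R2 < R3")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  lv <- c(level_A1, level_A2, level_A3, background)
  if (any(lv < 0)) stop("levels and background must be >= 0")
  structure(list(center_rc = as.numeric(center_rc), R1_px = R1_px,
                 R2_px = R2_px, R3_px = R3_px, level_A1 = level_A1,
                 level_A2 = level_A2, level_A3 = level_A3,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spot_model")
}

#' Occlusion specification
#'
#' Reflected-light frames carry darkened rectangles where the delivery tube
#' and prism shadow the field of view. The generator darkens these boxes
#' multiplicatively; the analysis may optionally exclude them.
#'
#' @param rectangles list of `c(row0, col0, row1, col1)` half-open 0-based
#'   pixel boxes.
#' @param attenuation multiplicative factor in `[0, 1]` applied inside the
#'   boxes (0 = black, 1 = no effect).
#' @return An object of class `occlusion_spec`.
#' @export
occlusion_spec <- function(rectangles, attenuation = 0.2) {
  if (attenuation < 0 || attenuation > 1)
    stop("`attenuation` must lie in [0, 1]")
  rectangles <- lapply(rectangles, function(r) {
    r <- as.numeric(r)
    if (length(r) != 4L || r[3] <= r[1] || r[4] <= r[2])
      stop("each rectangle must be c(row0, col0, row1, col1) with row1 > row0, col1 > col0")
    r
  })
  structure(list(rectangles = rectangles, attenuation = attenuation),
            class = "occlusion_spec")
}

#' Forward illuminance model in thickness and power
#'
#' Wraps a table of power-polynomial coefficients (the shape returned by
#' [reference_power_polynomials]) together with a gain factor converting
#' model illuminance units to DN. Transmitted-light ring illuminance is
#' m(P) exp(n(P) d); reflected-light is a(P) ln(d) + b(P).
#'
#' @param coefficients data.frame with columns `name`, `ring`, `c0`..`c6`
#'   (see [reference_power_polynomials], the default).
#' @param gain DN per model illuminance unit.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(coefficients = reference_power_polynomials(),
                          gain = 1) {
  need <- c("name", "ring", paste0("c", 0:6))
  miss <- setdiff(need, names(coefficients))
  if (length(miss))
    stop("coefficient table is missing columns: ", paste(miss, collapse = ", "))
  if (gain <= 0) stop("`gain` must be > 0")
  structure(list(coefficients = coefficients, gain = gain),
            class = "forward_model")
}

poly_eval <- function(coeffs, x) {
  # constant-first coefficients, Horner from the top
  acc <- 0
  for (c_k in rev(coeffs)) acc <- acc * x + c_k
  acc
}

fm_coeffs <- function(fm, name, ring) {
  tab <- fm$coefficients
  i <- which(tab$name == name & tab$ring == ring)
  if (length(i) != 1L)
    stop(sprintf("forward model has no unique '%s' polynomial for ring %s",
                 name, ring))
  cc <- as.numeric(tab[i, paste0("c", 0:6)])
  cc[!is.na(cc)]
}

#' Evaluate the forward illuminance model
#'
#' @param fm a [forward_model].
#' @param ring `"A2"` or `"A3"`.
#' @param mode `"transmitted"` or `"reflected"`.
#' @param d sample thickness, mm (> 0). The published transmitted-light fit
#'   is an approximation for d > 0.7 mm; evaluation below that is permitted
#'   but extrapolates.
#' @param P laser power, mW (> 0). Vectorized over `d` and `P`.
#' @return Model illuminance (model units; multiply by `fm$gain` for DN).
#' @export
model_illuminance <- function(fm, ring = c("A2", "A3"),
                              mode = c("transmitted", "reflected"), d, P) {
  stopifnot(inherits(fm, "forward_model"))
  ring <- match.arg(ring)
  mode <- match.arg(mode)
  if (any(d <= 0)) stop("`d` must be > 0")
  if (any(P <= 0)) stop("`P` must be > 0")
  if (mode == "transmitted") {
    m <- poly_eval(fm_coeffs(fm, "m", ring), P)
    n <- poly_eval(fm_coeffs(fm, "n", ring), P)
    m * exp(n * d)
  } else {
    a <- poly_eval(fm_coeffs(fm, "a", ring), P)
    b <- poly_eval(fm_coeffs(fm, "b", ring), P)
    a * log(d) + b
  }
}

#' Render one synthetic photometric frame
#'
#' Every pixel is classified by the distance from its center to the spot's
#' symmetry point using the same half-open rule as the analysis
#' ([zone_masks]): A1 for distance < R1, A2 for R1 <= distance < R2, A3 for
#' R2 <= distance < R3, background beyond. The zone's flat level plus
#' Gaussian read noise (drawn under the model's seed) is then attenuated
#' inside any occlusion rectangles, clipped to the DN range and rounded.
#'
#' @param model a [spot_model].
#' @param occ an [occlusion_spec], or `NULL` for none.
#' @param shape `c(rows, cols)` of the frame.
#' @param bit_depth 8 or 16.
#' @param thickness_mm,power_mW,mode,site_index,capture_index metadata for
#'   the resulting frame.
#' @return A [photometric_frame].
#' @export
render_frame <- function(model, occ = NULL, shape = c(480L, 640L),
                         bit_depth = 16L, thickness_mm = 1, power_mW = 1,
                         mode = "transmitted", site_index = 1L,
                         capture_index = 1L) {
  stopifnot(inherits(model, "spot_model"))
  nr <- shape[1]; nc <- shape[2]
  ctr <- model$center_rc
  if (ctr[1] - model$R3_px < 0 || ctr[1] + model$R3_px > nr ||
      ctr[2] - model$R3_px < 0 || ctr[2] + model$R3_px > nc)
    stop("R3 circle exceeds frame bounds")
  dr <- (seq_len(nr) - 0.5) - ctr[1]
  dc <- (seq_len(nc) - 0.5) - ctr[2]
  dist <- sqrt(outer(dr^2, dc^2, "+"))
  px <- matrix(model$background, nr, nc)
  px[dist < model$R3_px] <- model$level_A3
  px[dist < model$R2_px] <- model$level_A2
  px[dist < model$R1_px] <- model$level_A1
  if (model$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(model$seed)
    px <- px + matrix(stats::rnorm(nr * nc, sd = model$noise_sd), nr, nc)
  }
  if (!is.null(occ)) {
    stopifnot(inherits(occ, "occlusion_spec"))
    for (r in occ$rectangles) {
      if (r[1] < 0 || r[2] < 0 || r[3] > nr || r[4] > nc)
        stop("occlusion rectangle lies outside the frame")
      rows <- (r[1] + 1):r[3]; cols <- (r[2] + 1):r[4]
      px[rows, cols] <- px[rows, cols] * occ$attenuation
    }
  }
  maxdn <- 2^bit_depth - 1
  px <- round(pmin(pmax(px, 0), maxdn))
  photometric_frame(px, bit_depth = bit_depth, thickness_mm = thickness_mm,
                    power_mW = power_mW, mode = mode,
                    site_index = site_index, capture_index = capture_index)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Generate a synthetic thickness-by-power study
#'
#' Produces one frame per combination of thickness, power, mode, measurement
#' site and capture, emulating the replicate protocol of repeated captures
#' at several points along the sample perimeter. Ring target levels are
#' `gain * model_illuminance(...)`; the central circle A1 and the background
#' use fixed configurable levels. Negative model illuminances (possible when
#' extrapolating the reflected model to very thin samples) are clipped to 0
#' DN by rendering. Reflected-light frames receive the default occlusion
#' unless `occlusion` overrides it.
#'
#' @param fm a [forward_model]; its `gain` converts model units to DN.
#' @param thickness_grid thicknesses, mm. Either a numeric vector used for
#'   both modes or a named list `list(transmitted =, reflected =)`.
#' @param power_grid powers, mW.
#' @param modes subset of `c("transmitted", "reflected")`.
#' @param sites,captures replicate counts (sites x captures frames per
#'   condition).
#' @param noise_sd Gaussian read noise, DN.
#' @param seed base seed; per-frame seeds are derived deterministically.
#' @param shape,bit_depth frame geometry.
#' @param geometry list with `center_rc`, `R1_px`, `R2_px`, `R3_px`.
#' @param level_A1,background DN levels of the central circle and background.
#' @param occlusion an [occlusion_spec] for reflected frames, `NULL` for the
#'   default center-shadow rectangle, or `NA` to disable occlusion.
#' @return A list with `frameset` (a [frame_set]) and `manifest`
#'   (data.frame; `path` is filled by [write_frameset]).
#' @export
generate_study <- function(fm = forward_model(),
                           thickness_grid = seq(0.1, 10, by = 0.3),
                           power_grid = reference_power_grid(),
                           modes = c("transmitted", "reflected"),
                           sites = 3L, captures = 3L, noise_sd = 0,
                           seed = 1L, shape = c(480L, 640L), bit_depth = 16L,
                           geometry = NULL, level_A1 = NULL, background = 2,
                           occlusion = NULL) {
  stopifnot(inherits(fm, "forward_model"))
  modes <- match.arg(modes, several.ok = TRUE)
  if (!length(power_grid) || !length(modes)) stop("grids must be non-empty")
  tg <- if (is.list(thickness_grid)) thickness_grid
        else list(transmitted = thickness_grid, reflected = thickness_grid)
  if (any(vapply(tg[modes], length, 0L) == 0L)) stop("grids must be non-empty")
  if (any(unlist(tg[modes]) <= 0) || any(power_grid <= 0))
    stop("grids must be strictly positive")
  if (is.null(geometry))
    geometry <- list(center_rc = shape / 2, R1_px = 30, R2_px = 90,
                     R3_px = 150)
  maxdn <- 2^bit_depth - 1
  if (is.null(level_A1)) level_A1 <- 0.9 * maxdn
  default_occ <- occlusion_spec(list(c(
    geometry$center_rc[1] - 8, geometry$center_rc[2] - 24,
    geometry$center_rc[1] + 8, geometry$center_rc[2] + 24)))
  frames <- list()
  meta <- list()
  k <- 0L
  for (mode in modes) for (d in tg[[mode]]) for (P in power_grid)
    for (s in seq_len(sites)) for (cap in seq_len(captures)) {
      k <- k + 1L
      e2 <- fm$gain * model_illuminance(fm, "A2", mode, d, P)
      e3 <- fm$gain * model_illuminance(fm, "A3", mode, d, P)
      sm <- spot_model(geometry$center_rc, geometry$R1_px, geometry$R2_px,
                       geometry$R3_px, level_A1 = level_A1,
                       level_A2 = max(e2, 0), level_A3 = max(e3, 0),
                       background = background, noise_sd = noise_sd,
                       seed = (seed * 7919L + k * 104729L) %% 2147483647L)
      occ <- if (mode == "reflected") {
        if (is.null(occlusion)) default_occ
        else if (identical(occlusion, NA)) NULL else occlusion
      } else NULL
      frames[[k]] <- render_frame(sm, occ, shape = shape,
                                  bit_depth = bit_depth, thickness_mm = d,
                                  power_mW = P, mode = mode, site_index = s,
                                  capture_index = cap)
      meta[[k]] <- frame_metadata(frames[[k]])
    }
  manifest <- cbind(data.frame(path = rep(NA_character_, k),
                               stringsAsFactors = FALSE),
                    do.call(rbind, meta))
  list(frameset = frame_set(frames, provenance = "zonephot synthetic study"),
       manifest = manifest, geometry = geometry)
}

#' Model-level illuminance table for a study design
#'
#' Evaluates the forward model directly on a thickness-by-power grid,
#' bypassing image rendering and quantization. The result has the same
#' shape as the averaged output of the image pipeline and feeds
#' [run_regression] directly; it is the natural input for noiseless
#' parameter-recovery studies.
#'
#' @inheritParams generate_study
#' @return data.frame with columns `thickness_mm`, `power_mW`, `mode`,
#'   `ring`, `E` (model units times `fm$gain`).
#' @export
model_illuminance_table <- function(fm = forward_model(),
                                    thickness_grid = seq(0.1, 10, by = 0.1),
                                    power_grid = reference_power_grid(),
                                    modes = c("transmitted", "reflected")) {
  modes <- match.arg(modes, several.ok = TRUE)
  tg <- if (is.list(thickness_grid)) thickness_grid
        else list(transmitted = thickness_grid, reflected = thickness_grid)
  rows <- list()
  for (mode in modes) for (ring in c("A2", "A3")) {
    grid <- expand.grid(thickness_mm = tg[[mode]], power_mW = power_grid)
    grid$mode <- mode
    grid$ring <- ring
    grid$E <- fm$gain * model_illuminance(fm, ring, mode, grid$thickness_mm,
                                          grid$power_mW)
    rows[[paste(mode, ring)]] <- grid
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
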