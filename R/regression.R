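#' Fit the exponential thickness model for transmitted light
#'
#' Fits E = m exp(n d) to illuminance-vs-thickness points by least squares
#' on the original scale. Starting values come from the log-linear fit
#' ln E = ln m + n d; a Levenberg-Marquardt refinement then minimizes the
#' untransformed residual sum of squares (pure log-linear fitting would
#' re-weight errors toward thick, dim samples). If the refinement cannot
#' improve on the starting fit -- e.g. exactly degenerate data -- the
#' log-linear solution is kept, so the returned fit never has a larger
#' residual sum of squares than the log-linear one.
#'
#' The exponential law is an approximation valid above a minimum thickness,
#' so points with `d <= d_min` (default 0.7 mm) are excluded and the
#' exclusion counted.
#'
#' @param points data.frame with columns `d` (mm) and `E`, or a list with
#'   those elements.
#' @param d_min minimum thickness, mm; points at or below it are dropped.
#' @param ring,mode,power_mW metadata echoed into the result.
#' @return An object of class `thickness_fit` with `params = c(m, n)`,
#'   `r_squared` (original scale), `n_points` used and `n_excluded`.
#' @export
fit_transmitted <- function(points, d_min = 0.7, ring = NA_character_,
                            mode = "transmitted", power_mW = NA_real_) {
  d <- points$d; E <- points$E
  keep <- d > d_min
  n_excl <- sum(!keep)
  d <- d[keep]; E <- E[keep]
  if (length(d) < 3L)
    stop(sprintf("need >= 3 points with d > %g mm (have %d)", d_min,
                 length(d)))
  if (any(E <= 0))
    stop("non-positive illuminance among usable points; cannot fit an exponential")
  ll <- stats::lm(log(E) ~ d)
  start <- list(m = exp(unname(stats::coef(ll)[1])),
                n = unname(stats::coef(ll)[2]))
  ssr <- function(p) sum((E - p$m * exp(p$n * d))^2)
  fit <- tryCatch({
    nl <- minpack.lm::nlsLM(E ~ m * exp(n * d), start = start,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
    as.list(stats::coef(nl))
  }, error = function(e) start)
  if (ssr(fit) > ssr(start)) fit <- start
  new_thickness_fit(ring, mode, power_mW, params = c(m = fit$m, n = fit$n),
                    fitted = fit$m * exp(fit$n * d), observed = E,
                    n_points = length(d), n_excluded = n_excl)
}

#' Fit the logarithmic thickness model for reflected light
#'
#' Ordinary least squares of E on ln(d): E = a ln(d) + b, the closed-form
#' simple-regression solution.
#'
#' @param points data.frame (or list) with `d` (mm, > 0) and `E`.
#' @param ring,mode,power_mW metadata echoed into the result.
#' @return An object of class `thickness_fit` with `params = c(a, b)`.
#' @export
fit_reflected <- function(points, ring = NA_character_, mode = "reflected",
                          power_mW = NA_real_) {
  d <- points$d; E <- points$E
  if (length(d) < 3L) stop("need >= 3 points")
  if (any(d <= 0)) stop("`d` must be > 0 (ln d undefined)")
  fit <- stats::lm(E ~ log(d))
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  new_thickness_fit(ring, mode, power_mW, params = c(a = a, b = b),
                    fitted = a * log(d) + b, observed = E,
                    n_points = length(d), n_excluded = 0L)
}

new_thickness_fit <- function(ring, mode, power_mW, params, fitted, observed,
                              n_points, n_excluded) {
  structure(list(ring = ring, mode = mode, power_mW = power_mW,
                 params = params, r_squared = r_squared(observed, fitted),
                 n_points = n_points, n_excluded = n_excluded),
            class = "thickness_fit")
}

# 1 - SSres/SStot with centered SStot; a perfect fit of constant data is
# reported as 1 rather than 0/0.
r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res <= .Machine$double.eps^0.5) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' @export
print.thickness_fit <- function(x, ...) {
  cat(sprintf("<thickness_fit> %s %s, P = %g mW: %s, r^2 = %.6f (%d points, %d excluded)\n",
              x$mode, x$ring, x$power_mW,
              paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", "),
              x$r_squared, x$n_points, x$n_excluded))
  invisible(x)
}

#' Fit a polynomial of a model coefficient against laser power
#'
#' Least-squares polynomial of the stated degree in P, coefficients
#' constant-first. The amplitude (m), slope (a) and intercept (b) families
#' use degree 2; the exponential rate (n) uses degree 6. The reported
#' `r_squared` is the approximation reliability of the polynomial.
#'
#' @param P laser powers, mW; at least `degree + 1` distinct values.
#' @param values coefficient value at each power.
#' @param degree polynomial degree.
#' @param name,ring,mode metadata echoed into the result.
#' @return An object of class `power_polynomial` with `coeffs` (constant
#'   first) and `r_squared`.
#' @export
fit_power_polynomial <- function(P, values, degree, name = NA_character_,
                                 ring = NA_character_, mode = NA_character_) {
  if (length(P) != length(values)) stop("`P` and `values` differ in length")
  if (length(unique(P)) < degree + 1L)
    stop(sprintf("degree-%d fit needs >= %d distinct powers (have %d)",
                 degree, degree + 1L, length(unique(P))))
  fit <- stats::lm(values ~ stats::poly(P, degree, raw = TRUE))
  coeffs <- unname(stats::coef(fit))
  fitted_vals <- unname(stats::fitted(fit))
  structure(list(name = name, ring = ring, mode = mode,
                 degree = as.integer(degree), coeffs = coeffs,
                 r_squared = r_squared(values, fitted_vals)),
            class = "power_polynomial")
}

#' @export
print.power_polynomial <- function(x, ...) {
  cat(sprintf("<power_polynomial> %s(P), ring %s (%s), degree %d, r^2 = %.6f\n  %s\n",
              x$name, x$ring, x$mode, x$degree, x$r_squared,
              paste(sprintf("c%d = %.6g", seq_along(x$coeffs) - 1L, x$coeffs),
                    collapse = ", ")))
  invisible(x)
}

#' Two-stage regression of a thickness-by-power illuminance study
#'
#' Stage 1 fits the thickness model per (mode, ring, power): exponential
#' E = m exp(n d) for transmitted light (thicknesses above `d_min` only),
#' logarithmic E = a ln(d) + b for reflected light. Stage 2 fits each
#' family of stage-1 coefficients as a polynomial in laser power: degree 2
#' for m, a, b and degree 6 for n. Stage 2 is skipped (with a warning) for
#' families without enough distinct power levels.
#'
#' @param averaged illuminance table. Either long format with columns
#'   `thickness_mm`, `power_mW`, `mode`, `ring`, `E` (see
#'   [model_illuminance_table]) or the wide output of [average_replicates]
#'   with `E_A2`, `E_A3` columns.
#' @param d_min transmitted-light thickness cutoff, mm.
#' @param degrees named list of polynomial degrees for the m, n, a, b
#'   families.
#' @return List with `thickness_fits` (data.frame: ring, mode, power_mW,
#'   m, n, a, b, r_squared, n_points, n_excluded) and `power_polynomials`
#'   (data.frame: name, ring, mode, degree, c0..c6, r_squared), plus
#'   `fits` and `polynomials` as the underlying objects.
#' @export
run_regression <- function(averaged, d_min = 0.7,
                           degrees = list(m = 2L, n = 6L, a = 2L, b = 2L)) {
  long <- if ("ring" %in% names(averaged)) averaged else widen_to_long(averaged)
  need <- c("thickness_mm", "power_mW", "mode", "ring", "E")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("illuminance table is missing columns: ", paste(miss, collapse = ", "))
  fits <- list()
  for (mode in unique(long$mode)) for (ring in unique(long$ring)) {
    sub <- long[long$mode == mode & long$ring == ring, ]
    if (!nrow(sub)) next
    for (P in sort(unique(sub$power_mW))) {
      pts <- sub[sub$power_mW == P, ]
      pts <- list(d = pts$thickness_mm, E = pts$E)
      f <- tryCatch({
        if (mode == "transmitted")
          fit_transmitted(pts, d_min = d_min, ring = ring, power_mW = P)
        else fit_reflected(pts, ring = ring, power_mW = P)
      }, error = function(e)
        stop(sprintf("stage-1 fit failed for P = %g mW, ring %s, %s: %s",
                     P, ring, mode, conditionMessage(e)), call. = FALSE))
      fits[[length(fits) + 1L]] <- f
    }
  }
  polys <- list()
  for (mode in unique(vapply(fits, `[[`, "", "mode")))
    for (ring in unique(vapply(fits, `[[`, "", "ring"))) {
      sel <- Filter(function(f) f$mode == mode && f$ring == ring, fits)
      if (!length(sel)) next
      P <- vapply(sel, `[[`, 0, "power_mW")
      fam <- names(sel[[1]]$params)   # c("m","n") or c("a","b")
      if (length(unique(P)) < 2L) {
        warning(sprintf(
          "only one power level for ring %s (%s): power polynomials skipped",
          ring, mode))
        next
      }
      for (nm in fam) {
        vals <- vapply(sel, function(f) unname(f$params[nm]), 0)
        deg <- degrees[[nm]]
        pp <- tryCatch(
          fit_power_polynomial(P, vals, deg, name = nm, ring = ring,
                               mode = mode),
          error = function(e) {
            warning(sprintf("power polynomial %s(P), ring %s (%s) skipped: %s",
                            nm, ring, mode, conditionMessage(e)))
            NULL
          })
        if (!is.null(pp)) polys[[length(polys) + 1L]] <- pp
      }
    }
  list(thickness_fits = thickness_fits_table(fits),
       power_polynomials = power_polynomials_table(polys),
       fits = fits, polynomials = polys)
}

widen_to_long <- function(wide) {
  need <- c("thickness_mm", "power_mW", "mode", "E_A2", "E_A3")
  miss <- setdiff(need, names(wide))
  if (length(miss))
    stop("averaged table is missing columns: ", paste(miss, collapse = ", "))
  long <- rbind(
    data.frame(thickness_mm = wide$thickness_mm, power_mW = wide$power_mW,
               mode = wide$mode, ring = "A2", E = wide$E_A2,
               stringsAsFactors = FALSE),
    data.frame(thickness_mm = wide$thickness_mm, power_mW = wide$power_mW,
               mode = wide$mode, ring = "A3", E = wide$E_A3,
               stringsAsFactors = FALSE))
  long
}

thickness_fits_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    p <- f$params
    data.frame(ring = f$ring, mode = f$mode, power_mW = f$power_mW,
               m = unname(p["m"]), n = unname(p["n"]),
               a = unname(p["a"]), b = unname(p["b"]),
               r_squared = f$r_squared, n_points = f$n_points,
               n_excluded = f$n_excluded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

power_polynomials_table <- function(polys) {
  if (!length(polys))
    return(data.frame(name = character(), ring = character(),
                      mode = character(), degree = integer(),
                      c0 = numeric(), c1 = numeric(), c2 = numeric(),
                      c3 = numeric(), c4 = numeric(), c5 = numeric(),
                      c6 = numeric(), r_squared = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(polys, function(p) {
    c7 <- rep(NA_real_, 7L)
    c7[seq_along(p$coeffs)] <- p$coeffs
    data.frame(name = p$name, ring = p$ring, mode = p$mode,
               degree = p$degree, c0 = c7[1], c1 = c7[2], c2 = c7[3],
               c3 = c7[4], c4 = c7[5], c5 = c7[6], c6 = c7[7],
               r_squared = p$r_squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
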