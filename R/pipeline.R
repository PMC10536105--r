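#' Default pipeline configuration
#'
#' Returns the default run configuration as a nested list: a noiseless
#' synthetic study rendered from the packaged reference model, analyzed
#' with fixed batch radii and fitted with the standard degrees. Any YAML
#' config is merged over these defaults, so a user config only states what
#' differs.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "zonephot_run",
    manifest = NULL,            # set to analyze real captures instead
    generator = list(
      enabled = TRUE,
      render = TRUE,            # FALSE = model-level path (no images)
      gain = 1,
      noise_sd = 0,
      sites = 1L,
      captures = 1L,
      shape = c(480L, 640L),
      bit_depth = 16L,
      format = "pgm",
      write_images = FALSE,
      thickness_grid = list(transmitted = seq(0.8, 10, by = 0.2),
                            reflected = seq(0.1, 10, by = 0.1)),
      power_grid = reference_power_grid(),
      modes = c("transmitted", "reflected"),
      level_A1 = NULL,
      background = 2,
      geometry = list(center_rc = c(240, 320), R1_px = 30, R2_px = 90,
                      R3_px = 150)),
    zones = list(
      R1_px = 30, R2_px = 90, R3_px = 150,
      tau0 = 0.5, tau_step = 0.05, tau_min = 0.05,
      form_limits = c(0.8, 1.25),
      detect_center = FALSE,    # TRUE = per-frame ROI/symmetry detection
      exclude_occlusion = FALSE),
    regression = list(
      d_min = 0.7,
      degrees = list(m = 2L, n = 6L, a = 2L, b = 2L)))
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it (recursively) over [default_config].
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    override <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare `n` key as logical FALSE; restore the intended
    # degree-family name so `degrees: {m: 2, n: 6, ...}` works unquoted.
    dg <- override$regression$degrees
    if (!is.null(dg) && "FALSE" %in% names(dg)) {
      names(dg)[names(dg) == "FALSE"] <- "n"
      override$regression$degrees <- dg
    }
    cfg <- merge_config(cfg, override)
  }
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

# Hash of the analysis-relevant configuration: the output location does not
# change any result, so two runs into different directories share a hash.
config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}

#' Run the full photometry pipeline
#'
#' Executes generate (or ingest) -> zone analysis -> replicate averaging ->
#' two-stage regression as one reproducible run, writing every intermediate
#' table to the output directory. With `generator$render = FALSE` the model
#' illuminances feed the regression directly (no images are rendered); with
#' a `manifest` set and the generator disabled, real captures are analyzed
#' instead. All tables carry the configuration hash, and `config.json`
#' echoes the full configuration and seed.
#'
#' @param config configuration list (see [default_config]) or a YAML path.
#' @param seed optional override of `config$seed`.
#' @return Invisibly, a list with `averaged`, `thickness_fits`,
#'   `power_polynomials`, `config_hash`, `output_dir` (and `illuminance`
#'   when images were analyzed).
#' @export
run_pipeline <- function(config = default_config(), seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  hash <- config_hash(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(config = config, config_hash = hash),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  gen <- config$generator
  illum <- NULL
  if (isTRUE(gen$enabled) && !isTRUE(gen$render)) {
    fm <- forward_model(gain = gen$gain)
    averaged <- model_illuminance_table(fm, thickness_grid = gen$thickness_grid,
                                        power_grid = gen$power_grid,
                                        modes = gen$modes)
  } else {
    if (isTRUE(gen$enabled)) {
      fm <- forward_model(gain = gen$gain)
      study <- generate_study(fm, thickness_grid = gen$thickness_grid,
                              power_grid = gen$power_grid, modes = gen$modes,
                              sites = gen$sites, captures = gen$captures,
                              noise_sd = gen$noise_sd, seed = config$seed,
                              shape = gen$shape, bit_depth = gen$bit_depth,
                              geometry = gen$geometry,
                              level_A1 = gen$level_A1,
                              background = gen$background)
      fs <- study$frameset
      if (isTRUE(gen$write_images))
        write_frameset(fs, file.path(out_dir, "frames"), format = gen$format)
    } else {
      if (is.null(config$manifest))
        stop("stage generate: neither generator nor manifest configured")
      fs <- load_frameset(config$manifest)
    }
    zc <- config$zones
    geometry <- if (isTRUE(zc$detect_center)) NULL
                else zone_geometry(config$generator$geometry$center_rc,
                                   zc$R1_px, zc$R2_px, zc$R3_px)
    illum <- analyze_frameset(fs, R1_px = zc$R1_px, R2_px = zc$R2_px,
                              R3_px = zc$R3_px, geometry = geometry,
                              tau0 = zc$tau0, tau_step = zc$tau_step,
                              tau_min = zc$tau_min,
                              form_limits = zc$form_limits)
    write_table(illum, file.path(out_dir, "illuminance.csv"), hash)
    averaged <- average_replicates(illum)
  }
  write_table(averaged, file.path(out_dir, "averaged.csv"), hash)
  reg <- run_regression(averaged, d_min = config$regression$d_min,
                        degrees = config$regression$degrees)
  write_table(reg$thickness_fits, file.path(out_dir, "thickness_fits.csv"),
              hash)
  write_table(reg$power_polynomials,
              file.path(out_dir, "power_polynomials.csv"), hash)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         n_conditions = nrow(averaged),
         n_thickness_fits = nrow(reg$thickness_fits),
         power_polynomials = reg$power_polynomials),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(list(illuminance = illum, averaged = averaged,
                 thickness_fits = reg$thickness_fits,
                 power_polynomials = reg$power_polynomials,
                 config_hash = hash, output_dir = out_dir))
}

write_table <- function(df, path, hash) {
  df$config_hash <- hash
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Compare fitted power polynomials with a reference table
#'
#' Matches fitted and reference polynomials by (name, ring) and reports
#' per-coefficient absolute and relative differences. A coefficient passes
#' when its relative error is within `rel_tol`, or -- for near-zero
#' reference coefficients, where relative error is ill-conditioned -- when
#' its absolute error is within `abs_tol`.
#'
#' @param fitted,reference data.frames with columns `name`, `ring`,
#'   `c0`..`c6` (e.g. [run_regression]'s `power_polynomials` and
#'   [reference_power_polynomials]).
#' @param rel_tol relative tolerance (default 0.001).
#' @param abs_tol absolute tolerance for near-zero coefficients (default
#'   1e-9).
#' @return List with `table` (one row per coefficient: key, fitted value,
#'   reference value, abs_diff, rel_diff, pass) and `pass`, the overall
#'   verdict.
#' @export
compare_to_reference <- function(fitted,
                                 reference = reference_power_polynomials(),
                                 rel_tol = 1e-3, abs_tol = 1e-9) {
  keyf <- paste(fitted$name, fitted$ring)
  keyr <- paste(reference$name, reference$ring)
  if (!setequal(keyf, keyr) || anyDuplicated(keyf) || anyDuplicated(keyr))
    stop("fitted and reference polynomial keys do not match: fitted {",
         paste(sort(keyf), collapse = ", "), "} vs reference {",
         paste(sort(keyr), collapse = ", "), "}")
  rows <- list()
  for (k in keyf) {
    fr <- fitted[keyf == k, ]
    rr <- reference[keyr == k, ]
    for (j in 0:6) {
      cn <- paste0("c", j)
      rv <- rr[[cn]]; fv <- fr[[cn]]
      if (is.na(rv) && (is.null(fv) || is.na(fv))) next
      ad <- abs(fv - rv)
      rd <- if (rv != 0) ad / abs(rv) else Inf
      rows[[length(rows) + 1L]] <- data.frame(
        name = fr$name, ring = fr$ring, coefficient = cn, fitted = fv,
        reference = rv, abs_diff = ad, rel_diff = rd,
        pass = (ad <= abs_tol) || (rd <= rel_tol),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, pass = all(tab$pass))
}
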