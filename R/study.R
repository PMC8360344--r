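# End-to-end study runners: configuration, validation, and the four
# canonical simulation studies (imaging-parameter sweep, spatial
# resolution, noise/filter comparison, letter phantom).

# transverse gradients the imaging studies are anchored on (T/m at the
# slice, FFL at scan centre)
STUDY_GRADIENTS <- c("10" = 2.08, "17" = 1.25, "20" = 1.01)

#' Study configuration
#'
#' Assembles a validated configuration for [run_study()].  Presets
#' encode the four canonical studies; every block can be overridden.
#'
#' @param study One of "params" (shift/rotation sweep, 7 mm dots, FOV
#'   4 x 4 cm), "resolution" (2/3/4/5 mm separations at slice heights
#'   10/17/20 mm, FOV 2 x 2 cm), "noise" (7 mm dots at 10 mm;
#'   hann/cosine/shepp-logan filters at -60/-40/-20/-10 dB), "umb"
#'   (block-letter phantom, FOV 4 x 4 cm).
#' @param seed Integer seed for stochastic stages (noise injection).
#' @param ... Named overrides merged into the preset blocks, e.g.
#'   `protocol = list(n_shifts = 41)`, `recon = list(grid_n = 101)`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(study = c("resolution", "params", "noise",
                                   "umb"),
                         seed = 1L, ...) {
  study <- match.arg(study)
  base <- list(
    study = study,
    seed = as.integer(seed),
    geometry = list(),               # scanner_geometry() arguments
    protocol = list(n_shifts = 81L, n_rotations = 54L, f_drive = 25e3,
                    drive_amplitude = 5e-3, samples_per_period = 64L,
                    harmonic = 3L),
    phantom = list(concentration = 5, dot_size = 1e-3,
                   pixel_size = 0.25e-3),
    recon = list(filter = "hann", grid_n = 201L),
    metrics = list(signal_radius = 0.005, border_frac = 0.1),
    gradients = STUDY_GRADIENTS
  )
  preset <- switch(study,
    params = list(
      phantom = list(kind = "two_dot", separation = 7e-3, fov = 0.04),
      protocol = list(fov = 0.04, slice_height = 0.010),
      sweep = list(n_shifts = c(21L, 41L, 81L),
                   n_rotations = c(18L, 36L, 54L))
    ),
    resolution = list(
      phantom = list(kind = "two_dot", fov = 0.02),
      protocol = list(fov = 0.02),
      sweep = list(separation = c(2e-3, 3e-3, 4e-3, 5e-3),
                   slice_height = c(0.010, 0.017, 0.020))
    ),
    noise = list(
      phantom = list(kind = "two_dot", separation = 7e-3, fov = 0.02),
      protocol = list(fov = 0.02, slice_height = 0.010),
      sweep = list(filter = c("hann", "cosine", "shepp-logan"),
                   noise_db = c(-60, -40, -20, -10))
    ),
    umb = list(
      phantom = list(kind = "letters", text = "UMB", fov = 0.04),
      protocol = list(fov = 0.04, slice_height = 0.010),
      sweep = list()
    )
  )
  cfg <- utils::modifyList(base, preset)
  cfg <- utils::modifyList(cfg, list(...))
  cfg <- structure(cfg, class = "study_config")
  issues <- validate_config(cfg)
  if (length(issues) > 0)
    stop("study_config: invalid configuration:\n  ",
         paste(issues, collapse = "\n  "))
  cfg
}

#' Validate a study configuration
#'
#' Schema and physical-range checks.  Returns a character vector of
#' violations, empty when the configuration is valid.
#'
#' @param config A [study_config()].
#' @param cal Optional `ffl_calibration`; when given, the slice height
#'   is checked against the calibrated z range.
#' @export
validate_config <- function(config, cal = NULL) {
  issues <- character(0)
  need <- c("study", "seed", "geometry", "protocol", "phantom", "recon",
            "metrics")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0)
    return(paste("missing block:", missing))
  p <- config$protocol
  if (!is.null(p$fov) && p$fov <= 0)
    issues <- c(issues, "protocol$fov must be positive")
  if (!is.null(p$n_shifts) && p$n_shifts < 2)
    issues <- c(issues, "protocol$n_shifts must be >= 2")
  if (!is.null(p$n_rotations) && p$n_rotations < 1)
    issues <- c(issues, "protocol$n_rotations must be >= 1")
  if (!is.null(p$drive_amplitude) && p$drive_amplitude <= 0)
    issues <- c(issues, "protocol$drive_amplitude must be positive")
  if (!is.null(config$phantom$fov) && config$phantom$fov <= 0)
    issues <- c(issues, "phantom$fov must be positive")
  if (!is.null(config$phantom$separation) &&
      config$phantom$separation < 0)
    issues <- c(issues, "phantom$separation must be >= 0")
  if (!is.null(config$recon$filter) &&
      !config$recon$filter %in% c("hann", "cosine", "shepp-logan",
                                  "ram-lak"))
    issues <- c(issues, "recon$filter must be one of hann, cosine, ",
                "shepp-logan, ram-lak")
  if (!is.null(cal)) {
    zs <- p$slice_height
    if (!is.null(config$sweep$slice_height))
      zs <- config$sweep$slice_height
    bad <- zs[zs < cal$z_range[1] | zs > cal$z_range[2]]
    if (length(bad) > 0)
      issues <- c(issues, paste("slice height", bad,
                                "m outside the calibrated z range"))
  }
  issues
}

study_phantom <- function(config, fov) {
  ph <- config$phantom
  switch(ph$kind %||% "two_dot",
    two_dot = two_dot_phantom(ph$separation, ph$dot_size,
                              ph$concentration, fov, ph$pixel_size),
    letters = letters_phantom(ph$text %||% "UMB", ph$concentration,
                              fov, ph$pixel_size),
    disc = disc_phantom(ph$radius, c(0, 0), ph$concentration, fov,
                        ph$pixel_size),
    stop("study_phantom: unknown phantom kind ", ph$kind)
  )
}

study_protocol <- function(config, geom, cal, slice_height = NULL,
                           n_shifts = NULL, n_rotations = NULL) {
  p <- config$protocol
  z <- slice_height %||% p$slice_height
  I0 <- p$I0 %||% {
    G <- config$gradients[[as.character(round(z * 1000))]]
    if (is.null(G))
      stop("study_protocol: no anchor gradient for z = ", z,
           " m; set protocol$I0 explicitly")
    i0_for_gradient(geom, cal, z, G)
  }
  scan_protocol(
    fov = p$fov, n_shifts = n_shifts %||% p$n_shifts,
    n_rotations = n_rotations %||% p$n_rotations,
    f_drive = p$f_drive, drive_amplitude = p$drive_amplitude,
    slice_height = z, I0 = I0,
    samples_per_period = p$samples_per_period,
    harmonic = p$harmonic)
}

#' Run a simulation study end to end
#'
#' Builds the phantom(s), acquires sinograms through the calibrated
#' trajectory correction, reconstructs with filtered backprojection,
#' and evaluates contrast (and SNR for the noise study).  Deterministic
#' given the configuration seed.
#'
#' @param config A [study_config()].
#' @param geom A [scanner_geometry()]; built from the config's geometry
#'   block when NULL.
#' @param cal An `ffl_calibration`; computed when NULL (slow).
#' @param particle A [particle_model()].
#' @param output_dir Optional directory; when given, sinograms, images
#'   (CSV), metrics (CSV) and a log are written there.
#' @return A list of class `study_result`: `metrics` (tibble), `images`,
#'   `sinograms` (named lists), `config`.
#' @export
run_study <- function(config, geom = NULL, cal = NULL,
                      particle = particle_model(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  geom <- geom %||% do.call(scanner_geometry, config$geometry)
  cal <- cal %||% calibrate_trajectory(geom)
  issues <- validate_config(config, cal)
  if (length(issues) > 0)
    stop("run_study: ", paste(issues, collapse = "; "))
  log <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log <<- c(log, msg)
    message(msg)
  }
  images <- list(); sinograms <- list(); rows <- list()
  add_case <- function(id, sino, img, row) {
    sinograms[[id]] <<- sino; images[[id]] <<- img
    rows[[id]] <<- row
  }
  filter <- config$recon$filter
  grid_n <- config$recon$grid_n

  if (config$study == "resolution") {
    sw <- config$sweep
    for (z in sw$slice_height) {
      prot <- study_protocol(config, geom, cal, slice_height = z)
      for (sep in sw$separation) {
        cfg <- config; cfg$phantom$separation <- sep
        ph <- study_phantom(cfg, config$phantom$fov)
        say("resolution: z = ", z * 1000, " mm, separation = ",
            sep * 1000, " mm")
        sino <- acquire_sinogram(ph, geom, prot, cal, particle)
        img <- fbp(sino, filter, grid_n)
        ctr <- dot_contrast(img, c(-sep / 2, 0), c(sep / 2, 0))
        id <- sprintf("z%02.0f_sep%1.0f", z * 1000, sep * 1000)
        add_case(id, sino, img, tibble::tibble(
          study = "resolution", id = id, slice_height = z,
          separation = sep, filter = filter, noise_db = -Inf,
          C = ctr$C, resolved = ctr$resolved, snr = NA_real_))
      }
    }
  } else if (config$study == "params") {
    ph <- study_phantom(config, config$phantom$fov)
    sep <- config$phantom$separation
    for (ns in config$sweep$n_shifts)
      for (nr in config$sweep$n_rotations) {
        prot <- study_protocol(config, geom, cal, n_shifts = ns,
                               n_rotations = nr)
        say("params: ", ns, " shifts x ", nr, " rotations")
        sino <- acquire_sinogram(ph, geom, prot, cal, particle)
        img <- fbp(sino, filter, grid_n)
        ctr <- dot_contrast(img, c(-sep / 2, 0), c(sep / 2, 0))
        id <- sprintf("s%02d_r%02d", ns, nr)
        add_case(id, sino, img, tibble::tibble(
          study = "params", id = id,
          n_shifts = ns, n_rotations = nr,
          separation = sep, filter = filter,
          C = ctr$C, resolved = ctr$resolved))
      }
  } else if (config$study == "noise") {
    ph <- study_phantom(config, config$phantom$fov)
    sep <- config$phantom$separation
    prot <- study_protocol(config, geom, cal)
    say("noise: acquiring noiseless sinogram")
    sino0 <- acquire_sinogram(ph, geom, prot, cal, particle)
    centers <- list(c(-sep / 2, 0), c(sep / 2, 0))
    k <- 0L
    for (flt in config$sweep$filter)
      for (db in config$sweep$noise_db) {
        k <- k + 1L
        sino <- add_noise(sino0, db, seed = config$seed + k)
        img <- fbp(sino, flt, grid_n)
        ctr <- dot_contrast(img, centers[[1]], centers[[2]])
        snr <- image_snr(img, centers, config$metrics$signal_radius,
                         config$metrics$border_frac)
        say("noise: ", flt, " at ", db, " dB: SNR = ", signif(snr, 3))
        id <- sprintf("%s_%03.0fdB", flt, -db)
        add_case(id, sino, img, tibble::tibble(
          study = "noise", id = id, slice_height = prot$slice_height,
          separation = sep, filter = flt, noise_db = db,
          C = ctr$C, resolved = ctr$resolved, snr = snr))
      }
  } else if (config$study == "umb") {
    ph <- study_phantom(config, config$phantom$fov)
    prot <- study_protocol(config, geom, cal)
    say("umb: acquiring ", prot$n_rotations, " x ", prot$n_shifts,
        " sinogram")
    sino <- acquire_sinogram(ph, geom, prot, cal, particle)
    img <- fbp(sino, filter, grid_n)
    add_case("umb", sino, img, tibble::tibble(
      study = "umb", id = "umb", slice_height = prot$slice_height,
      filter = filter, peak = max(img$values)))
  }

  metrics <- dplyr::bind_rows(rows)
  result <- structure(list(metrics = metrics, images = images,
                           sinograms = sinograms, config = config,
                           log = log),
                      class = "study_result")
  if (!is.null(output_dir)) write_study(result, output_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> '", x$config$study, "': ", nrow(x$metrics),
      " cases\n", sep = "")
  print(x$metrics)
  invisible(x)
}

write_study <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics,
                   file.path(output_dir, "metrics.csv"),
                   row.names = FALSE)
  for (id in names(result$sinograms))
    write_sinogram(result$sinograms[[id]],
                   file.path(output_dir, paste0("sinogram_", id,
                                                ".csv")))
  for (id in names(result$images))
    utils::write.table(result$images[[id]]$values,
                       file.path(output_dir, paste0("image_", id,
                                                    ".tsv")),
                       sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  writeLines(result$log, file.path(output_dir, "run.log"))
  invisible(output_dir)
}
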