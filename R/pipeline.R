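## Run configuration, the end-to-end pipeline driver, and plotting.

.stageError <- function(stage, msg)
  stop(errorCondition(sprintf("[%s] %s", stage, msg),
                      class = c("phreshStageError", "error"),
                      stage = stage))

.withStage <- function(stage, expr)
  withCallingHandlers(expr, error = function(e) {
    if (!inherits(e, "phreshStageError")) .stageError(stage, conditionMessage(e))
  })

#' Default run configuration
#'
#' A fully serializable configuration describing one reproducible run:
#' the recipe, seeds, cohort sizes, geometry / optics / noise settings
#' and the comparisons to test. All fields can be overridden from a
#' YAML file ([readPhreshConfig()]).
#'
#' @param recipe `"fig_notch_timecourse"` (Notch-inhibition timecourse),
#'   `"fig_gli1_rescue"` (ectopic Gli1 rescue) or `"map"`
#'   (spatiotemporal PHRESH map).
#' @param seed master seed.
#' @param ... named overrides of any default field.
#' @return a config list of class `phreshConfig`.
#' @export
phreshConfig <- function(recipe = "fig_notch_timecourse", seed = 1L, ...) {
  cfg <- list(
    recipe = recipe, seed = as.integer(seed),
    n_embryos = 8L, n_sections = 8L,
    timepoints = c(1, 2), markers = c("ptc2", "sox2"),
    drug_start = 20, duration = 10, heatshock_time = 20,
    cell_spacing = 2.5, amplitude = 50, embryo_sigma = 0.03, brightness_sigma = 0.10,
    geometry = list(dv_height = 50, ml_width = 20, ap_length = 250,
                    canal_dv_frac = 0.3, canal_ml_frac = 0.5,
                    somite_length = 50, cell_diameter = 5),
    optics = list(voxel_size = c(1, 1, 1), psf_sigma = c(1, 1, 1),
                  background_offset = 5),
    noise = list(photon_gain = 50, read_noise_sigma = 2),
    map = list(t0_grid = c(24, 36, 48, 60, 72), pathway = "hh",
               n_embryos = 1L, cell_spacing = 5, dt = 0.1),
    comparisons = NULL, out_dir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("phreshConfig", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [phreshConfig()]; everything else keeps its default, so a minimal
#' file stating only `recipe` and `seed` is a valid full configuration.
#'
#' @param path YAML file.
#' @return a config list of class `phreshConfig`.
#' @export
readPhreshConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(phreshConfig(), raw)
  class(cfg) <- c("phreshConfig", "list")
  cfg
}

.configGeometry <- function(cfg) {
  g <- cfg$geometry
  SpinalCordGeometry(dvHeight = g$dv_height, mlWidth = g$ml_width,
                     apLength = g$ap_length,
                     canalDvFrac = g$canal_dv_frac,
                     canalMlFrac = g$canal_ml_frac,
                     somiteLength = g$somite_length,
                     cellDiameter = g$cell_diameter)
}

.configOptics <- function(cfg)
  OpticsModel(voxelSize = as.numeric(cfg$optics$voxel_size),
              psfSigma = as.numeric(cfg$optics$psf_sigma),
              backgroundOffset = cfg$optics$background_offset)

.configNoise <- function(cfg)
  NoiseModel(photonGain = cfg$noise$photon_gain,
             readNoiseSigma = cfg$noise$read_noise_sigma,
             seed = cfg$seed)

## Hash of the scientific configuration; output locations are excluded
## so the same experiment hashes identically wherever it is written.
.configHash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.validateConfig <- function(cfg) {
  known <- c("fig_notch_timecourse", "fig_gli1_rescue", "map")
  if (is.null(cfg$recipe) || !cfg$recipe %in% known)
    .stageError("config", sprintf("unknown recipe '%s'", cfg$recipe))
  condNames <- switch(cfg$recipe,
    fig_notch_timecourse = c("DMSO",
      sprintf("LY411575_%gh", cfg$timepoints)),
    fig_gli1_rescue = c("DMSO", "Gli1_DMSO", "Gli1_LY411575"),
    map = character(0))
  for (cmp in cfg$comparisons) {
    bad <- setdiff(unlist(cmp[c("a", "b")]), condNames)
    if (length(bad))
      .stageError("config", sprintf(
        "comparison references unknown condition(s): %s",
        paste(bad, collapse = ", ")))
  }
  invisible(condNames)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> render -> quantify -> compare for the configured
#' recipe, logs progress to stderr, and (when `out_dir` is set) writes a
#' tidy per-embryo CSV and a machine-readable results JSON recording
#' the config hash and seed. Results depend only on the configuration:
#' the same config yields byte-identical JSON.
#'
#' @param config a config list from [phreshConfig()] /
#'   [readPhreshConfig()].
#' @param quiet suppress progress messages.
#' @return the report bundle (list), invisibly when written to disk.
#' @export
runPipeline <- function(config = phreshConfig(), quiet = FALSE) {
  log <- function(...) if (!quiet) message("[phresh] ", sprintf(...))
  condNames <- .validateConfig(config)
  hash <- .configHash(config)
  log("recipe %s, seed %d, config %s", config$recipe, config$seed, hash)

  geometry <- .configGeometry(config)
  optics <- .configOptics(config)
  noise <- .configNoise(config)

  results <- list(recipe = config$recipe, seed = config$seed,
                  config_hash = hash)
  bundle <- NULL
  if (config$recipe == "fig_notch_timecourse") {
    bundle <- .withStage("simulate", notchInhibitionTimecourse(
      timepoints = config$timepoints, markers = config$markers,
      drugStart = config$drug_start, nEmbryos = config$n_embryos,
      nSections = config$n_sections, seed = config$seed,
      geometry = geometry, optics = optics, noise = noise,
      cellSpacing = config$cell_spacing, amplitude = config$amplitude,
      embryoSigma = config$embryo_sigma,
      brightnessSigma = config$brightness_sigma))
    red <- bundle$reductions
    results$reductions <- red
    log("reductions: %s", paste(sprintf("%s %gh: %.1f%%", red$marker,
        red$timepoint_h, red$reduction_pct), collapse = "; "))
  } else if (config$recipe == "fig_gli1_rescue") {
    bundle <- .withStage("simulate", gli1RescueExperiment(
      duration = config$duration, heatshockTime = config$heatshock_time,
      nEmbryos = config$n_embryos, nSections = config$n_sections,
      seed = config$seed, geometry = geometry, optics = optics,
      noise = noise, cellSpacing = config$cell_spacing,
      amplitude = config$amplitude, embryoSigma = config$embryo_sigma,
      brightnessSigma = config$brightness_sigma))
    results$enlargement_pct <- bundle$enlargementPct
    results$rescue_normalized_mean <- bundle$rescueNormalizedMean
    log("olig2 enlargement %.1f%%; rescue %.1f%% of control max",
        bundle$enlargementPct, bundle$rescueNormalizedMean)
  } else {
    m <- config$map
    cohort <- .withStage("simulate", {
      cs <- lapply(m$t0_grid, function(t0)
        lapply(seq_len(m$n_embryos), function(e)
          simulatePhreshStack(t0, pathway = m$pathway,
            geometry = geometry, optics = optics, noise = noise,
            cellSpacing = m$cell_spacing,
            seed = .subSeed(config$seed, match(t0, m$t0_grid), e),
            dt = m$dt)))
      names(cs) <- m$t0_grid
      cs
    })
    bundle <- .withStage("quantify", list(map = buildMap(cohort)))
    results$class_fractions <- as.data.frame(bundle$map@classFractions)
    results$class_fractions$t0 <- bundle$map@t0
  }

  if (!is.null(bundle$normalized) && length(config$comparisons)) {
    results$comparisons <- .withStage("compare", {
      lapply(config$comparisons, function(cmp) {
        norm <- bundle$normalized
        sel <- if (!is.null(cmp$marker))
          norm[norm$marker == cmp$marker, ] else norm
        va <- sel$pct_normalized[sel$condition == cmp$a]
        vb <- sel$pct_normalized[sel$condition == cmp$b]
        if (length(va) == 0 || length(vb) == 0)
          .stageError("compare", sprintf("empty group in %s vs %s",
                                         cmp$a, cmp$b))
        mw <- mannWhitneyU(va, vb)
        list(a = cmp$a, b = cmp$b, marker = cmp$marker, U = mw$U,
             p = mw$p, method = mw$method, stars = mw$stars)
      })
    })
  }
  if (!is.null(bundle$normalized)) {
    groups <- split(bundle$normalized$pct_normalized,
                    paste(bundle$normalized$marker,
                          bundle$normalized$condition, sep = ":"))
    results$group_summary <- summarizeGroups(groups)
  }

  if (!is.null(config$out_dir)) {
    .withStage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!is.null(bundle$normalized))
        writeDomainsCsv(bundle$normalized,
                        file.path(config$out_dir, "domains.csv"))
      jsonlite::write_json(results,
                           file.path(config$out_dir, "results.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      log("wrote %s", file.path(config$out_dir, "results.json"))
    })
  }
  bundle$results <- results
  if (is.null(config$out_dir)) bundle else invisible(bundle)
}

#' Plot an intensity profile
#'
#' Line plot of a DV or ML profile in the conventional orientation:
#' position as a fraction of the axis, intensity as % of the
#' unconverted-region green maximum on a 0-50% axis by default, with
#' the canal position dashed.
#'
#' @param profile an [IntensityProfile-class].
#' @param ylim intensity axis limits (%).
#' @param ... passed to [graphics::plot()].
#' @return the profile, invisibly.
#' @export
plotProfile <- function(profile, ylim = c(0, 50), ...) {
  stopifnot(is(profile, "IntensityProfile"))
  graphics::plot(profilePositions(profile), profileValues(profile),
                 type = "l", lwd = 2, col = "#1b7837", ylim = ylim,
                 xlab = sprintf("%s position (fraction)", profile@axis),
                 ylab = "Kaede-green (% of unconverted max)", ...)
  if (is.finite(profile@canalFrac))
    graphics::abline(v = profile@canalFrac, lty = 2, col = "grey40")
  invisible(profile)
}
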