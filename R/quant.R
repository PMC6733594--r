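## The PHRESH measurement chain: unconverted-reference normalization,
## DV/ML intensity profiles, response-state classification, and the
## spatiotemporal signalling map.

## Modal intensity of a vector of counts (integer-rounded histogram mode);
## the stack background estimate used before normalization.
.modalIntensity <- function(x) {
  r <- round(x)
  tab <- tabulate(r - min(r) + 1)
  (which.max(tab) + min(r) - 1)
}

#' Unconverted-region reference intensity
#'
#' The green-channel normalization reference: the maximum (or a robust
#' high percentile, the default, to resist hot pixels) of the
#' background-subtracted green intensity over voxels whose AP position
#' lies outside the converted window. Dividing profile intensities by
#' this reference removes transgene-expression and exposure differences
#' between embryos.
#'
#' @param stack a [KaedeStack-class] with a recorded converted AP window.
#' @param statistic `"percentile"` (default) or `"max"`.
#' @param prob percentile used in `"percentile"` mode.
#' @param background background counts to subtract; defaults to the
#'   modal green intensity of the stack.
#' @return list with `reference` (counts, > 0) and `background` (counts).
#' @export
unconvertedReference <- function(stack, statistic = c("percentile", "max"),
                                 prob = 0.999, background = NULL) {
  stopifnot(is(stack, "KaedeStack"))
  statistic <- match.arg(statistic)
  green <- stackData(stack, "green")
  d <- dim(green)
  apCentre <- (seq_len(d[3]) - 0.5) * stack@voxelSize[3]
  w <- stack@convertedApWindow
  outside <- if (length(w) == 2) apCentre < w[1] | apCentre > w[2] else
    rep(TRUE, d[3])
  if (!any(outside))
    stop("converted window covers the full AP extent: no unconverted reference region")
  if (is.null(background)) background <- .modalIntensity(green)
  vals <- green[, , outside] - background
  ref <- if (statistic == "max") max(vals) else
    as.numeric(quantile(vals, prob, names = FALSE))
  if (ref <= 0) stop("unconverted reference intensity is not positive")
  list(reference = ref, background = background)
}

.resampleProfile <- function(frac, values, grid) {
  approx(frac, values, xout = grid, rule = 2)$y
}

#' Dorsoventral intensity profile through the canal
#'
#' Averages `nLines` vertical traces drawn through (and flanking) the
#' spinal canal, normalizes them to the unconverted-region reference,
#' and resamples onto a common fractional grid (0 = ventral edge,
#' 1 = dorsal edge of the traced rows) so profiles from different
#' embryos can be averaged.
#'
#' @param section `[Y = DV, Z = ML]` matrix of green counts.
#' @param canal `c(y, z)` voxel indices of the canal (see
#'   [canalPosition()]).
#' @param reference reference counts (> 0) from
#'   [unconvertedReference()].
#' @param nLines number of traces (default 3: the canal column plus one
#'   flanking column each side).
#' @param lineSpacing spacing between traces, um (default one cell
#'   diameter).
#' @param voxelSize um per voxel in the section plane.
#' @param rows DV voxel rows to trace (default: all rows); pass the cord
#'   rows to profile the cord only.
#' @param background background counts subtracted before normalization.
#' @param gridStep fractional resampling step (default 0.01, a 101-point
#'   grid).
#' @return an [IntensityProfile-class] (values in % of the reference).
#' @export
dvProfile <- function(section, canal, reference, nLines = 3,
                      lineSpacing = 5, voxelSize = 1, rows = NULL,
                      background = 0, gridStep = 0.01) {
  if (!is.matrix(section)) stop("'section' must be a [DV, ML] matrix")
  if (reference <= 0) stop("'reference' must be > 0")
  if (length(canal) != 2 || canal[1] < 1 || canal[1] > nrow(section) ||
      canal[2] < 1 || canal[2] > ncol(section))
    stop("canal position lies outside the section")
  if (is.null(rows)) rows <- seq_len(nrow(section))
  spacingVox <- max(1, round(lineSpacing / voxelSize))
  offsets <- spacingVox * (seq_len(nLines) - (nLines + 1) / 2)
  cols <- round(canal[2] + offsets)
  if (any(cols < 1 | cols > ncol(section)))
    stop("trace columns fall outside the section")
  trace <- rowMeans(section[rows, cols, drop = FALSE]) - background
  vals <- pmax(trace, 0) / reference * 100
  frac <- (seq_along(rows) - 1) / max(1, length(rows) - 1)
  grid <- seq(0, 1, by = gridStep)
  IntensityProfile("DV", grid, .resampleProfile(frac, vals, grid),
                   canalFrac = (which.min(abs(rows - canal[1])) - 1) /
                     max(1, length(rows) - 1),
                   nLines = nLines, nSomites = 1L)
}

#' Mediolateral intensity profile dorsal to the canal
#'
#' A single horizontal trace drawn directly dorsal to the spinal canal
#' (offset `dorsalOffset` um), normalized and resampled as in
#' [dvProfile()].
#'
#' @inheritParams dvProfile
#' @param dorsalOffset distance of the trace above the canal, um
#'   (default one cell diameter).
#' @param cols ML voxel columns to trace (default: all columns).
#' @return an [IntensityProfile-class].
#' @export
mlProfile <- function(section, canal, reference, dorsalOffset = 5,
                      voxelSize = 1, rows = NULL, cols = NULL,
                      background = 0, gridStep = 0.01) {
  if (!is.matrix(section)) stop("'section' must be a [DV, ML] matrix")
  if (reference <= 0) stop("'reference' must be > 0")
  if (length(canal) != 2 || canal[1] < 1 || canal[1] > nrow(section) ||
      canal[2] < 1 || canal[2] > ncol(section))
    stop("canal position lies outside the section")
  row <- round(canal[1] + dorsalOffset / voxelSize)
  if (is.null(rows)) rows <- seq_len(nrow(section))
  if (!(row %in% rows))
    stop("the dorsal offset places the trace outside the traced rows")
  if (is.null(cols)) cols <- seq_len(ncol(section))
  trace <- section[row, cols] - background
  vals <- pmax(trace, 0) / reference * 100
  frac <- (seq_along(cols) - 1) / max(1, length(cols) - 1)
  grid <- seq(0, 1, by = gridStep)
  IntensityProfile("ML", grid, .resampleProfile(frac, vals, grid),
                   canalFrac = (which.min(abs(cols - canal[2])) - 1) /
                     max(1, length(cols) - 1),
                   nLines = 1L, nSomites = 1L)
}

#' Average intensity profiles across somite sections
#'
#' Pointwise mean of profiles measured on one section per somite. All
#' profiles must share the axis and position grid; a count different
#' from `expectedN` (default 5 neighbouring somites) raises a warning,
#' not an error.
#'
#' @param profiles list of [IntensityProfile-class] objects.
#' @param expectedN expected number of somite sections.
#' @return an [IntensityProfile-class] with `nSomites` recorded.
#' @export
averageOverSomites <- function(profiles, expectedN = 5) {
  if (length(profiles) == 0) stop("no profiles to average")
  stopifnot(all(vapply(profiles, is, logical(1), "IntensityProfile")))
  ax <- unique(vapply(profiles, function(p) p@axis, character(1)))
  if (length(ax) != 1) stop("profiles mix DV and ML axes")
  pos <- profiles[[1]]@positions
  for (p in profiles[-1])
    if (length(p@positions) != length(pos) ||
        any(abs(p@positions - pos) > 1e-12))
      stop("profiles have mismatched position grids")
  if (length(profiles) != expectedN)
    warning(sprintf("averaging %d somite sections (expected %d)",
                    length(profiles), expectedN))
  vals <- rowMeans(vapply(profiles, profileValues,
                          numeric(length(pos))))
  IntensityProfile(ax, pos, vals, canalFrac = profiles[[1]]@canalFrac,
                   nLines = profiles[[1]]@nLines,
                   nSomites = length(profiles))
}

#' Classify signalling history from normalized channel intensities
#'
#' Reads the PHRESH colour code: green above threshold only = response
#' begun after conversion ("new"); red only = response ended before
#' conversion ("past"); both = response spanning the conversion
#' ("continued"); neither = "none". The four classes are exhaustive and
#' mutually exclusive.
#'
#' @param greenNorm,redNorm normalized intensities (% of the unconverted
#'   green reference); vectors are classified elementwise.
#' @param threshold presence threshold, % of reference (default 10).
#' @return factor with levels new / continued / past / none.
#' @examples
#' classifyResponse(c(50, 40, 1, 1), c(1, 40, 40, 1))
#' @export
classifyResponse <- function(greenNorm, redNorm, threshold = 10) {
  if (any(!is.finite(greenNorm)) || any(!is.finite(redNorm)) ||
      any(greenNorm < 0) || any(redNorm < 0))
    stop("normalized intensities must be finite and >= 0")
  g <- greenNorm > threshold
  r <- redNorm > threshold
  factor(ifelse(g & r, "continued",
         ifelse(g, "new", ifelse(r, "past", "none"))),
         levels = c("new", "continued", "past", "none"))
}

#' Fraction of the axis where a profile exceeds half its maximum
#'
#' @param profile an [IntensityProfile-class].
#' @return fraction of positions with value > max(value) / 2.
#' @export
aboveHalfMaxExtent <- function(profile) {
  stopifnot(is(profile, "IntensityProfile"))
  v <- profileValues(profile)
  mean(v > max(v) / 2)
}

## AP voxel indices of one section per somite, restricted to the
## converted window when one is recorded.
.somiteSectionIndices <- function(stack) {
  geometry <- stack@meta$geometry
  if (is.null(geometry)) stop("stack metadata lacks geometry")
  centres <- (seq_len(somiteCount(geometry)) - 0.5) * geometry@somiteLength
  w <- stack@convertedApWindow
  if (length(w) == 2) centres <- centres[centres >= w[1] & centres <= w[2]]
  if (length(centres) == 0) stop("no somite sections inside the converted window")
  pmin(pmax(round(centres / stack@voxelSize[3]), 1), dim(stack@data)[3])
}

## Averaged DV/ML profiles and class composition for one stack.
.quantifyStack <- function(stack, threshold = 10, statistic = "percentile") {
  geometry <- stack@meta$geometry
  ref <- unconvertedReference(stack, statistic = statistic)
  canal <- canalPosition(stack)
  mask <- cordSectionMask(stack)
  cordRows <- which(apply(mask, 1, any))
  cordCols <- which(apply(mask, 2, any))
  idx <- .somiteSectionIndices(stack)
  vox <- stack@voxelSize[2]
  dvs <- lapply(idx, function(i)
    dvProfile(transverseSection(stack, i, "green"), canal, ref$reference,
              lineSpacing = geometry@cellDiameter, voxelSize = vox,
              rows = cordRows, background = ref$background))
  mls <- lapply(idx, function(i)
    mlProfile(transverseSection(stack, i, "green"), canal, ref$reference,
              dorsalOffset = geometry@cellDiameter, voxelSize = vox,
              rows = cordRows, cols = cordCols,
              background = ref$background))
  nSomites <- length(idx)
  dvAvg <- averageOverSomites(dvs, expectedN = nSomites)
  mlAvg <- averageOverSomites(mls, expectedN = nSomites)

  ## class composition over cord voxels of the converted sections
  g <- stackData(stack, "green"); r <- stackData(stack, "red")
  gN <- pmax(g - ref$background, 0) / ref$reference * 100
  rN <- pmax(r - ref$background, 0) / ref$reference * 100
  sel <- array(FALSE, dim(g))
  for (i in idx) sel[, , i] <- t(mask)
  cls <- classifyResponse(gN[sel], rN[sel], threshold)
  frac <- as.numeric(table(cls) / length(cls))
  names(frac) <- levels(cls)
  list(dv = dvAvg, ml = mlAvg, classFractions = frac)
}

.meanProfiles <- function(profiles) {
  if (length(profiles) == 1) return(profiles[[1]])
  pos <- profiles[[1]]@positions
  vals <- rowMeans(vapply(profiles, profileValues, numeric(length(pos))))
  IntensityProfile(profiles[[1]]@axis, pos, vals,
                   canalFrac = profiles[[1]]@canalFrac,
                   nLines = profiles[[1]]@nLines,
                   nSomites = profiles[[1]]@nSomites)
}

#' Assemble a spatiotemporal signalling map
#'
#' Quantifies a cohort of stacks photoconverted on a grid of conversion
#' times: per stack, the averaged DV and ML profiles (three lines, one
#' section per somite) and the response-class composition of cord
#' voxels; per conversion time, the embryo average of each.
#'
#' @param cohort named list: names are conversion times (hpf), each
#'   element a [KaedeStack-class] or a list of stacks (one per embryo).
#' @param threshold classification threshold, % of reference.
#' @return a [SpatiotemporalMap-class].
#' @export
buildMap <- function(cohort, threshold = 10) {
  if (length(cohort) == 0) stop("empty cohort")
  t0 <- as.numeric(names(cohort))
  if (any(is.na(t0))) stop("cohort names must be conversion times in hpf")
  ord <- order(t0)
  t0 <- t0[ord]; cohort <- cohort[ord]
  dv <- ml <- vector("list", length(t0))
  cf <- matrix(0, length(t0), 4,
               dimnames = list(NULL, c("new", "continued", "past", "none")))
  for (i in seq_along(cohort)) {
    stacks <- cohort[[i]]
    if (is(stacks, "KaedeStack")) stacks <- list(stacks)
    if (length(stacks) == 0) stop("empty cohort entry")
    q <- lapply(stacks, .quantifyStack, threshold = threshold)
    dv[[i]] <- .meanProfiles(lapply(q, `[[`, "dv"))
    ml[[i]] <- .meanProfiles(lapply(q, `[[`, "ml"))
    cf[i, ] <- colMeans(do.call(rbind, lapply(q, `[[`, "classFractions")))
  }
  new("SpatiotemporalMap", t0 = t0, dvProfiles = dv, mlProfiles = ml,
      classFractions = cf)
}

#' Simulate one PHRESH embryo stack
#'
#' Convenience wrapper chaining [buildEmbryo()], [simulateReporter()]
#' and [renderStack()] for one conversion experiment: conversion at
#' `t0`, imaging `imagingInterval` hours later.
#'
#' @param t0 conversion time, hpf.
#' @param pathway `"notch"` or `"hh"`.
#' @param perturbation a [PerturbationSpec-class].
#' @param geometry a [SpinalCordGeometry-class].
#' @param schedule a [PhaseSchedule-class].
#' @param params a [ReporterParams-class].
#' @param optics an [OpticsModel-class].
#' @param noise a [NoiseModel-class]; its seed is combined with `seed`.
#' @param cellSpacing cell grid spacing, um.
#' @param imagingInterval hours between conversion and imaging.
#' @param apWindow converted AP window, um; default the central three
#'   somites.
#' @param seed integer seed for the population and the render.
#' @param dt integration step, hours.
#' @return a [KaedeStack-class] with timing recorded in `meta`.
#' @export
simulatePhreshStack <- function(t0, pathway = "hh",
                                perturbation = PerturbationSpec(),
                                geometry = SpinalCordGeometry(),
                                schedule = PhaseSchedule(),
                                params = ReporterParams(),
                                optics = OpticsModel(),
                                noise = NoiseModel(),
                                cellSpacing = 2.5,
                                imagingInterval = 6, apWindow = NULL,
                                seed = 1L, dt = 0.05) {
  if (is.null(apWindow)) {
    mid <- geometry@apLength / 2
    apWindow <- mid + c(-1.5, 1.5) * geometry@somiteLength
  }
  cells <- buildEmbryo(geometry, cellSpacing = cellSpacing, seed = seed)
  field <- activityField(pathway, perturbation, schedule, geometry)
  event <- ConversionEvent(t0 = t0, apWindow = apWindow)
  states <- simulateReporter(cells, field, event, tImage = t0 +
                               imagingInterval, params = params, dt = dt)
  noise@seed <- as.integer((noise@seed + 1000003 * seed) %% .Machine$integer.max)
  stack <- renderStack(states[, c("green", "red")], cells, geometry,
                       optics = optics, noise = noise,
                       convertedApWindow = apWindow)
  stack@meta$t0 <- t0
  stack@meta$tImage <- t0 + imagingInterval
  stack
}

#' Export profiles as tidy CSV
#'
#' @param profiles list of [IntensityProfile-class] (optionally named).
#' @param path output file.
#' @param t0,tImage optional timing columns, hpf.
#' @return the path, invisibly.
#' @export
writeProfilesCsv <- function(profiles, path, t0 = NA, tImage = NA) {
  if (is(profiles, "IntensityProfile")) profiles <- list(profiles)
  if (is.null(t0) || length(t0) == 0) t0 <- NA
  if (is.null(tImage) || length(tImage) == 0) tImage <- NA
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(axis = p@axis, position_frac = p@positions,
               value_pct = p@values, n_lines = p@nLines,
               n_somites = p@nSomites, t0_hpf = t0,
               t_image_hpf = tImage)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
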