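## Expression-domain morphometry on transverse sections: segmentation,
## area percentage of the spinal cord, per-embryo averaging,
## control-maximum normalization, and the cohort-level recipes for the
## Notch-inhibition timecourse and the ectopic-Gli1 rescue experiment.

#' Segment an expression domain within the spinal cord
#'
#' Thresholds a transverse section inside the cord mask. `"fixed"` keeps
#' pixels at or above `threshold`; `"otsu"` computes the Otsu threshold
#' from the histogram of in-cord pixels (via \pkg{EBImage}) -- a
#' stand-in for the interactive outlining used on real chromogenic
#' sections.
#'
#' @param section `[DV, ML]` numeric matrix.
#' @param cordMask logical matrix marking the spinal-cord cross-section.
#' @param method `"otsu"` (default), `"fixed"`, or `"mass"` -- a
#'   mass-conserving threshold for relative-expression images (values on
#'   a 0..1 scale, see [relativeExpression()]): the threshold is chosen
#'   so the segmented pixel count equals the total relative-expression
#'   mass inside the cord, which keeps the segmented area unbiased under
#'   the symmetric optical blur of a domain boundary.
#' @param threshold threshold counts, required for `"fixed"`.
#' @return logical domain mask, a subset of `cordMask`.
#' @export
segmentExpression <- function(section, cordMask,
                              method = c("otsu", "fixed", "mass"),
                              threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(section) || !is.logical(cordMask) ||
      !all(dim(section) == dim(cordMask)))
    stop("'section' and 'cordMask' must be matrices of equal dimension")
  if (!any(cordMask)) stop("'cordMask' is empty")
  if (method == "fixed") {
    if (is.null(threshold)) stop("'threshold' required for method = \"fixed\"")
    return(section >= threshold & cordMask)
  }
  vals <- section[cordMask]
  if (method == "mass") {
    k <- min(round(sum(pmax(vals, 0))), length(vals))
    if (k < 1) return(cordMask & FALSE)
    thr <- sort(vals, decreasing = TRUE)[k]
    return(section >= thr & cordMask)
  }
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(cordMask & FALSE)
  v <- (vals - lo) / (hi - lo)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(v, nrow = 1)),
                         range = c(0, 1))
  thr <- lo + thr01 * (hi - lo)
  section > thr & cordMask
}

## Light Gaussian smoothing of one section (sigma in pixels).
.smoothSection <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Relative expression of a marker against a counterstain
#'
#' Normalized-convolution readout of a marker channel: both the marker
#' section and a ubiquitous counterstain section are lightly smoothed
#' and background-subtracted, and their ratio is returned. On the
#' resulting 0..1 scale a fully expressing cell reads ~1 regardless of
#' local cell-packing texture or the intensity roll-off at the tissue
#' boundary, which makes domain areas segmentable without the biases
#' absolute intensity thresholds suffer at blurred edges.
#'
#' @param markerSection,counterSection `[DV, ML]` matrices (counts).
#' @param background background counts; estimated from the marker
#'   section's modal intensity when `NULL`.
#' @param smoothSigma Gaussian smoothing sigma, pixels.
#' @param floor relative values below this are set to 0 (suppresses
#'   shot-noise mass in non-expressing regions).
#' @return matrix of relative expression (>= 0, ~1 at full expression).
#' @export
relativeExpression <- function(markerSection, counterSection,
                               background = NULL, smoothSigma = 1,
                               floor = 0.1) {
  if (!is.matrix(markerSection) || !is.matrix(counterSection) ||
      !all(dim(markerSection) == dim(counterSection)))
    stop("marker and counterstain sections must have equal dimensions")
  if (is.null(background)) background <- .modalIntensity(markerSection)
  m <- pmax(.smoothSection(markerSection, smoothSigma) - background, 0)
  cs <- pmax(.smoothSection(counterSection, smoothSigma) - background,
             .Machine$double.eps)
  r <- m / cs
  r[r < floor] <- 0
  r
}

#' Expression-domain area as a percentage of the spinal cord
#'
#' @param domainMask logical domain mask; must be a subset of
#'   `cordMask`.
#' @param cordMask logical spinal-cord mask (non-empty).
#' @return a one-row `data.frame`: `area_domain`, `area_cord` (pixel
#'   counts) and `pct` (= 100 * area_domain / area_cord).
#' @examples
#' cord <- matrix(TRUE, 10, 10)
#' dom <- cord & row(cord) <= 2 & col(cord) <= 5
#' domainPercentage(dom, cord)  # 10 of 100 pixels -> 10%
#' @export
domainPercentage <- function(domainMask, cordMask) {
  if (!is.logical(domainMask) || !is.logical(cordMask) ||
      !all(dim(domainMask) == dim(cordMask)))
    stop("masks must be logical matrices of equal dimension")
  if (!any(cordMask)) stop("'cordMask' is empty")
  if (any(domainMask & !cordMask))
    stop("domain pixels found outside the cord mask")
  ad <- sum(domainMask); ac <- sum(cordMask)
  data.frame(area_domain = ad, area_cord = ac, pct = 100 * ad / ac)
}

#' Per-embryo summary of section measurements
#'
#' Arithmetic mean of the per-section domain percentages of one embryo.
#' The conventional design images 6-10 sections per embryo; other
#' counts raise a warning, not an error.
#'
#' @param measurements numeric vector of per-section percentages, or a
#'   `data.frame` with a `pct` column (e.g. rows from
#'   [domainPercentage()]).
#' @param embryoId identifier recorded in the summary.
#' @return a one-row `data.frame`: `embryo_id`, `n_sections`,
#'   `mean_pct`.
#' @export
summarizeEmbryo <- function(measurements, embryoId = NA) {
  pct <- if (is.data.frame(measurements)) measurements$pct else
    measurements
  if (length(pct) < 1 || any(!is.finite(pct)))
    stop("at least one finite measurement required")
  if (length(pct) < 6 || length(pct) > 10)
    warning(sprintf("%d sections for embryo %s (expected 6-10)",
                    length(pct), embryoId))
  data.frame(embryo_id = embryoId, n_sections = length(pct),
             mean_pct = mean(pct))
}

#' Normalize per-embryo values to the control maximum
#'
#' The mean of the control (DMSO) group is the "control maximum"; every
#' value is expressed as a percentage of it, so the normalized control
#' group has mean 100% exactly and different markers become directly
#' comparable. Normalized values may exceed 100.
#'
#' @param values per-embryo domain percentages to normalize.
#' @param controlValues per-embryo percentages of the control group.
#' @return a `data.frame`: `pct_raw`, `pct_normalized`, `control_max`.
#' @examples
#' normalizeToControlMax(c(40, 60), c(80, 80))
#' @export
normalizeToControlMax <- function(values, controlValues) {
  if (length(controlValues) == 0)
    stop("control group is empty")
  controlMax <- mean(controlValues)
  if (!is.finite(controlMax) || controlMax <= 0)
    stop("control group mean must be > 0")
  data.frame(pct_raw = values,
             pct_normalized = 100 * values / controlMax,
             control_max = controlMax)
}

#' Per-timepoint percent reduction versus control
#'
#' For each (marker, condition, timepoint) group of control-max
#' normalized per-embryo values, the reduction is 100 minus the group's
#' normalized mean. The paired marker table supports comparing when
#' different markers diverge (e.g. the Hh target falling before the
#' progenitor marker).
#'
#' @param normalized `data.frame` with columns `marker`, `condition`,
#'   `timepoint_h` and `pct_normalized` (one row per embryo).
#' @param control name of the control condition (excluded from the
#'   output; must be present).
#' @return `data.frame`: `marker`, `condition`, `timepoint_h`,
#'   `n`, `normalized_mean`, `reduction_pct`.
#' @export
timecourseReduction <- function(normalized, control = "DMSO") {
  need <- c("marker", "condition", "timepoint_h", "pct_normalized")
  if (!all(need %in% names(normalized)))
    stop("'normalized' must have columns ",
         paste(need, collapse = ", "))
  if (!control %in% normalized$condition)
    stop(sprintf("control group '%s' missing", control))
  treated <- normalized[normalized$condition != control, , drop = FALSE]
  if (nrow(treated) == 0) stop("no treated groups present")
  key <- interaction(treated$marker, treated$condition,
                     treated$timepoint_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(treated, key), function(g)
    data.frame(marker = g$marker[1], condition = g$condition[1],
               timepoint_h = g$timepoint_h[1], n = nrow(g),
               normalized_mean = mean(g$pct_normalized),
               reduction_pct = 100 - mean(g$pct_normalized))))
  rownames(out) <- NULL
  out[order(out$marker, out$timepoint_h), , drop = FALSE]
}

## ---- synthetic marker cohorts -------------------------------------------

## Soft edge weight: fraction of a cell of width `soft` (um) centred at
## distance `dist` (um, positive = inside) from a domain boundary that
## lies inside the domain. Anti-aliases domain edges that fall between
## cell rows so the painted band area matches the planted fraction.
.edgeWeight <- function(dist, soft) pmin(pmax(0.5 + dist / soft, 0), 1)

## Domain membership weight of cord cells for each marker's spatial
## motif: ptc2 a ventral-anchored band, sox2 a medial band, olig2 a
## thin band just above the floor plate; "counterstain" marks every
## cell of every tissue. Area fraction of the cord cross-section equals
## `fraction` for each marker motif. (Somite ptc2 expression is real
## but lives outside the cord outline the measurement uses, so the
## morphometry sections paint cord domains only.)
.markerDomainMembership <- function(cells, marker, fraction, geometry,
                                    soft) {
  if (marker == "counterstain") return(rep(1, nrow(cells)))
  isCord <- cells$tissue == "spinal_cord"
  w <- numeric(nrow(cells))
  dv <- cells$dv_frac[isCord]; ml <- cells$ml_frac[isCord]
  if (marker == "sox2") {
    w[isCord] <-
      .edgeWeight((ml - (0.5 - fraction / 2)) * geometry@mlWidth, soft) *
      .edgeWeight(((0.5 + fraction / 2) - ml) * geometry@mlWidth, soft)
  } else if (marker == "olig2") {
    base <- 0.08
    w[isCord] <-
      .edgeWeight((dv - base) * geometry@dvHeight, soft) *
      .edgeWeight((base + fraction - dv) * geometry@dvHeight, soft)
  } else {                                   # ptc2 and other ventral domains
    w[isCord] <- .edgeWeight((fraction - dv) * geometry@dvHeight, soft)
  }
  w
}

#' Paint marker expression onto a cell population
#'
#' Assigns in-situ-marker intensity (a.u.) to cells inside each
#' marker's ground-truth domain, modulated by the per-cell
#' heterogeneity factor. Cells straddling a domain boundary receive a
#' proportional amplitude so the painted area matches the planted
#' fraction independent of how the boundary falls on the cell grid.
#'
#' @param cells population from [buildEmbryo()].
#' @param markers character vector of marker names.
#' @param fractions domain fractions of cord area, one per marker.
#' @param amplitude expression amplitude, a.u.
#' @param geometry a [SpinalCordGeometry-class].
#' @param edgeSoftness width of the boundary anti-aliasing, um
#'   (typically the cell grid spacing).
#' @return numeric matrix (cells x markers).
#' @export
paintMarkers <- function(cells, markers, fractions, amplitude = 50,
                         geometry = SpinalCordGeometry(),
                         edgeSoftness = 2.5) {
  cells <- .asCells(cells)
  stopifnot(length(markers) == length(fractions))
  noise <- if ("noise_factor" %in% names(cells)) cells$noise_factor else 1
  m <- vapply(seq_along(markers), function(i)
    amplitude * noise * .markerDomainMembership(cells, markers[i],
                                                fractions[i], geometry,
                                                edgeSoftness),
    numeric(nrow(cells)))
  colnames(m) <- markers
  m
}

.subSeed <- function(seed, i, j = 0)
  as.integer((abs(seed) * 1009 + i * 7919 + j * 104729) %% 2147483629)

#' Simulate and measure a marker-expression cohort
#'
#' The full planted-truth pipeline: for every condition and embryo,
#' build a cell population, look up the ground-truth domain fraction of
#' each marker (modulated by an embryo-level lognormal factor), paint
#' marker intensity plus a ubiquitous counterstain, render a stack with
#' confocal optics and noise, reslice it, and on `nSections` transverse
#' sections segment the domain from the counterstain-referenced
#' relative-expression image ([relativeExpression()]) with the
#' mass-conserving threshold of [segmentExpression()], recording the
#' area percentage of the cord.
#'
#' @param conditions list of condition descriptors, each a list with
#'   `name`, `perturbation` (a [PerturbationSpec-class]) and
#'   `hoursSince` (hours since drug start / heat shock at fixation),
#'   and optionally `timepoint_h` (defaults to `hoursSince`).
#' @param markers marker names to measure.
#' @param nEmbryos embryos per condition.
#' @param nSections transverse sections measured per embryo.
#' @param seed master seed; every population, embryo factor and render
#'   derives its own stream from it.
#' @param geometry a [SpinalCordGeometry-class].
#' @param optics an [OpticsModel-class].
#' @param noise a [NoiseModel-class] (its seed slot is re-derived per
#'   embryo).
#' @param cellSpacing cell grid spacing, um.
#' @param amplitude marker expression amplitude, a.u.
#' @param embryoSigma sigma of the embryo-level lognormal factor on the
#'   domain fraction (domain extents are developmentally canalized, so
#'   this is small).
#' @param brightnessSigma sigma of the embryo-level lognormal factor on
#'   overall staining / exposure intensity, applied to every channel;
#'   the counterstain-referenced measurement cancels it -- it is the
#'   nuisance the control-maximum normalization exists for.
#' @return list with `sections` (tidy per-section `data.frame`) and
#'   `embryos` (per-embryo means: `condition`, `timepoint_h`, `marker`,
#'   `embryo_id`, `n_sections`, `mean_pct`).
#' @export
simulateMarkerCohort <- function(conditions, markers,
                                 nEmbryos = 8, nSections = 8, seed = 1L,
                                 geometry = SpinalCordGeometry(),
                                 optics = OpticsModel(),
                                 noise = NoiseModel(),
                                 cellSpacing = 2.5, amplitude = 50,
                                 embryoSigma = 0.03,
                                 brightnessSigma = 0.10) {
  secRows <- embRows <- list()
  layout <- embryoLayout(geometry)
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    tp <- if (!is.null(cond$timepoint_h)) cond$timepoint_h else
      cond$hoursSince
    truth <- vapply(markers, markerDomainTruth, numeric(1),
                    perturbation = cond$perturbation,
                    hoursSince = cond$hoursSince)
    for (e in seq_len(nEmbryos)) {
      sE <- .subSeed(seed, ci, e)
      cells <- buildEmbryo(geometry, cellSpacing = cellSpacing, seed = sE,
                           layout = layout)
      draws <- .withSeed(.subSeed(seed, ci, e + 1000), {
        list(size = exp(rnorm(length(markers), -embryoSigma^2 / 2,
                              embryoSigma)),
             bright = exp(rnorm(1, -brightnessSigma^2 / 2,
                                brightnessSigma)))
      })
      fracs <- pmin(pmax(truth * draws$size, 0), 1)
      states <- paintMarkers(cells, c(markers, "counterstain"),
                             c(fracs, 1), amplitude * draws$bright,
                             geometry, edgeSoftness = cellSpacing)
      noise@seed <- .subSeed(seed, ci, e + 2000)
      stack <- renderStack(states, cells, geometry, optics = optics,
                           noise = noise, layout = layout,
                           channels = c(markers, "counterstain"))
      mask <- cordSectionMask(stack)
      d <- dim(stack@data)
      apIdx <- unique(round(seq(0.1, 0.9, length.out = nSections) * d[3]))
      counter <- lapply(apIdx, function(i)
        transverseSection(stack, i, "counterstain"))
      for (mi in seq_along(markers)) {
        for (si in seq_along(apIdx)) {
          sec <- transverseSection(stack, apIdx[si], markers[mi])
          rel <- relativeExpression(sec, counter[[si]])
          dom <- segmentExpression(rel, mask, method = "mass")
          meas <- domainPercentage(dom, mask)
          secRows[[length(secRows) + 1]] <- data.frame(
            condition = cond$name, timepoint_h = tp, marker = markers[mi],
            embryo_id = e, section = si, pct = meas$pct)
        }
        pcts <- vapply(secRows[length(secRows) - seq_along(apIdx) + 1],
                       function(r) r$pct, numeric(1))
        embRows[[length(embRows) + 1]] <- data.frame(
          condition = cond$name, timepoint_h = tp, marker = markers[mi],
          embryo_id = e, n_sections = length(pcts), mean_pct = mean(pcts))
      }
    }
  }
  list(sections = do.call(rbind, secRows),
       embryos = do.call(rbind, embRows))
}

## Normalize per-embryo means of each marker to its control-group mean.
.normalizeCohort <- function(embryos, control = "DMSO") {
  out <- lapply(split(embryos, embryos$marker), function(g) {
    ctrl <- g$mean_pct[g$condition == control]
    if (length(ctrl) == 0)
      stop(sprintf("control group '%s' missing for marker %s", control,
                   g$marker[1]))
    nm <- normalizeToControlMax(g$mean_pct, ctrl)
    cbind(g, nm[, c("pct_normalized", "control_max")])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Notch-inhibition timecourse cohort
#'
#' Simulates the canonical divergence experiment: embryos treated with
#' the gamma-secretase inhibitor LY-411575 from 20 hpf for 1, 2 (or
#' more) hours versus DMSO controls, measured for the ptc2 (Hh target)
#' and sox2 (neural progenitor) expression domains by the full
#' render-segment-normalize pipeline, 8 embryos x 8 sections per
#' condition by default.
#'
#' @param timepoints treatment durations, hours.
#' @param markers markers to measure.
#' @param drugStart treatment start, hpf.
#' @param ... passed to [simulateMarkerCohort()] (`nEmbryos`,
#'   `nSections`, `seed`, `geometry`, `optics`, `noise`, ...).
#' @return list with `sections`, `embryos`, `normalized` (per-embryo
#'   control-max normalized values) and `reductions` (per marker and
#'   timepoint, from [timecourseReduction()]).
#' @export
notchInhibitionTimecourse <- function(timepoints = c(1, 2),
                                      markers = c("ptc2", "sox2"),
                                      drugStart = 20, ...) {
  conditions <- c(
    list(list(name = "DMSO", perturbation = PerturbationSpec(),
              hoursSince = 0, timepoint_h = 0)),
    lapply(timepoints, function(tp) list(
      name = sprintf("LY411575_%gh", tp),
      perturbation = PerturbationSpec(drug = "LY411575",
                                      drugStart = drugStart),
      hoursSince = tp, timepoint_h = tp)))
  res <- simulateMarkerCohort(conditions, markers, ...)
  norm <- .normalizeCohort(res$embryos, control = "DMSO")
  res$normalized <- norm
  res$reductions <- timecourseReduction(norm, control = "DMSO")
  res
}

#' Ectopic Gli1 activation and rescue cohort
#'
#' Simulates the epistasis experiment testing whether ectopic Gli1 can
#' restore Hh output in Notch-off spinal cords: wild-type DMSO
#' controls, heat-shock EGFP-Gli1 embryos in DMSO (expected olig2
#' domain enlargement), and heat-shock EGFP-Gli1 embryos treated with
#' LY-411575 (partial rescue), all fixed after `duration` hours and
#' measured for the olig2 domain.
#'
#' @param duration hours between heat shock / drug start and fixation.
#' @param heatshockTime heat-shock time, hpf.
#' @param ... passed to [simulateMarkerCohort()].
#' @return list with `sections`, `embryos`, `normalized`,
#'   `enlargementPct` (percent enlargement of the Gli1 DMSO group over
#'   wild-type control) and `rescueNormalizedMean` (Gli1 + LY-411575
#'   group as % of the wild-type control maximum).
#' @export
gli1RescueExperiment <- function(duration = 10, heatshockTime = 20, ...) {
  conditions <- list(
    list(name = "DMSO", perturbation = PerturbationSpec(),
         hoursSince = 0, timepoint_h = duration),
    list(name = "Gli1_DMSO",
         perturbation = PerturbationSpec(transgene = "EGFP_Gli1",
                                         heatshockTime = heatshockTime),
         hoursSince = duration, timepoint_h = duration),
    list(name = "Gli1_LY411575",
         perturbation = PerturbationSpec(drug = "LY411575",
                                         drugStart = heatshockTime,
                                         transgene = "EGFP_Gli1",
                                         heatshockTime = heatshockTime),
         hoursSince = duration, timepoint_h = duration))
  res <- simulateMarkerCohort(conditions, markers = "olig2", ...)
  norm <- .normalizeCohort(res$embryos, control = "DMSO")
  res$normalized <- norm
  groupMean <- function(cond)
    mean(norm$pct_normalized[norm$condition == cond])
  res$enlargementPct <- groupMean("Gli1_DMSO") - 100
  res$rescueNormalizedMean <- groupMean("Gli1_LY411575")
  res
}

#' Export domain measurements as tidy CSV
#'
#' @param embryos per-embryo `data.frame` (e.g. `$normalized` from a
#'   cohort recipe).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDomainsCsv <- function(embryos, path) {
  utils::write.csv(embryos, path, row.names = FALSE)
  invisible(path)
}
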