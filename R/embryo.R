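## Synthetic embryo: tissue layout, cell populations, and ground-truth
## Notch / Hedgehog activity fields over the three signalling phases.

#' Tissue layout of the simulated stack
#'
#' Maps the spinal-cord geometry onto absolute stack coordinates (um).
#' The cord is flanked by somite blocks along ML and sits on a thin
#' ventral vasculature strip; a small margin surrounds everything so the
#' rendered point-spread function does not clip at the stack edge.
#'
#' @param geometry a [SpinalCordGeometry-class].
#' @param somiteThickness ML thickness of each flanking somite block, um.
#' @param vasculatureHeight DV height of the ventral vasculature strip, um.
#' @param margin empty border around the tissues, um.
#' @return a list of named extents and offsets (um), including the stack
#'   size (`sizeMl`, `sizeDv`, `sizeAp`) and the cord origin
#'   (`cordMl0`, `cordDv0`).
#' @export
embryoLayout <- function(geometry, somiteThickness = 12,
                         vasculatureHeight = 6, margin = 2) {
  list(
    sizeMl = margin + somiteThickness + geometry@mlWidth +
      somiteThickness + margin,
    sizeDv = margin + vasculatureHeight + geometry@dvHeight + margin,
    sizeAp = geometry@apLength,
    cordMl0 = margin + somiteThickness,
    cordDv0 = margin + vasculatureHeight,
    somiteThickness = somiteThickness,
    vasculatureHeight = vasculatureHeight,
    margin = margin)
}

## Evaluate expr with a private, restored RNG stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.tileBlock <- function(x0, x1, y0, y1, z0, z1, spacing) {
  gx <- seq(x0 + spacing / 2, x1 - spacing / 4, by = spacing)
  gy <- seq(y0 + spacing / 2, y1 - spacing / 4, by = spacing)
  gz <- seq(z0 + spacing / 2, z1 - spacing / 4, by = spacing)
  expand.grid(ap_um = gx, dv_um = gy, ml_um = gz, KEEP.OUT.ATTRS = FALSE)
}

#' Build a synthetic cell population
#'
#' Tiles the spinal cord, the two flanking somite blocks and a ventral
#' vasculature strip with cells on a jittered grid. Each cell carries its
#' absolute position (um, stack frame), its position as a fraction of its
#' own tissue extent, and a seeded multiplicative lognormal activity factor
#' modelling cell-to-cell heterogeneity (occasional near-silent cells).
#'
#' @param geometry a [SpinalCordGeometry-class].
#' @param cellSpacing grid spacing between cell centres, um; must be
#'   positive and at most twice the cell diameter.
#' @param seed integer seed; populations are bit-identical for equal seeds.
#' @param layout a layout from [embryoLayout()] (defaults to the
#'   geometry's default layout).
#' @param heterogeneitySigma sigma of the lognormal per-cell activity
#'   factor (0 disables heterogeneity).
#' @return a `data.frame` with columns `id`, `tissue` (spinal_cord,
#'   somite, vasculature), `ap_um`, `dv_um`, `ml_um`, `dv_frac`,
#'   `ml_frac`, `noise_factor`.
#' @examples
#' cells <- buildEmbryo(SpinalCordGeometry(), cellSpacing = 5, seed = 1)
#' table(cells$tissue)
#' @export
buildEmbryo <- function(geometry, cellSpacing = 2.5, seed = 1L,
                        layout = embryoLayout(geometry),
                        heterogeneitySigma = 0.1) {
  stopifnot(is(geometry, "SpinalCordGeometry"))
  if (!is.numeric(cellSpacing) || length(cellSpacing) != 1 ||
      !is.finite(cellSpacing) || cellSpacing <= 0)
    stop("'cellSpacing' must be a single positive length in um")
  if (cellSpacing > 2 * geometry@cellDiameter)
    stop("'cellSpacing' must not exceed twice the cell diameter")

  L <- layout
  cord <- .tileBlock(0, L$sizeAp,
                     L$cordDv0, L$cordDv0 + geometry@dvHeight,
                     L$cordMl0, L$cordMl0 + geometry@mlWidth, cellSpacing)
  cord$tissue <- "spinal_cord"
  somL <- .tileBlock(0, L$sizeAp,
                     L$cordDv0, L$cordDv0 + geometry@dvHeight,
                     L$margin, L$margin + L$somiteThickness, cellSpacing)
  somR <- .tileBlock(0, L$sizeAp,
                     L$cordDv0, L$cordDv0 + geometry@dvHeight,
                     L$cordMl0 + geometry@mlWidth,
                     L$cordMl0 + geometry@mlWidth + L$somiteThickness,
                     cellSpacing)
  somL$tissue <- somR$tissue <- "somite"
  vasc <- .tileBlock(0, L$sizeAp,
                     L$margin, L$margin + L$vasculatureHeight,
                     L$cordMl0, L$cordMl0 + geometry@mlWidth, cellSpacing)
  vasc$tissue <- "vasculature"

  cells <- rbind(cord, somL, somR, vasc)
  n <- nrow(cells)
  cells <- .withSeed(seed, {
    jit <- cellSpacing * 0.15
    cells$ap_um <- cells$ap_um + runif(n, -jit, jit)
    cells$dv_um <- cells$dv_um + runif(n, -jit, jit)
    cells$ml_um <- cells$ml_um + runif(n, -jit, jit)
    cells$noise_factor <- if (heterogeneitySigma > 0)
      exp(rnorm(n, -heterogeneitySigma^2 / 2, heterogeneitySigma)) else
        rep(1, n)
    cells
  })
  ## clamp jitter inside the stack
  cells$ap_um <- pmin(pmax(cells$ap_um, 0), L$sizeAp)

  ## tissue-local fractional coordinates in [0, 1]
  dvFrac <- mlFrac <- numeric(n)
  isCord <- cells$tissue == "spinal_cord"
  isVasc <- cells$tissue == "vasculature"
  isSom <- cells$tissue == "somite"
  dvFrac[isCord] <- (cells$dv_um[isCord] - L$cordDv0) / geometry@dvHeight
  mlFrac[isCord] <- (cells$ml_um[isCord] - L$cordMl0) / geometry@mlWidth
  dvFrac[isSom] <- (cells$dv_um[isSom] - L$cordDv0) / geometry@dvHeight
  mlFrac[isSom] <- ifelse(cells$ml_um[isSom] < L$cordMl0,
    (cells$ml_um[isSom] - L$margin) / L$somiteThickness,
    (cells$ml_um[isSom] - L$cordMl0 - geometry@mlWidth) / L$somiteThickness)
  dvFrac[isVasc] <- (cells$dv_um[isVasc] - L$margin) / L$vasculatureHeight
  mlFrac[isVasc] <- (cells$ml_um[isVasc] - L$cordMl0) / geometry@mlWidth
  cells$dv_frac <- pmin(pmax(dvFrac, 0), 1)
  cells$ml_frac <- pmin(pmax(mlFrac, 0), 1)
  cells$id <- seq_len(n)
  rownames(cells) <- NULL
  cells[, c("id", "tissue", "ap_um", "dv_um", "ml_um",
            "dv_frac", "ml_frac", "noise_factor")]
}

## Phase envelope: 1 through activation + consolidation, linear ramp to 0
## across [rampStart, rampEnd] during termination, 0 outside.
.phaseEnvelope <- function(t, schedule, rampEnd) {
  if (t < schedule@activation[1]) return(0)
  rampStart <- schedule@termination[1]
  if (t < rampStart) return(1)
  max(0, 1 - (t - rampStart) / (rampEnd - rampStart))
}

## Spatial mask of the active region: whole cord during activation,
## shrinking linearly during consolidation to a medial band 1.5 cell
## diameters tall directly dorsal to the canal, which persists through
## termination. dvTop0 is the initial dorsal limit of the active region.
.activeRegionMask <- function(dvFrac, mlFrac, t, schedule, geometry,
                              dvTop0 = 1) {
  bandFrac <- 1.5 * geometry@cellDiameter / geometry@dvHeight
  mlBandHalf <- 0.75 * geometry@cellDiameter / geometry@mlWidth
  canal <- geometry@canalDvFrac
  cons <- schedule@consolidation
  s <- if (t < cons[1]) 0 else min(1, (t - cons[1]) / (cons[2] - cons[1]))
  lo <- 0 + s * canal
  hi <- dvTop0 + s * (canal + bandFrac - dvTop0)
  mlHalf <- 0.5 + s * (mlBandHalf - 0.5)
  dvFrac >= lo & dvFrac <= hi & abs(mlFrac - 0.5) <= mlHalf
}

.notchOffStart <- function(perturbation) {
  if (perturbation@genotype == "mindbomb") return(0)
  if (perturbation@drug == "LY411575") return(perturbation@drugStart)
  NA_real_
}

.asCells <- function(cells) {
  if (is.data.frame(cells)) return(cells)
  stop("'cells' must be a data.frame from buildEmbryo()")
}

#' Ground-truth Notch pathway activity
#'
#' Notch response in the spinal cord is dorsoventrally uniform during the
#' activation phase, consolidates to a medial band 1-2 cell tiers dorsal
#' to the canal during the consolidation phase, and returns to the basal
#' level during termination (basal by 72 hpf). LY-411575 (gamma-secretase
#' inhibition) ramps the response linearly to exactly 0 over 4 h from
#' `drugStart`; the `mindbomb` genotype behaves like LY-411575 from 0 hpf.
#' Heat-shock-induced NICD drives the response to its maximum cord-wide
#' (independent of gamma-secretase). Cells outside the spinal cord report
#' the basal level.
#'
#' @param cells a population `data.frame` from [buildEmbryo()] (or any
#'   data.frame with `tissue`, `dv_frac`, `ml_frac`).
#' @param t time, hpf.
#' @param perturbation a [PerturbationSpec-class].
#' @param schedule a [PhaseSchedule-class].
#' @param geometry a [SpinalCordGeometry-class].
#' @param basal basal activity level.
#' @return numeric vector of activity levels in [0, 1], one per cell.
#' @examples
#' cells <- buildEmbryo(SpinalCordGeometry(), cellSpacing = 5, seed = 1)
#' act <- notchActivity(cells, t = 30)
#' range(act)
#' @export
notchActivity <- function(cells, t, perturbation = PerturbationSpec(),
                          schedule = PhaseSchedule(),
                          geometry = SpinalCordGeometry(), basal = 0.02) {
  cells <- .asCells(cells)
  stopifnot(is(perturbation, "PerturbationSpec"),
            is(schedule, "PhaseSchedule"))
  n <- nrow(cells)
  level <- rep(basal, n)
  isCord <- cells$tissue == "spinal_cord"
  if (any(isCord)) {
    env <- .phaseEnvelope(t, schedule, rampEnd = schedule@termination[1] + 6)
    inside <- .activeRegionMask(cells$dv_frac[isCord], cells$ml_frac[isCord],
                                t, schedule, geometry, dvTop0 = 1)
    level[isCord] <- pmax(basal, as.numeric(inside) * env)
  }
  tOff <- .notchOffStart(perturbation)
  if (!is.na(tOff)) {
    ramp <- max(0, 1 - max(0, t - tOff) / 4)
    level[isCord] <- level[isCord] * ramp
  }
  if (perturbation@transgene == "NICD" &&
      length(perturbation@heatshockTime) &&
      t >= perturbation@heatshockTime)
    level[isCord] <- 1
  pmin(pmax(level, 0), 1)
}

## Notch gate on cord Hh response: relaxes exponentially (half-time
## `halfTime` hours) from the intact level towards the supplied
## notch level once Notch is off.
.notchGate <- function(notchLevel, t, perturbation, halfTime = 0.8) {
  tOff <- .notchOffStart(perturbation)
  decay <- if (is.na(tOff)) 0 else 2^(-max(0, t - tOff) / halfTime)
  notchLevel + (1 - notchLevel) * decay
}

#' Ground-truth Hedgehog pathway activity
#'
#' In the unperturbed spinal cord during the activation phase the Hh
#' response is graded along DV: maximal ventrally, falling linearly to
#' half-maximum at `ventralExtent` (default the ventral 75% of the cord)
#' and basal dorsal of that, so the above-half-maximum region spans the
#' ventral 75% of cord height. The active region consolidates to the
#' medial band dorsal to the canal and terminates (basal by 78 hpf,
#' slightly delayed relative to Notch). Within the spinal cord the
#' response is gated by Notch: when Notch is lost the cord response
#' relaxes exponentially towards the (scaled) Notch level with a 0.8 h
#' half-time. Somite and vasculature responses are Notch-independent.
#' Cyclopamine reduces the cord response to a residual floor (0.1) and
#' the somite response to 0, each ramping over 4 h; heat-shock rSmoM2
#' raises the response everywhere except Notch-off cord cells; heat-shock
#' EGFP-Gli1 raises the cord response to 0.8 even without Notch (capped
#' below the unperturbed ventral maximum); the `iguana` genotype has a
#' low uniform Smo-independent cord response (0.3), still Notch-gated.
#'
#' @inheritParams notchActivity
#' @param notchLevel per-cell Notch activity in [0, 1]; computed with
#'   [notchActivity()] when `NULL`. Supplying it explicitly (e.g. 0 or 1)
#'   probes the gating directly.
#' @param ventralExtent DV fraction bounding the graded ventral response.
#' @return numeric vector of activity levels in [0, 1], one per cell.
#' @examples
#' cells <- buildEmbryo(SpinalCordGeometry(), cellSpacing = 5, seed = 1)
#' act <- hhActivity(cells, t = 30)
#' @export
hhActivity <- function(cells, t, perturbation = PerturbationSpec(),
                       notchLevel = NULL, schedule = PhaseSchedule(),
                       geometry = SpinalCordGeometry(), basal = 0.02,
                       ventralExtent = 0.75) {
  cells <- .asCells(cells)
  stopifnot(is(perturbation, "PerturbationSpec"),
            is(schedule, "PhaseSchedule"))
  n <- nrow(cells)
  explicitNotch <- !is.null(notchLevel)
  if (explicitNotch) {
    if (any(!is.finite(notchLevel)) || any(notchLevel < 0) ||
        any(notchLevel > 1))
      stop("'notchLevel' must lie in [0, 1]")
    notchLevel <- rep_len(notchLevel, n)
  } else {
    notchLevel <- notchActivity(cells, t, perturbation, schedule,
                                geometry, basal)
  }
  hs <- length(perturbation@heatshockTime) == 1 &&
    t >= perturbation@heatshockTime
  smoM2 <- perturbation@transgene == "rSmoM2" && hs
  gli1 <- perturbation@transgene == "EGFP_Gli1" && hs

  level <- rep(basal, n)
  isCord <- cells$tissue == "spinal_cord"
  isSom <- cells$tissue == "somite"

  if (any(isCord)) {
    dv <- cells$dv_frac[isCord]
    if (perturbation@genotype == "iguana") {
      base <- rep(0.3, sum(isCord))
    } else if (smoM2) {
      base <- rep(1, sum(isCord))
    } else {
      grad <- ifelse(dv < ventralExtent, 1 - 0.5 * dv / ventralExtent,
                     basal)
      env <- .phaseEnvelope(t, schedule,
                            rampEnd = schedule@termination[2])
      inside <- .activeRegionMask(dv, cells$ml_frac[isCord], t, schedule,
                                  geometry, dvTop0 = ventralExtent)
      base <- pmax(basal, grad * as.numeric(inside) * env)
    }
    ## Notch gating is a spinal-cord-specific cross-talk
    gate <- if (explicitNotch || !is.na(.notchOffStart(perturbation))) {
      .notchGate(notchLevel[isCord], t, perturbation)
    } else 1
    cordLevel <- base * gate
    if (gli1) cordLevel <- pmax(cordLevel, 0.8)
    if (perturbation@drug == "cyclopamine" &&
        perturbation@genotype != "iguana") {
      s <- min(1, max(0, (t - perturbation@drugStart) / 4))
      cordLevel <- ifelse(cordLevel > 0.1,
                          cordLevel * (1 - s) + 0.1 * s, cordLevel)
    }
    level[isCord] <- cordLevel
  }
  if (any(isSom)) {
    somLevel <- rep(if (t >= schedule@activation[1]) 0.6 else basal,
                    sum(isSom))
    if (smoM2) somLevel <- rep(1, sum(isSom))
    if (perturbation@drug == "cyclopamine") {
      s <- min(1, max(0, (t - perturbation@drugStart) / 4))
      somLevel <- somLevel * (1 - s)
    }
    level[isSom] <- somLevel
  }
  pmin(pmax(level, 0), 1)
}

#' Build an activity field
#'
#' Wraps [notchActivity()] / [hhActivity()] into a callable
#' `f(cells, t)` with fixed condition, schedule and geometry -- the form
#' consumed by [simulateReporter()].
#'
#' @inheritParams notchActivity
#' @param pathway `"notch"` or `"hh"`.
#' @param ventralExtent passed to [hhActivity()].
#' @return a function `(cells, t) -> activity vector`, with the basal
#'   level attached as attribute `"basal"`.
#' @export
activityField <- function(pathway = c("notch", "hh"),
                          perturbation = PerturbationSpec(),
                          schedule = PhaseSchedule(),
                          geometry = SpinalCordGeometry(), basal = 0.02,
                          ventralExtent = 0.75) {
  pathway <- match.arg(pathway)
  f <- if (pathway == "notch") {
    function(cells, t) notchActivity(cells, t, perturbation, schedule,
                                     geometry, basal)
  } else {
    function(cells, t) hhActivity(cells, t, perturbation, NULL, schedule,
                                  geometry, basal, ventralExtent)
  }
  attr(f, "basal") <- basal
  attr(f, "pathway") <- pathway
  f
}

.MARKER_CONTROL <- c(ptc2 = 0.75, sox2 = 0.80, olig2 = 0.10)

## Piecewise-linear factor trajectories, indexed by marker and condition
## key. Knot times are hours since drug start (or heat shock when no
## drug); the factor multiplies the control domain fraction. Values
## beyond the last knot hold.
.MARKER_TRAJ <- list(
  ptc2 = list(
    control   = list(t = 0, f = 1),
    LY411575  = list(t = c(0, 1, 2, 3), f = c(1, 0.56, 0.50, 0.35)),
    cyclopamine = list(t = c(0, 4), f = c(1, 0.30)),
    rSmoM2    = list(t = c(0, 10), f = c(1, 1.20)),
    EGFP_Gli1 = list(t = c(0, 10), f = c(1, 1.20))),
  sox2 = list(
    control   = list(t = 0, f = 1),
    LY411575  = list(t = c(0, 1, 2, 3), f = c(1, 0.90, 0.50, 0.35)),
    cyclopamine = list(t = 0, f = 1)),
  olig2 = list(
    control   = list(t = 0, f = 1),
    LY411575  = list(t = c(0, 3, 10), f = c(1, 0.65, 0.10)),
    rSmoM2    = list(t = c(0, 10), f = c(1, 1.25)),
    EGFP_Gli1 = list(t = c(0, 10), f = c(1, 1.25)),
    `rSmoM2+LY411575`    = list(t = c(0, 10), f = c(1, 0.10)),
    `EGFP_Gli1+LY411575` = list(t = c(0, 10), f = c(1, 0.63))))

.conditionKey <- function(perturbation) {
  drug <- perturbation@drug
  if (perturbation@genotype == "mindbomb") drug <- "LY411575"
  tg <- perturbation@transgene
  if (tg != "none" && drug == "LY411575") paste0(tg, "+LY411575")
  else if (tg != "none") tg
  else if (drug == "none") "control"
  else drug
}

#' Ground-truth marker domain fraction
#'
#' The planted fraction of the spinal-cord cross-section occupied by a
#' marker's expression domain under a given condition, used to paint
#' marker intensity onto cells before rendering. Control fractions:
#' ptc2 0.75 (the graded ventral Hh-responsive domain), sox2 0.80
#' (neural progenitor domain), olig2 0.10 (motor neuron precursor
#' domain). Condition trajectories are piecewise-linear in hours since
#' drug start (or heat shock); control trajectories are constant.
#'
#' @param marker `"ptc2"`, `"sox2"` or `"olig2"`.
#' @param perturbation a [PerturbationSpec-class].
#' @param hoursSince hours since drug start (heat shock when no drug).
#' @return domain fraction of cord cross-section area, in [0, 1].
#' @examples
#' markerDomainTruth("ptc2",
#'   PerturbationSpec(drug = "LY411575", drugStart = 20), hoursSince = 1)
#' @export
markerDomainTruth <- function(marker, perturbation = PerturbationSpec(),
                              hoursSince = 0) {
  if (length(marker) != 1 || !marker %in% names(.MARKER_CONTROL))
    stop(sprintf("unknown marker '%s'", paste(marker, collapse = ",")))
  stopifnot(is(perturbation, "PerturbationSpec"))
  if (!is.numeric(hoursSince) || any(hoursSince < 0))
    stop("'hoursSince' must be >= 0")
  key <- .conditionKey(perturbation)
  traj <- .MARKER_TRAJ[[marker]][[key]]
  if (is.null(traj))
    stop(sprintf("no trajectory for marker '%s' under condition '%s'",
                 marker, key))
  f <- if (length(traj$t) == 1) rep(traj$f, length(hoursSince)) else
    approx(traj$t, traj$f, xout = pmin(hoursSince, max(traj$t)),
           rule = 2)$y
  pmin(pmax(.MARKER_CONTROL[[marker]] * f, 0), 1)
}

#' @describeIn markerDomainTruth control (unperturbed) domain fraction of
#'   a marker.
#' @export
markerControlFraction <- function(marker) {
  if (!marker %in% names(.MARKER_CONTROL))
    stop(sprintf("unknown marker '%s'", marker))
  .MARKER_CONTROL[[marker]]
}

#' Export a cell population as CSV
#'
#' @param cells population from [buildEmbryo()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePopulationCsv <- function(cells, path) {
  utils::write.csv(
    cells[, c("id", "tissue", "dv_frac", "ml_frac", "ap_um")],
    path, row.names = FALSE)
  invisible(path)
}
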