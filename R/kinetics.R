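## Kaede reporter kinetics: first-order synthesis/decay of the green pool,
## passive decay of the red pool, and instantaneous photoconversion.
## dG/dt = alpha * a(t) - delta * G ; dR/dt = -delta * R.

#' Advance reporter state over one time step
#'
#' Exact exponential-integrator step for piecewise-constant pathway
#' activity: over a step of length `dt` with constant activity `a`,
#' `G' = G e^{-delta dt} + (alpha a / delta)(1 - e^{-delta dt})` (and the
#' `delta = 0` limit `G' = G + alpha a dt`); the red pool decays as
#' `R' = R e^{-delta dt}`.
#'
#' @param state numeric `c(green, red)` in a.u., or a 2-column matrix
#'   with one row per cell.
#' @param activity pathway activity in [0, 1] (scalar or one per row).
#' @param dt step length, hours (> 0).
#' @param params a [ReporterParams-class].
#' @return updated state, same shape as `state`.
#' @examples
#' p <- ReporterParams(synthesisRate = 1, decayRate = 0.1)
#' stepReporter(c(0, 0), activity = 1, dt = 1, params = p)
#' @export
stepReporter <- function(state, activity, dt, params = ReporterParams()) {
  stopifnot(is(params, "ReporterParams"))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number of hours")
  if (any(!is.finite(activity)) || any(activity < 0) || any(activity > 1))
    stop("'activity' must lie in [0, 1]")
  vec <- is.null(dim(state))
  m <- if (vec) matrix(state, ncol = 2) else state
  if (ncol(m) != 2 || any(m < 0))
    stop("'state' must be non-negative c(green, red) pairs")
  a <- params@synthesisRate
  d <- params@decayRate
  if (d > 0) {
    e <- exp(-d * dt)
    m[, 1] <- m[, 1] * e + (a * activity / d) * (1 - e)
    m[, 2] <- m[, 2] * e
  } else {
    m[, 1] <- m[, 1] + a * activity * dt
  }
  if (vec) as.numeric(m) else m
}

#' Photoconvert the green pool
#'
#' Moves a fraction `efficiency` of the green pool into the red pool:
#' `G' = (1 - eta) G`, `R' = R + eta G`. The green + red total is
#' conserved exactly.
#'
#' @param state numeric `c(green, red)` or a 2-column matrix.
#' @param efficiency conversion efficiency eta in [0, 1].
#' @return converted state, same shape as `state`.
#' @examples
#' photoconvert(c(5, 0), efficiency = 1)
#' @export
photoconvert <- function(state, efficiency = 1) {
  if (!is.numeric(efficiency) || length(efficiency) != 1 ||
      !is.finite(efficiency) || efficiency < 0 || efficiency > 1)
    stop("'efficiency' must lie in [0, 1]")
  vec <- is.null(dim(state))
  m <- if (vec) matrix(state, ncol = 2) else state
  if (ncol(m) != 2 || any(m < 0))
    stop("'state' must be non-negative c(green, red) pairs")
  g <- m[, 1]
  m[, 2] <- m[, 2] + efficiency * g
  m[, 1] <- (1 - efficiency) * g
  if (vec) as.numeric(m) else m
}

#' Simulate per-cell reporter states through a photoconversion experiment
#'
#' Integrates the Kaede kinetics for every cell from `tStart` to
#' `tImage`, applying the photoconversion event at `event@t0` to cells
#' whose AP position falls inside the converted window. Activity is taken
#' from `field(cells, t)` (see [activityField()]), multiplied by each
#' cell's heterogeneity factor and clamped to [0, 1]. A positive
#' `maturationLag` delays the appearance of fluorescent green signal by
#' drawing activity from `t - maturationLag`.
#'
#' @param cells population from [buildEmbryo()].
#' @param field activity field, a function `(cells, t) -> [0, 1]`.
#' @param event a [ConversionEvent-class].
#' @param tImage imaging time, hpf; must be after `event@t0`.
#' @param params a [ReporterParams-class].
#' @param tStart integration start, hpf (reporter pools start empty).
#' @param dt integration step, hours.
#' @return a `data.frame` with `id`, `green`, `red` (a.u.) and
#'   `converted` (logical).
#' @examples
#' cells <- buildEmbryo(SpinalCordGeometry(), cellSpacing = 5, seed = 1)
#' f <- activityField("hh")
#' ev <- ConversionEvent(t0 = 24, apWindow = c(50, 200))
#' st <- simulateReporter(cells, f, ev, tImage = 30)
#' head(st)
#' @export
simulateReporter <- function(cells, field, event, tImage,
                             params = ReporterParams(), tStart = 18,
                             dt = 0.05) {
  cells <- .asCells(cells)
  stopifnot(is(event, "ConversionEvent"), is(params, "ReporterParams"),
            is.function(field))
  if (tImage <= event@t0)
    stop("'tImage' must be after the conversion time t0")
  if (tStart > event@t0)
    stop("'tStart' must not be after the conversion time t0")
  n <- nrow(cells)
  state <- matrix(0, n, 2, dimnames = list(NULL, c("green", "red")))
  converted <- cells$ap_um >= event@apWindow[1] &
    cells$ap_um <= event@apWindow[2]
  noise <- if ("noise_factor" %in% names(cells)) cells$noise_factor else
    rep(1, n)

  integrate <- function(state, from, to) {
    if (to <= from) return(state)
    nStep <- max(1L, ceiling((to - from) / dt - 1e-9))
    bounds <- seq(from, to, length.out = nStep + 1)
    for (i in seq_len(nStep)) {
      tMid <- (bounds[i] + bounds[i + 1]) / 2 - params@maturationLag
      act <- pmin(pmax(field(cells, tMid) * noise, 0), 1)
      state <- stepReporter(state, act, bounds[i + 1] - bounds[i], params)
    }
    state
  }
  state <- integrate(state, tStart, event@t0)
  state[converted, ] <- photoconvert(state[converted, , drop = FALSE],
                                     event@efficiency)
  state <- integrate(state, event@t0, tImage)
  data.frame(id = cells$id, green = state[, 1], red = state[, 2],
             converted = converted)
}

#' Classify a reporter state against the detection floor
#'
#' @param green,red channel amounts, a.u.
#' @param floor detection floor, a.u.
#' @return factor with levels new / continued / past / none (green-only,
#'   both, red-only, neither above the floor).
#' @export
reporterStateClass <- function(green, red, floor = 0) {
  g <- green > floor
  r <- red > floor
  factor(ifelse(g & r, "continued",
         ifelse(g, "new", ifelse(r, "past", "none"))),
         levels = c("new", "continued", "past", "none"))
}

#' Export per-cell reporter states as CSV
#'
#' @param states `data.frame` from [simulateReporter()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeStatesCsv <- function(states, path) {
  utils::write.csv(
    data.frame(id = states$id, green = states$green, red = states$red,
               converted_flag = states$converted),
    path, row.names = FALSE)
  invisible(path)
}
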