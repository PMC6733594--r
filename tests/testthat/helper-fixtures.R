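# Shared fixtures and independent oracles.

# Small desk geometry for fast rendering tests.
smallGeometry <- function() {
  SpinalCordGeometry(dvHeight = 30, mlWidth = 16, apLength = 100,
                     somiteLength = 20, cellDiameter = 4)
}

# A dense DV grid of cord "cells" with unit heterogeneity, for direct
# activity-field evaluation.
cordDvGrid <- function(n = 1001, ml = 0.5) {
  data.frame(tissue = "spinal_cord", dv_frac = seq(0, 1, length.out = n),
             ml_frac = ml, noise_factor = 1)
}

oneCell <- function(tissue = "spinal_cord", dv = 0.5, ml = 0.5) {
  data.frame(tissue = tissue, dv_frac = dv, ml_frac = ml,
             ap_um = 50, dv_um = 20, ml_um = 10, id = 1L,
             noise_factor = 1)
}

# Closed-form green pool under constant activity a from G(0) = 0:
# G(t) = (alpha a / delta) (1 - exp(-delta t)).
greenClosedForm <- function(t, a, alpha, delta) {
  if (delta == 0) alpha * a * t else (alpha * a / delta) * (1 - exp(-delta * t))
}

# Brute-force Mann-Whitney: enumerate all rank arrangements of the
# combined sample and compute the exact two-sided p-value by doubling
# the smaller tail mass (capped at 1). Tie-free samples only.
enumMannWhitneyP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  obs <- sum(outer(a, b, ">"))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) {
    r <- seq_len(n1 + n2)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  pLow <- mean(us <= obs)
  pHigh <- mean(us >= obs)
  min(1, 2 * min(pLow, pHigh))
}

# Trapezoid quadrature of a scalar function on [t0, t1].
trapezoid <- function(f, t0, t1, n = 2000) {
  x <- seq(t0, t1, length.out = n + 1)
  y <- vapply(x, f, numeric(1))
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}
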