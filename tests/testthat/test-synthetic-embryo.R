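test_that("geometry and schedule validity rules hold", {
  expect_error(SpinalCordGeometry(dvHeight = -1), "dvHeight")
  expect_error(SpinalCordGeometry(canalDvFrac = 1.2), "canalDvFrac")
  expect_error(SpinalCordGeometry(apLength = 100, somiteLength = 50),
               "5 somites")
  expect_error(PhaseSchedule(activation = c(24, 40),
                             consolidation = c(42, 66)), "contiguous")
  expect_error(PerturbationSpec(drug = "tea"), "unknown drug")
  expect_error(PerturbationSpec(transgene = "NICD"), "heatshockTime")
  expect_equal(somiteCount(SpinalCordGeometry()), 5L)
})

test_that("buildEmbryo tiles deterministically and within bounds", {
  geom <- smallGeometry()
  a <- buildEmbryo(geom, cellSpacing = 4, seed = 42)
  b <- buildEmbryo(geom, cellSpacing = 4, seed = 42)
  expect_identical(a, b)
  d <- buildEmbryo(geom, cellSpacing = 4, seed = 43)
  expect_false(identical(a, d))
  expect_setequal(unique(a$tissue), c("spinal_cord", "somite",
                                      "vasculature"))
  cord <- a[a$tissue == "spinal_cord", ]
  expect_true(all(cord$dv_frac >= 0 & cord$dv_frac <= 1))
  expect_true(all(cord$ml_frac >= 0 & cord$ml_frac <= 1))
  expect_true(all(a$ap_um >= 0 & a$ap_um <= geom@apLength))
  expect_false(anyDuplicated(a$id) > 0)
  # AP span covers all 5 somite intervals
  expect_equal(range(floor(cord$ap_um / geom@somiteLength)), c(0, 4))
  expect_error(buildEmbryo(geom, cellSpacing = -1), "positive")
  expect_error(buildEmbryo(geom, cellSpacing = 100), "twice")
})

test_that("Notch response is DV-uniform in activation and basal after termination", {
  grid <- cordDvGrid()
  act30 <- notchActivity(grid, t = 30)
  expect_equal(act30[grid$dv_frac < 0.3], act30[grid$dv_frac > 0.7][
    seq_along(act30[grid$dv_frac < 0.3])])
  expect_true(all(act30 == act30[1]))
  # basal after the end of termination
  expect_equal(notchActivity(grid, t = 80), rep(0.02, nrow(grid)))
  # and before activation begins
  expect_equal(notchActivity(grid, t = 20), rep(0.02, nrow(grid)))
})

test_that("LY-411575 ramps Notch response to exactly zero within 4 h", {
  grid <- cordDvGrid(101)
  ly <- PerturbationSpec(drug = "LY411575", drugStart = 20)
  expect_equal(notchActivity(grid, t = 24, perturbation = ly),
               rep(0, 101))
  expect_equal(notchActivity(grid, t = 30, perturbation = ly),
               rep(0, 101))
  # halfway through the ramp the response is halved
  mid <- notchActivity(grid, t = 22, perturbation = ly,
                       schedule = PhaseSchedule(c(20, 42), c(42, 66),
                                                c(66, 78)))
  full <- notchActivity(grid, t = 22,
                        schedule = PhaseSchedule(c(20, 42), c(42, 66),
                                                 c(66, 78)))
  expect_equal(mid, full / 2)
  # mindbomb behaves like inhibition from 0 hpf
  mib <- PerturbationSpec(genotype = "mindbomb")
  expect_equal(notchActivity(grid, t = 30, perturbation = mib),
               rep(0, 101))
})

test_that("NICD heat shock drives Notch response to maximum cord-wide", {
  grid <- cordDvGrid(101)
  nicd <- PerturbationSpec(transgene = "NICD", heatshockTime = 20)
  expect_equal(notchActivity(grid, t = 70, perturbation = nicd),
               rep(1, 101))
  expect_equal(notchActivity(oneCell("somite"), t = 30,
                             perturbation = nicd), 0.02)
})

test_that("Hh response is ventrally graded with above-half-max extent 75%", {
  grid <- cordDvGrid(2001)
  act <- hhActivity(grid, t = 30)
  l <- function(dv) act[which.min(abs(grid$dv_frac - dv))]
  expect_gt(l(0.1), l(0.5))
  expect_gt(l(0.5), 0.02)
  expect_equal(l(0.9), 0.02)
  expect_equal(mean(act > max(act) / 2), 0.75, tolerance = 0.002)
  # monotone non-increasing along DV throughout the activation phase
  for (t in c(24, 30, 36, 41.9))
    expect_true(all(diff(hhActivity(grid, t = t)) <= 1e-12))
})

test_that("somite Hh response ignores Notch state entirely", {
  som <- oneCell("somite")
  ly <- PerturbationSpec(drug = "LY411575", drugStart = 20)
  for (t in c(21, 24, 30, 50, 70))
    expect_identical(hhActivity(som, t = t, perturbation = ly),
                     hhActivity(som, t = t))
  # but cyclopamine eliminates it
  cyc <- PerturbationSpec(drug = "cyclopamine", drugStart = 20)
  expect_equal(hhActivity(som, t = 30, perturbation = cyc), 0)
})

test_that("Notch gates Hh response in the cord, monotonically", {
  cord <- oneCell("spinal_cord", dv = 0.3)
  ly <- PerturbationSpec(drug = "LY411575", drugStart = 20)
  off <- hhActivity(cord, t = 30, perturbation = ly, notchLevel = 0)
  on <- hhActivity(cord, t = 30, perturbation = ly, notchLevel = 1)
  expect_lte(off, on)
  # randomized: gating is monotone in the Notch level
  set.seed(7)
  for (i in 1:20) {
    nl <- sort(runif(2))
    v <- vapply(nl, function(x)
      hhActivity(cord, t = 25, perturbation = ly, notchLevel = x),
      numeric(1))
    expect_lte(v[1], v[2] + 1e-12)
  }
  expect_error(hhActivity(cord, t = 30, notchLevel = 1.5), "0, 1")
})

test_that("Notch-off Hh decay follows the 0.8 h half-time in the cord", {
  cord <- oneCell("spinal_cord", dv = 0.1)
  ly <- PerturbationSpec(drug = "LY411575", drugStart = 24)
  base <- hhActivity(cord, t = 24)
  # one half-time after drug start, with Notch fully off
  v <- hhActivity(cord, t = 24.8, perturbation = ly, notchLevel = 0)
  expect_equal(v, base / 2, tolerance = 1e-10)
})

test_that("rSmoM2 raises Hh everywhere except Notch-off cord cells", {
  smo <- PerturbationSpec(transgene = "rSmoM2", heatshockTime = 20)
  cord <- oneCell("spinal_cord", dv = 0.5)
  expect_equal(hhActivity(cord, t = 30, perturbation = smo,
                          notchLevel = 0), 0)
  withNotch <- hhActivity(cord, t = 30, perturbation = smo,
                          notchLevel = 1)
  expect_gt(withNotch, hhActivity(cord, t = 30))
  expect_equal(hhActivity(oneCell("somite"), t = 30,
                          perturbation = smo), 1)
})

test_that("EGFP-Gli1 partially restores cord Hh without Notch", {
  gli <- PerturbationSpec(transgene = "EGFP_Gli1", heatshockTime = 20)
  cord <- oneCell("spinal_cord", dv = 0.5)
  v <- hhActivity(cord, t = 30, perturbation = gli, notchLevel = 0)
  expect_equal(v, 0.8)
  expect_lt(v, 1)  # capped below the unperturbed ventral maximum
  # and raises the dorsal cord in DMSO
  dors <- oneCell("spinal_cord", dv = 0.9)
  expect_gt(hhActivity(dors, t = 30, perturbation = gli), 0.02)
})

test_that("iguana cords have low uniform Smo-independent, Notch-gated Hh", {
  igu <- PerturbationSpec(genotype = "iguana")
  grid <- cordDvGrid(51)
  v <- hhActivity(grid, t = 30, perturbation = igu)
  expect_true(all(v == 0.3))
  cyc <- PerturbationSpec(drug = "cyclopamine", drugStart = 20,
                          genotype = "iguana")
  expect_equal(hhActivity(grid, t = 30, perturbation = cyc), v)
  mib <- PerturbationSpec(genotype = "mindbomb")
  # Notch-off eliminates even the Smo-independent activity
  expect_lt(max(hhActivity(cordDvGrid(51), t = 40, perturbation = mib,
                           notchLevel = 0)), 0.01)
})

test_that("activity levels stay in [0, 1] over a dense grid of conditions", {
  base <- cordDvGrid(41, ml = 0.2)
  cells <- rbind(base, cordDvGrid(41, ml = 0.9),
                 oneCell("somite")[, names(base)],
                 oneCell("vasculature")[, names(base)])
  perts <- list(
    PerturbationSpec(),
    PerturbationSpec(drug = "LY411575", drugStart = 20),
    PerturbationSpec(drug = "cyclopamine", drugStart = 20),
    PerturbationSpec(transgene = "rSmoM2", heatshockTime = 20),
    PerturbationSpec(transgene = "EGFP_Gli1", heatshockTime = 20,
                     drug = "LY411575", drugStart = 20),
    PerturbationSpec(genotype = "iguana"),
    PerturbationSpec(genotype = "mindbomb"))
  for (p in perts) for (t in seq(18, 84, by = 6)) {
    for (f in list(notchActivity, hhActivity)) {
      v <- f(cells, t, p)
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("the above-half-max Hh width shrinks through consolidation", {
  grid <- cordDvGrid(1001)
  widths <- vapply(seq(42, 66, by = 3), function(t) {
    v <- hhActivity(grid, t = t)
    mean(v > max(v) / 2)
  }, numeric(1))
  expect_true(all(diff(widths) <= 1e-9))
  # and ends in a medial band 1-2 cell tiers dorsal to the canal
  v66 <- hhActivity(grid, t = 65.9)
  active <- grid$dv_frac[v66 > max(v66) / 2]
  geom <- SpinalCordGeometry()
  expect_gte(min(active), geom@canalDvFrac - 0.01)
  expect_lte(max(active),
             geom@canalDvFrac + 1.5 * geom@cellDiameter / geom@dvHeight +
               0.01)
})

test_that("marker domain truths match the calibrated trajectories", {
  ly <- PerturbationSpec(drug = "LY411575", drugStart = 20)
  ctrl <- markerControlFraction("ptc2")
  expect_equal(ctrl, 0.75)
  expect_equal(markerDomainTruth("ptc2", ly, 1), ctrl * (1 - 0.44))
  expect_equal(markerDomainTruth("ptc2", ly, 2), ctrl * 0.50)
  expect_equal(markerDomainTruth("ptc2", ly, 3), ctrl * 0.35)
  expect_equal(markerDomainTruth("sox2", ly, 1), 0.80 * (1 - 0.10))
  expect_equal(markerDomainTruth("sox2", ly, 2), 0.80 * 0.50)
  gli <- PerturbationSpec(transgene = "EGFP_Gli1", heatshockTime = 20)
  gliLy <- PerturbationSpec(transgene = "EGFP_Gli1", heatshockTime = 20,
                            drug = "LY411575", drugStart = 20)
  expect_equal(markerDomainTruth("olig2", gli, 10), 0.10 * 1.25)
  expect_equal(markerDomainTruth("olig2", gliLy, 10), 0.10 * 0.63)
  # control trajectories are constant
  expect_equal(markerDomainTruth("ptc2", PerturbationSpec(), 7), ctrl)
  # intermediate times interpolate linearly
  expect_equal(markerDomainTruth("ptc2", ly, 1.5),
               ctrl * mean(c(0.56, 0.50)))
  expect_error(markerDomainTruth("shh", ly, 1), "unknown marker")
  expect_error(markerDomainTruth("sox2",
    PerturbationSpec(transgene = "rSmoM2", heatshockTime = 20), 1),
    "no trajectory")
  expect_error(markerDomainTruth("ptc2", ly, -1), ">= 0")
})

test_that("cell populations export to CSV round-trip", {
  cells <- buildEmbryo(smallGeometry(), cellSpacing = 4, seed = 1)
  f <- tempfile(fileext = ".csv")
  writePopulationCsv(cells, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(cells))
  expect_named(back, c("id", "tissue", "dv_frac", "ml_frac", "ap_um"))
})
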