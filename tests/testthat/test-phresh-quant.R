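emptyStack <- function(z = 4, y = 6, x = 20, value = 0, window = c(5, 15)) {
  KaedeStack(array(value, c(z, y, x, 2)), convertedApWindow = window)
}

test_that("unconverted reference finds the planted maximum", {
  st <- emptyStack()
  st@data[2, 3, 2, 1] <- 1000        # AP index 2 lies outside [5, 15]
  ref <- unconvertedReference(st, statistic = "max", background = 0)
  expect_equal(ref$reference, 1000)
  # the converted region must not contribute
  st@data[2, 3, 10, 1] <- 5000
  expect_equal(unconvertedReference(st, statistic = "max",
                                    background = 0)$reference, 1000)
})

test_that("a fully converted stack has no reference region", {
  st <- emptyStack(window = c(0, 20))
  expect_error(unconvertedReference(st), "no unconverted reference")
})

test_that("the percentile reference resists a hot pixel", {
  st <- emptyStack(z = 10, y = 10, x = 30, value = 100, window = c(20, 30))
  st@data[5, 5, 2, 1] <- 10000
  ref <- unconvertedReference(st, statistic = "percentile", prob = 0.999,
                              background = 0)
  expect_lt(ref$reference, 10000)
  expect_gte(ref$reference, 100)
})

test_that("dvProfile normalizes and averages traces as specified", {
  sec <- matrix(40, 20, 11)
  p <- dvProfile(sec, canal = c(10, 6), reference = 80, background = 0)
  expect_s4_class(p, "IntensityProfile")
  expect_true(all(abs(profileValues(p) - 50) < 1e-9))
  # three traces a, b, c average before normalization
  sec2 <- matrix(0, 20, 11)
  sec2[, 5] <- 30; sec2[, 6] <- 60; sec2[, 7] <- 90
  p2 <- dvProfile(sec2, canal = c(10, 6), reference = 100, nLines = 3,
                  lineSpacing = 1, voxelSize = 1, background = 0)
  expect_true(all(abs(profileValues(p2) - 60) < 1e-9))
  expect_error(dvProfile(sec, canal = c(99, 6), reference = 80),
               "outside")
  expect_error(dvProfile(sec, canal = c(10, 6), reference = 0), "> 0")
})

test_that("a planted ventral band is recovered at its true extent", {
  sec <- matrix(0, 50, 11)
  sec[1:20, ] <- 100                       # ventral 40% bright
  p <- dvProfile(sec, canal = c(15, 6), reference = 100, background = 0)
  expect_equal(aboveHalfMaxExtent(p), 0.40, tolerance = 0.05)
})

test_that("mlProfile traces dorsal to the canal", {
  sec <- matrix(25, 30, 20)
  p <- mlProfile(sec, canal = c(10, 10), reference = 50, dorsalOffset = 3,
                 background = 0)
  expect_true(all(abs(profileValues(p) - 50) < 1e-9))
  # a medial Gaussian band peaks at the centre
  sec2 <- matrix(0, 30, 21)
  sec2[13, ] <- 100 * exp(-(seq_len(21) - 11)^2 / 8)
  p2 <- mlProfile(sec2, canal = c(10, 11), reference = 100,
                  dorsalOffset = 3, background = 0)
  peak <- profilePositions(p2)[which.max(profileValues(p2))]
  expect_equal(peak, 0.5, tolerance = 0.05)
  expect_error(mlProfile(sec, canal = c(10, 10), reference = 50,
                         dorsalOffset = 100), "outside")
})

test_that("somite averaging is a pointwise mean with contract checks", {
  mk <- function(vals) IntensityProfile("DV", seq(0, 1, 0.25), vals)
  five <- replicate(5, mk(c(1, 2, 3, 4, 5)), simplify = FALSE)
  avg <- averageOverSomites(five)
  expect_equal(profileValues(avg), c(1, 2, 3, 4, 5))
  expect_equal(avg@nSomites, 5L)
  mixed <- c(replicate(4, mk(rep(0, 5)), simplify = FALSE),
             list(mk(c(5, 5, 5, 5, 5))))
  expect_equal(profileValues(averageOverSomites(mixed)), rep(1, 5))
  expect_warning(averageOverSomites(five[1:3]), "expected 5")
  bad <- list(mk(1:5), IntensityProfile("DV", seq(0, 1, 0.5), 1:3))
  expect_error(suppressWarnings(averageOverSomites(bad)), "mismatched")
})

test_that("response classification matches the colour code", {
  expect_equal(as.character(classifyResponse(50, 1)), "new")
  expect_equal(as.character(classifyResponse(40, 40)), "continued")
  expect_equal(as.character(classifyResponse(1, 40)), "past")
  expect_equal(as.character(classifyResponse(1, 1)), "none")
  expect_error(classifyResponse(-1, 5), ">= 0")
})

test_that("the four response classes partition every input", {
  set.seed(21)
  g <- c(runif(500, 0, 60), 10, 0, 10.0001)
  r <- c(runif(500, 0, 60), 10, 0, 9.9999)
  cls <- classifyResponse(g, r, threshold = 10)
  expect_false(any(is.na(cls)))
  manual <- ifelse(g > 10 & r > 10, "continued",
            ifelse(g > 10, "new", ifelse(r > 10, "past", "none")))
  expect_equal(as.character(cls), manual)
})

test_that("profiles are invariant to rescaling the green channel", {
  geom <- smallGeometry()
  cells <- buildEmbryo(geom, cellSpacing = 4, seed = 5)
  states <- cbind(green = 20 * cells$noise_factor *
                    (cells$dv_frac < 0.6 | cells$tissue != "spinal_cord"),
                  red = 0)
  st <- renderStack(states, cells, geom, noise = noiseOff(gain = 30),
                    convertedApWindow = c(30, 70))
  profileOf <- function(stack) {
    ref <- unconvertedReference(stack)
    dvProfile(transverseSection(stack, 50, "green"),
              canalPosition(stack), ref$reference,
              background = ref$background)
  }
  p1 <- profileOf(st)
  st3 <- st
  st3@data[, , , 1] <- st3@data[, , , 1] * 3
  p3 <- profileOf(st3)
  expect_equal(profileValues(p3), profileValues(p1), tolerance = 1e-9)
})

test_that("per-cell histories are recovered from rendered stacks", {
  geom <- smallGeometry()
  cells <- buildEmbryo(geom, cellSpacing = 4, seed = 8,
                       heterogeneitySigma = 0)
  # step-function histories planted by DV position:
  # ventral third past-only, middle continued, dorsal third new-only;
  # everything outside the cord stays continuously active
  field <- function(c, t) {
    on <- rep(TRUE, nrow(c))
    cord <- c$tissue == "spinal_cord"
    on[cord & c$dv_frac < 1 / 3] <- t < 30
    on[cord & c$dv_frac >= 2 / 3] <- t >= 30
    as.numeric(on)
  }
  truth <- with(cells, ifelse(tissue != "spinal_cord", "continued",
                ifelse(dv_frac < 1 / 3, "past",
                ifelse(dv_frac >= 2 / 3, "new", "continued"))))
  ev <- ConversionEvent(t0 = 30, apWindow = c(25, 75))
  states <- simulateReporter(cells, field, ev, tImage = 36,
                             params = ReporterParams(), tStart = 20)
  st <- renderStack(states[, c("green", "red")], cells, geom,
                    optics = OpticsModel(backgroundOffset = 2),
                    noise = NoiseModel(photonGain = 200,
                                       readNoiseSigma = 1, seed = 4),
                    convertedApWindow = c(25, 75))
  ref <- unconvertedReference(st)
  vs <- st@voxelSize
  iz <- pmin(pmax(floor(cells$ml_um / vs[1]) + 1, 1), dim(st@data)[1])
  iy <- pmin(pmax(floor(cells$dv_um / vs[2]) + 1, 1), dim(st@data)[2])
  ix <- pmin(pmax(floor(cells$ap_um / vs[3]) + 1, 1), dim(st@data)[3])
  lin <- cbind(iz, iy, ix)
  gN <- pmax(st@data[, , , 1][lin] - ref$background, 0) /
    ref$reference * 100
  rN <- pmax(st@data[, , , 2][lin] - ref$background, 0) /
    ref$reference * 100
  conv <- states$converted
  cls <- classifyResponse(gN[conv], rN[conv], threshold = 10)
  agree <- mean(as.character(cls) == truth[conv])
  expect_gte(agree, 0.95)
})

test_that("the spatiotemporal map reproduces the three phases", {
  geom <- smallGeometry()
  mk <- function(t0, seed) simulatePhreshStack(
    t0, pathway = "hh", geometry = geom, cellSpacing = 4,
    noise = NoiseModel(photonGain = 100, readNoiseSigma = 1),
    seed = seed, dt = 0.1,
    params = ReporterParams(synthesisRate = 20, decayRate = log(2) / 24))
  cohort <- list(`24` = mk(24, 1), `54` = mk(54, 2), `72` = mk(72, 3))
  map <- buildMap(cohort)
  expect_s4_class(map, "SpatiotemporalMap")
  extents <- vapply(map@dvProfiles, aboveHalfMaxExtent, numeric(1))
  # wide activation-phase response narrows by mid-consolidation
  expect_gt(extents[1], extents[2])
  # by late termination most of the cord is past/none
  lateFrac <- map@classFractions[3, ]
  expect_gt(lateFrac[["past"]] + lateFrac[["none"]], 0.5)
  expect_error(buildMap(list()), "empty")
  # a single-embryo cohort equals that embryo's own profiles
  one <- buildMap(list(`24` = cohort[[1]]))
  two <- buildMap(list(`24` = list(cohort[[1]], cohort[[1]])))
  expect_equal(profileValues(one@dvProfiles[[1]]),
               profileValues(two@dvProfiles[[1]]))
})
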