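test_that("segmentation honours its contract in fixed and otsu modes", {
  sec <- matrix(0, 20, 20)
  cord <- matrix(TRUE, 20, 20)
  expect_equal(sum(segmentExpression(sec, cord, "otsu")), 0)
  sec[3:8, ] <- 100
  fixed <- segmentExpression(sec, cord, "fixed", threshold = 50)
  expect_identical(fixed, sec >= 50)
  expect_error(segmentExpression(sec, matrix(FALSE, 20, 20)), "empty")
  expect_error(segmentExpression(sec, cord, "fixed"), "threshold")
})

test_that("otsu segmentation recovers a planted noisy rectangle", {
  set.seed(13)
  sec <- matrix(rnorm(40 * 30, 10, 3), 40, 30)
  truthMask <- matrix(FALSE, 40, 30)
  truthMask[10:25, 8:22] <- TRUE
  sec[truthMask] <- rnorm(sum(truthMask), 100, 10)
  cord <- matrix(TRUE, 40, 30)
  dom <- segmentExpression(sec, cord, "otsu")
  iou <- sum(dom & truthMask) / sum(dom | truthMask)
  expect_gte(iou, 0.9)
})

test_that("the mass-conserving threshold matches total relative mass", {
  r <- matrix(0, 10, 10)
  r[1:3, ] <- 1                     # 30 pixels of unit mass
  cord <- matrix(TRUE, 10, 10)
  dom <- segmentExpression(r, cord, "mass")
  expect_equal(sum(dom), 30)
  expect_true(all(which(dom) %in% which(r == 1)))
})

test_that("domain percentage is an exact pixel ratio", {
  cord <- matrix(TRUE, 10, 10)
  dom <- matrix(FALSE, 10, 10); dom[1:5, 1:5] <- TRUE
  expect_equal(domainPercentage(dom, cord)$pct, 25)
  expect_equal(domainPercentage(matrix(FALSE, 10, 10), cord)$pct, 0)
  expect_equal(domainPercentage(cord, cord)$pct, 100)
  outside <- dom; outside[1, 1] <- TRUE
  shrunk <- cord; shrunk[1, 1] <- FALSE
  expect_error(domainPercentage(outside, shrunk), "outside the cord")
})

test_that("domain percentage ignores intensity rescaling with a fixed mask", {
  set.seed(2)
  sec <- matrix(runif(100, 0, 50), 10, 10)
  cord <- matrix(TRUE, 10, 10)
  m1 <- segmentExpression(sec, cord, "fixed", threshold = 25)
  m2 <- segmentExpression(sec * 4, cord, "fixed", threshold = 100)
  expect_identical(domainPercentage(m1, cord), domainPercentage(m2, cord))
})

test_that("embryo summaries average sections and flag unusual counts", {
  s <- summarizeEmbryo(c(20, 30, 25, 25, 22, 28), embryoId = "e1")
  expect_equal(s$mean_pct, 25)
  expect_equal(s$n_sections, 6)
  expect_warning(one <- summarizeEmbryo(37, embryoId = "e2"), "1 sections")
  expect_equal(one$mean_pct, 37)
  expect_warning(twelve <- summarizeEmbryo(rep(10, 12)), "12 sections")
  expect_equal(twelve$mean_pct, 10)
})

test_that("control-max normalization behaves exactly as defined", {
  n <- normalizeToControlMax(40, c(80, 80))
  expect_equal(n$pct_normalized, 50)
  # normalized control group mean is exactly 100
  ctrl <- c(61.2, 78.9, 70.4, 66.6)
  expect_equal(mean(normalizeToControlMax(ctrl, ctrl)$pct_normalized), 100)
  # values may exceed 100
  expect_equal(normalizeToControlMax(120, c(60, 100))$pct_normalized, 150)
  expect_error(normalizeToControlMax(1, numeric(0)), "empty")
  expect_error(normalizeToControlMax(1, c(0, 0)), "> 0")
  # scale-free: a common factor cancels
  v <- c(30, 50); ctrl2 <- c(55, 65)
  expect_equal(normalizeToControlMax(v * 7, ctrl2 * 7)$pct_normalized,
               normalizeToControlMax(v, ctrl2)$pct_normalized)
})

test_that("timecourse reductions are 100 minus the normalized mean", {
  df <- data.frame(
    marker = rep(c("ptc2", "sox2"), each = 4),
    condition = rep(c("DMSO", "DMSO", "LY", "LY"), 2),
    timepoint_h = rep(c(0, 0, 1, 1), 2),
    pct_normalized = c(98, 102, 60, 52, 99, 101, 88, 92))
  red <- timecourseReduction(df, control = "DMSO")
  expect_equal(red$reduction_pct[red$marker == "ptc2"], 44)
  expect_equal(red$reduction_pct[red$marker == "sox2"], 10)
  same <- within(df, pct_normalized[condition == "LY"] <- 100)
  expect_equal(timecourseReduction(same)$reduction_pct, c(0, 0),
               ignore_attr = TRUE)
  expect_error(timecourseReduction(df, control = "water"), "missing")
})

test_that("relative expression reads ~1 inside a planted domain", {
  geom <- smallGeometry()
  cells <- buildEmbryo(geom, cellSpacing = 4, seed = 3)
  st <- paintMarkers(cells, c("ptc2", "counterstain"), c(0.5, 1),
                     amplitude = 40, geometry = geom, edgeSoftness = 4)
  stack <- renderStack(st, cells, geom, noise = NoiseModel(seed = 5),
                       channels = c("ptc2", "counterstain"))
  mask <- cordSectionMask(stack)
  rel <- relativeExpression(transverseSection(stack, 50, "ptc2"),
                            transverseSection(stack, 50, "counterstain"))
  rows <- which(apply(mask, 1, any))
  deep <- rel[rows[3:6], which(apply(mask, 2, any))]
  expect_equal(mean(deep), 1, tolerance = 0.15)
  far <- rel[rows[(length(rows) - 5):(length(rows) - 2)],
             which(apply(mask, 2, any))]
  expect_lt(mean(far), 0.1)
})

test_that("the rendered pipeline recovers planted domain fractions", {
  geom <- SpinalCordGeometry()
  cells <- buildEmbryo(geom, cellSpacing = 2.5, seed = 6)
  planted <- c(ptc2 = 0.6, sox2 = 0.5, olig2 = 0.15)
  st <- paintMarkers(cells, c(names(planted), "counterstain"),
                     c(planted, 1), geometry = geom, edgeSoftness = 2.5)
  stack <- renderStack(st, cells, geom, noise = noiseOff(gain = 50),
                       channels = c(names(planted), "counterstain"))
  mask <- cordSectionMask(stack)
  for (m in names(planted)) {
    pct <- mean(vapply(c(60, 125, 190), function(i) {
      rel <- relativeExpression(transverseSection(stack, i, m),
                                transverseSection(stack, i, "counterstain"),
                                background = 5)
      domainPercentage(segmentExpression(rel, mask, "mass"), mask)$pct
    }, numeric(1)))
    expect_equal(pct, 100 * planted[[m]], tolerance = 2.5)
  }
})

test_that("cohort ordering follows the planted trajectories", {
  res <- notchInhibitionTimecourse(timepoints = c(1, 2),
                                   markers = c("ptc2", "sox2"),
                                   nEmbryos = 3, nSections = 4, seed = 2)
  emb <- res$embryos
  gm <- function(m, cond) mean(emb$mean_pct[emb$marker == m &
                                              emb$condition == cond])
  # planted: ptc2 falls before sox2, both roughly halve by 2 h
  expect_gt(gm("ptc2", "DMSO"), gm("ptc2", "LY411575_1h"))
  expect_gt(gm("ptc2", "LY411575_1h"), gm("ptc2", "LY411575_2h"))
  expect_gt(gm("sox2", "LY411575_1h"), gm("sox2", "LY411575_2h"))
  red <- res$reductions
  r <- function(m, tp) red$reduction_pct[red$marker == m &
                                           red$timepoint_h == tp]
  expect_gt(r("ptc2", 1), r("sox2", 1))
})
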