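test_that("default day-3 geometry places T+ ground truth at radii 250-350 um", {
  ci <- generateColonyImage(disruption = 0, noiseSd = 0, seed = 1)
  tr <- truth(ci)
  ij <- which(tr$tMask, arr.ind = TRUE)
  r <- sqrt((ij[, 2] - tr$centroid[1])^2 + (ij[, 1] - tr$centroid[2])^2) *
    pixelSize(ci)
  expect_gte(min(r), 250 - pixelSize(ci))  # discretization: one pixel slack
  expect_lte(max(r), 350 + pixelSize(ci))
  expect_equal(tr$annulusInner, 250)
  expect_equal(tr$annulusOuter, 350)
  # micropattern area of the 1-mm circle
  expect_equal(colonyArea(colonyGeometry()), pi * 500^2)
})

test_that("generation is a pure function of its arguments including seed", {
  a <- generateColonyImage(noiseSd = 10, seed = 7)
  b <- generateColonyImage(noiseSd = 10, seed = 7)
  expect_identical(intensity(a), intensity(b))
  expect_identical(truth(a), truth(b))
  s1 <- generateDoseSeries(coarseGeometry(), nPerGroup = 2, noiseSd = 5,
                           seed = 3)
  s2 <- generateDoseSeries(coarseGeometry(), nPerGroup = 2, noiseSd = 5,
                           seed = 3)
  expect_identical(intensity(s1[[5]]), intensity(s2[[5]]))
  v1 <- generateViabilityData(viabilityDesign(), seed = 11)
  expect_identical(v1, generateViabilityData(viabilityDesign(), seed = 11))
})

test_that("disrupted annulus follows the widen/inward model and the closed form", {
  m <- disruptionModel(widenCoeff = 1, inwardCoeff = 150)
  ci <- generateColonyImage(disruption = 1, model = m, noiseSd = 0, seed = 2)
  tr <- truth(ci)
  # centre-line radius 300 - 150 = 150, half-width 50 * 2 = 100
  expect_equal(tr$annulusInner, 50)
  expect_equal(tr$annulusOuter, 250)
  ij <- which(tr$tMask, arr.ind = TRUE)
  r <- sqrt((ij[, 2] - tr$centroid[1])^2 + (ij[, 1] - tr$centroid[2])^2) *
    pixelSize(ci)
  expect_lt(abs(mean(r) - annulusMeanRadius(50, 250)), 5)
})

test_that("annulus bound violations raise parameter errors naming the bound", {
  m <- disruptionModel(widenCoeff = 0, inwardCoeff = 300)
  expect_error(generateColonyImage(disruption = 1, model = m),
               "past the colony centroid")
  m2 <- disruptionModel(widenCoeff = 5, inwardCoeff = 0)
  expect_error(generateColonyImage(disruption = 1, model = m2),
               "past the colony edge")
})

test_that("dose series has 4 x n records and only disrupted groups shift", {
  m <- disruptionModel(disruptionByGroup = c(control = 0, low = 0,
                                             medium = 0, high = 1))
  cs <- generateDoseSeries(coarseGeometry(), model = m, nPerGroup = 3,
                           noiseSd = 0, seed = 5)
  expect_equal(length(cs), 12)
  info <- colonyInfo(cs)
  expect_setequal(unique(info$group), c("control", "low", "medium", "high"))
  expect_equal(table(info$group)[["high"]], 3)
  # ground-truth annulus statistics shift only in the high group
  inner <- vapply(seq_len(length(cs)), function(i) {
    tr <- truth(cs[[i]])
    tr$annulusInner / tr$colonyRadius  # jitter-invariant, scaled
  }, numeric(1))
  expect_true(all(abs(inner[info$group != "high"] - 250 / 500) < 1e-9))
  expect_true(all(inner[info$group == "high"] < 0.3))
  expect_error(generateDoseSeries(coarseGeometry(), nPerGroup = 1),
               "ANOVA")
})

test_that("dose series disruption model validity is enforced", {
  expect_error(disruptionModel(disruptionByGroup =
    c(control = 0.2, low = 0.2, medium = 0.5, high = 1)), "control")
  expect_error(disruptionModel(disruptionByGroup =
    c(control = 0, low = 0.5, medium = 0.3, high = 1)), "monotone")
})

test_that("viability tables follow the 4PL with vehicle normalization", {
  d <- viabilityDesign(noiseSd = 0, top = 1, bottom = 0, ic50 = 100,
                       hill = 1, cMax = 100 * 5^4)
  tab <- generateViabilityData(d, seed = 1)
  expect_equal(tab$viability[tab$concentration == 100], rep(0.5, 3))
  expect_equal(tab$viability[tab$concentration == 0], rep(1, 3))
  # monotone non-increasing in concentration (hill > 0, no noise)
  means <- tapply(tab$viability, tab$concentration, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) <= 0))
  # (8 + 1) concentrations x 3 replicates
  noisy <- generateViabilityData(viabilityDesign(noiseSd = 0.05), seed = 2)
  expect_equal(nrow(noisy), 27)
  expect_error(viabilityDesign(nDoses = 8, cMax = -1), "doses")
})

test_that("time-lapse front moves linearly with ground truth attached", {
  still <- generateTimelapse(40, 4, frontStartPx = 10,
                             frontVelocityPxPerFrame = 0)
  expect_identical(still$stack[, , 1], still$stack[, , 4])
  tl <- generateTimelapse(40, 6, frontStartPx = 10,
                          frontVelocityPxPerFrame = 2)
  expect_equal(tl$edgePositions[6], 20)  # frame index 5, start 10, v 2
  expect_error(generateTimelapse(20, 10, frontStartPx = 10,
                                 frontVelocityPxPerFrame = 2),
               "exits the frame")
})

test_that("ground-truth masks make segmentation accuracy measurable", {
  # at noise <= 10% of the T+ intensity, Otsu recovers the ring to
  # Jaccard >= 0.9
  ci <- generateColonyImage(noiseSd = 20, seed = 9)
  seg <- segmentColony(ci)
  tr <- truth(ci)
  jac <- sum(tMask(seg) & tr$tMask) / sum(tMask(seg) | tr$tMask)
  expect_gte(jac, 0.9)
})
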