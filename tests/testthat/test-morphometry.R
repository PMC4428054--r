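test_that("colony detection recovers the disk, its centroid, and translates", {
  ci <- generateColonyImage(noiseSd = 0, seed = 1)
  seg <- detectColony(ci)
  areaPx <- sum(colonyMask(seg))
  expect_lt(abs(areaPx * pixelSize(ci)^2 - pi * 500^2) / (pi * 500^2), 0.02)
  ctr <- (dim(intensity(ci)) + 1) / 2
  expect_lt(max(abs(centroid(seg) - ctr)), 1)

  shifted <- generateColonyImage(noiseSd = 0, seed = 1,
                                 centerOffset = c(30, 0))
  seg2 <- detectColony(shifted)
  expect_lt(abs(centroid(seg2)[1] - (ctr[1] + 30)), 1)
  expect_lt(abs(centroid(seg2)[2] - ctr[2]), 1)
  expect_equal(sum(colonyMask(seg2)), areaPx)

  flat <- new("ColonyImage", intensity = matrix(77, 50, 50), pixelSize = 2,
              metadata = list(), truth = list())
  expect_error(detectColony(flat), "no colony found")
})

test_that("T+/T- split adapts its threshold and flags absent patterns", {
  ci <- generateColonyImage(noiseSd = 5, seed = 4)
  seg <- segmentColony(ci)
  jac <- sum(tMask(seg) & truth(ci)$tMask) /
    sum(tMask(seg) | truth(ci)$tMask)
  expect_gte(jac, 0.9)
  # threshold lies within the colony intensity range
  expect_gt(segThreshold(seg), min(intensity(ci)[colonyMask(seg)]))
  expect_lt(segThreshold(seg), max(intensity(ci)[colonyMask(seg)]))

  # Otsu invariance to foreground level: a brighter ring yields the same mask
  dim200 <- generateColonyImage(colonyGeometry(tIntensity = 200),
                                noiseSd = 0, seed = 1)
  bright <- generateColonyImage(colonyGeometry(tIntensity = 400),
                                noiseSd = 0, seed = 1)
  expect_identical(tMask(segmentColony(dim200)),
                   tMask(segmentColony(bright)))

  # a colony with no T+ signal: flagged, not an error
  geoFlat <- colonyGeometry()
  blank <- generateColonyImage(geoFlat, noiseSd = 0, seed = 1)
  img <- intensity(blank)
  img[truth(blank)$tMask] <- geoFlat@colonyBaselineIntensity
  flatCi <- new("ColonyImage", intensity = img, pixelSize = 2,
                metadata = list(), truth = truth(blank))
  segF <- segmentTpos(flatCi, detectColony(flatCi))
  expect_true(segF@noTpos)
  expect_true(all(is.na(extractFeatures(flatCi, segF))))
})

test_that("radial features match closed-form annulus and disk integrals", {
  ci <- generateColonyImage(noiseSd = 0, seed = 1)
  seg <- truthSegmentation(ci)
  f <- extractFeatures(ci, seg)
  # uniform annulus a = 250, b = 350 in an R = 500 colony
  expect_lt(abs(f[["mean_dist_centroid"]] - annulusMeanRadius(250, 350)) /
              annulusMeanRadius(250, 350), 0.01)
  expect_lt(abs(f[["mean_dist_outline"]] - (500 - annulusMeanRadius(250, 350))) /
              (500 - annulusMeanRadius(250, 350)), 0.01)
  expect_lt(abs(f[["mean_rho"]] - annulusMeanRadius(250, 350) / 500), 0.01)

  # T+ = whole disk: mean distance 2R/3 to centroid, R/3 to outline
  segDisk <- seg
  segDisk@tMask <- colonyMask(seg)
  fd <- extractFeatures(ci, segDisk)
  expect_equal(fd[["area_fraction"]], 1)
  expect_lt(abs(fd[["mean_dist_centroid"]] - 2 * 500 / 3) / (2 * 500 / 3), 0.01)
  expect_lt(abs(fd[["mean_dist_outline"]] - 500 / 3) / (500 / 3), 0.01)
})

test_that("features are invariant under 90-degree rotation and deterministic", {
  ci <- generateColonyImage(noiseSd = 5, seed = 6)
  f1 <- extractFeatures(ci, segmentColony(ci))
  rot <- new("ColonyImage", intensity = rot90(intensity(ci)), pixelSize = 2,
             metadata = list(), truth = list())
  f2 <- extractFeatures(rot, segmentColony(rot))
  # rotation permutes the pixel lattice exactly: radial and intensity
  # statistics agree to numerical precision (well within the 1% contract)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-8)
  # determinism: same image in, same vector out
  expect_identical(f1, extractFeatures(ci, segmentColony(ci)))
})

test_that("lengths scale with pixel size, dimensionless features do not", {
  ci <- generateColonyImage(noiseSd = 5, seed = 8)
  seg <- segmentColony(ci)
  f1 <- extractFeatures(ci, seg, pixelSize = 2)
  f2 <- extractFeatures(ci, seg, pixelSize = 4)
  expect_equal(f2[["area_T"]], 4 * f1[["area_T"]])
  expect_equal(f2[["mean_dist_centroid"]], 2 * f1[["mean_dist_centroid"]])
  expect_equal(f2[["mean_dist_outline"]], 2 * f1[["mean_dist_outline"]])
  dimless <- setdiff(morphFeatureNames(),
                     c("area_T", "mean_dist_centroid", "mean_dist_outline"))
  expect_equal(f1[dimless], f2[dimless])
})

test_that("quantile ordering and histogram bounds hold on random masks", {
  set.seed(31)
  geo <- coarseGeometry()
  for (i in 1:5) {
    d <- runif(1, 0, 0.8)
    ci <- generateColonyImage(geo, disruption = d, noiseSd = 20,
                              seed = 100 + i)
    f <- extractFeatures(ci, segmentColony(ci, minArea = COARSE_MIN_AREA))
    expect_lte(f[["inner_edge_rho"]], f[["median_rho"]])
    expect_lte(f[["median_rho"]], f[["outer_edge_rho"]])
    expect_gte(f[["iqr_rho"]], 0)
    expect_gte(f[["entropy_rho"]], 0)
    expect_lte(f[["entropy_rho"]], log2(64))
    expect_gte(f[["energy_rho"]], 1 / 64)
    expect_lte(f[["energy_rho"]], 1)
    expect_gte(f[["n_components"]], 1)
  }
})

test_that("feature tables carry keys and QC flags", {
  cs <- generateDoseSeries(coarseGeometry(), nPerGroup = 2, noiseSd = 5,
                           seed = 12)
  ft <- extractFeatureTable(cs, minArea = COARSE_MIN_AREA)
  expect_equal(nrow(ft), 8)
  expect_true(all(c("compound", "group", "replicate", "qc_no_tpos",
                    morphFeatureNames()) %in% names(ft)))
  expect_false(any(ft$qc_no_tpos))
})
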