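test_that("auto filtering drops features that correlate with nothing", {
  # one feature replaced by an independent uniform draw among latent-driven
  # features: dropped in >= 95% of seeds
  hits <- 0
  for (s in 1:50) {
    ft <- latentFeatureTable(n = 30, randomCols = "kurt_rho", seed = s)
    filt <- filterExtraneous(ft, mode = "auto", threshold = 0.4)
    if ("kurt_rho" %in% filt$dropped$feature) hits <- hits + 1
  }
  expect_gte(hits, 48)  # 95% of 50 seeds

  # empty manual list keeps all 19; threshold 0 drops nothing
  ft <- latentFeatureTable(n = 30, seed = 1)
  expect_length(filterExtraneous(ft, mode = "manual_list")$retained, 19)
  expect_length(filterExtraneous(ft, mode = "auto", threshold = 0)$retained,
                19)
  expect_error(filterExtraneous(ft[1:4, ]), "6 colonies")
})

test_that("retained + dropped partition the 19-feature roster", {
  ft <- latentFeatureTable(n = 30, randomCols = c("kurt_rho", "energy_rho"),
                           seed = 2)
  filt <- filterExtraneous(ft, mode = "auto", threshold = 0.4)
  expect_equal(length(filt$retained) + nrow(filt$dropped), 19)
  expect_length(intersect(filt$retained, filt$dropped$feature), 0)
})

test_that("correlation distance groups duplicates and splits negations", {
  set.seed(7)
  n <- 20
  base <- rnorm(n)
  other <- 2 * base + rnorm(n, sd = 0.01)
  ft <- latentFeatureTable(n = n, seed = 7)
  ft$mean_rho <- base
  ft$median_rho <- base          # identical column: distance 0
  ft$inner_edge_rho <- -base     # negation: distance 2
  ft$outer_edge_rho <- other
  cl <- clusterFeatures(ft, k = 2,
                        retained = c("mean_rho", "median_rho",
                                     "inner_edge_rho", "outer_edge_rho"))
  a <- clusterAssignment(cl)
  expect_equal(a[["mean_rho"]], a[["median_rho"]])
  expect_false(a[["mean_rho"]] == a[["inner_edge_rho"]])

  # hand-computed 3-feature linkage: f1 ~ f2 (r ~ 1, d ~ 0), f3 = -f1
  # (d ~ 2): complete linkage merges {f1, f2} at ~0 and f3 joins at ~2,
  # so k = 2 cuts into {f1, f2} vs {f3}
  d <- 1 - cor(cbind(base, other, -base))
  expect_lt(d[1, 2], 0.01)
  expect_gt(d[1, 3], 1.99)

  # k = number of features: all singletons
  cl4 <- clusterFeatures(ft, k = 4,
                         retained = c("mean_rho", "inner_edge_rho",
                                      "outer_edge_rho", "area_T"))
  expect_equal(sort(unname(clusterAssignment(cl4))), 1:4)
})

test_that("clustering is invariant to affine feature rescaling and trees nest", {
  ft <- latentFeatureTable(n = 30, seed = 9)
  cl1 <- clusterFeatures(ft, k = 7)
  ft2 <- ft
  ft2$area_T <- 100 * ft2$area_T - 5
  ft2$mean_rho <- ft$mean_rho * 3 + 2
  cl2 <- clusterFeatures(ft2, k = 7)
  expect_identical(clusterAssignment(cl1), clusterAssignment(cl2))

  # cutting at k-1 merges exactly two clusters of the k-cut
  cl6 <- clusterFeatures(ft, k = 6)
  tab <- table(clusterAssignment(cl1), clusterAssignment(cl6)[
    names(clusterAssignment(cl1))])
  # each k=7 cluster maps into exactly one k=6 cluster...
  expect_true(all(rowSums(tab > 0) == 1))
  # ...and exactly one k=6 cluster receives two k=7 clusters
  expect_equal(sort(unname(colSums(tab > 0))), c(rep(1, 5), 2))
})

test_that("zero-variance features are excluded with a warning", {
  ft <- latentFeatureTable(n = 20, seed = 3)
  ft$n_components <- 1
  expect_warning(cl <- clusterFeatures(ft, k = 5), "zero-variance")
  expect_false("n_components" %in% cl@retained)
})

test_that("cluster readouts average z-scores within clusters", {
  ft <- latentFeatureTable(n = 24, seed = 4)
  cl <- clusterFeatures(ft, k = 7)
  ro <- clusterReadouts(ft, cl)
  expect_equal(nrow(ro), 24)
  expect_length(grep("^CL", names(ro)), 7)
  # every CL column is centred (z-scores average to 0 over the experiment)
  for (col in grep("^CL", names(ro), value = TRUE))
    expect_lt(abs(mean(ro[[col]])), 1e-10)

  # singleton cluster readout equals the z-scored feature
  asg <- clusterAssignment(cl)
  singles <- names(asg)[asg %in% which(tabulate(asg) == 1)]
  if (length(singles)) {
    feat <- singles[1]
    z <- as.vector(scale(ft[[feat]]))
    expect_equal(ro[[paste0("CL", asg[[feat]])]], z)
  }

  # two perfectly correlated members: readout equals either member's z-score
  ft2 <- latentFeatureTable(n = 24, seed = 5)
  ft2$median_rho <- 3 * ft2$mean_rho + 1
  cl2 <- clusterFeatures(ft2, k = 7)
  a2 <- clusterAssignment(cl2)
  expect_equal(a2[["mean_rho"]], a2[["median_rho"]])
  members <- names(a2)[a2 == a2[["mean_rho"]]]
  if (identical(sort(members), sort(c("mean_rho", "median_rho")))) {
    ro2 <- clusterReadouts(ft2, cl2)
    expect_equal(ro2[[paste0("CL", a2[["mean_rho"]])]],
                 as.vector(scale(ft2$mean_rho)))
  }
})

test_that("the linkage tree serializes to Newick", {
  ft <- latentFeatureTable(n = 20, seed = 6)
  cl <- clusterFeatures(ft, k = 7)
  nwk <- linkageNewick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, cl@retained)
})

test_that("position features shift monotonically with dose", {
  m <- disruptionModel(inwardCoeff = 150, widenCoeff = 0.5,
                       disruptionByGroup = c(control = 0, low = 0.3,
                                             medium = 0.6, high = 0.9))
  cs <- generateDoseSeries(coarseGeometry(), model = m, nPerGroup = 4,
                           noiseSd = 5, seed = 21)
  ft <- extractFeatureTable(cs, minArea = COARSE_MIN_AREA)
  # n_components can be constant in a clean series; its exclusion is expected
  cl <- suppressWarnings(clusterFeatures(ft, k = 7))
  ro <- suppressWarnings(clusterReadouts(ft, cl))
  posCl <- paste0("CL", clusterAssignment(cl)[["mean_dist_outline"]])
  mns <- tapply(ro[[posCl]], factor(ro$group, c("control", "low", "medium",
                                                "high")), mean)
  # inward displacement grows the outline distance monotonically
  expect_true(all(diff(mns) > 0) || all(diff(mns) < 0))
})
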