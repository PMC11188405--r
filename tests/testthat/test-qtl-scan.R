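pop <- tiny_pop(seed = 5, n_lines = 150)
grid <- build_grid(pop$map, step = 1)
P <- expected_genotype_matrix(pop$geno, pop$map, grid)

test_that("scan LOD equals the single-marker regression oracle at typed markers", {
  set.seed(21)
  at <- which(!is.na(grid$at_marker))
  for (k in 1:5) {
    y <- rnorm(nrow(pop$geno))
    names(y) <- rownames(pop$geno)
    prof <- interval_mapping_scan(y, pop$geno, pop$map, grid, P = P)
    for (j in at[seq(1, length(at), by = 13)]) {
      expect_lt(abs(prof$lod[j] -
                      single_marker_lod(y, pop$geno[, grid$at_marker[j]])),
                1e-8)
    }
  }
})

test_that("LOD is invariant under affine transformation of the trait", {
  set.seed(22)
  y <- rnorm(nrow(pop$geno)) + pop$geno[, "M_chr1_020"] * 0.8
  names(y) <- rownames(pop$geno)
  p1 <- interval_mapping_scan(y, pop$geno, pop$map, grid, P = P)
  p2 <- interval_mapping_scan(3.7 * y - 11, pop$geno, pop$map, grid, P = P)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
})

test_that("a trait equal to a marker code saturates at that marker", {
  y <- pop$geno[, "M_chr2_015"]
  names(y) <- rownames(pop$geno)
  prof <- interval_mapping_scan(y, pop$geno, pop$map, grid, P = P)
  j <- which(grid$at_marker == "M_chr2_015")
  expect_true(prof$saturated[j])
  expect_equal(prof$r2[j], 1, tolerance = 1e-9)
  expect_equal(which.max(prof$lod), j)
})

test_that("degenerate traits are rejected", {
  expect_error(interval_mapping_scan(rep(1, nrow(pop$geno)), pop$geno,
                                     pop$map, grid, P = P),
               "zero-variance")
  y <- rnorm(nrow(pop$geno)); y[-(1:5)] <- NA
  expect_error(interval_mapping_scan(y, pop$geno, pop$map, grid, P = P),
               "fewer than 10")
})

test_that("forward-BIC cofactor selection recovers a strong planted marker", {
  expect_identical(select_cofactors(rnorm(nrow(pop$geno)), pop$geno, pop$map,
                                    grid, max_cofactors = 0, P = P),
                   character())
  hits <- 0; null_empty <- 0
  truth_cm <- pop$map$cM[pop$map$marker == "M_chr1_020"]
  for (s in 1:20) {
    set.seed(100 + s)
    g <- pop$geno[, "M_chr1_020"]
    y <- sqrt(0.5) * as.numeric(scale(g)) + sqrt(0.5) * rnorm(length(g))
    names(y) <- rownames(pop$geno)
    sel <- select_cofactors(y, pop$geno, pop$map, grid, P = P)
    if (length(sel)) {
      first <- pop$map[pop$map$marker == sel[1], ]
      if (first$chrom == "chr1" && abs(first$cM - truth_cm) <= 5) hits <- hits + 1
    }
    sel0 <- select_cofactors(rnorm(length(g)), pop$geno, pop$map, grid, P = P)
    if (length(sel0) == 0) null_empty <- null_empty + 1
  }
  expect_gte(hits, 18)        # >= 90% of sims find the driver first
  expect_gte(null_empty, 18)  # EBIC admits no marker in >= 90% of null sims
})

test_that("CIM with no cofactors reduces to interval mapping", {
  set.seed(31)
  y <- rnorm(nrow(pop$geno))
  names(y) <- rownames(pop$geno)
  expect_equal(cim_scan(y, pop$geno, pop$map, grid, cofactors = character(), P = P),
               interval_mapping_scan(y, pop$geno, pop$map, grid, P = P))
})

test_that("the CIM window keeps a local cofactor from absorbing its own QTL", {
  wins <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    g <- pop$geno[, "M_chr3_025"]
    y <- sqrt(0.25) * as.numeric(scale(g)) + sqrt(0.75) * rnorm(length(g))
    names(y) <- rownames(pop$geno)
    j <- which(grid$at_marker == "M_chr3_025")
    lod_w10 <- cim_scan(y, pop$geno, pop$map, grid,
                        cofactors = "M_chr3_025", window = 10, P = P)$lod[j]
    lod_w0 <- cim_scan(y, pop$geno, pop$map, grid,
                       cofactors = "M_chr3_025", window = 0, P = P)$lod[j]
    if (lod_w10 >= lod_w0 - 1e-9) wins <- wins + 1
  }
  expect_equal(wins, 10)
})

test_that("permutation thresholds are reproducible and honour quantile bounds", {
  set.seed(41)
  y <- rnorm(nrow(pop$geno))
  names(y) <- rownames(pop$geno)
  t1 <- permutation_threshold(y, pop$geno, pop$map, grid, n_perm = 50,
                              seed = 9, P = P)
  t2 <- permutation_threshold(y, pop$geno, pop$map, grid, n_perm = 50,
                              seed = 9, P = P)
  expect_identical(t1$threshold, t2$threshold)
  expect_identical(t1$maxima, t2$maxima)
  tmin <- permutation_threshold(y, pop$geno, pop$map, grid, n_perm = 50,
                                alpha = 1, seed = 9, P = P)
  expect_equal(tmin$threshold, min(tmin$maxima))
  expect_error(permutation_threshold(y, pop$geno, pop$map, grid, n_perm = 10, P = P),
               "n_perm")
})

test_that("peak calling merges nearby maxima and respects thresholds", {
  flat <- data.frame(chrom = "c1", pos_cM = 0:20, lod = rep(0.5, 21),
                     r2 = 0.01, additive = 0.1, saturated = FALSE)
  expect_equal(nrow(call_peaks(flat, threshold = 2)), 0)

  two <- data.frame(chrom = "c1", pos_cM = 0:20,
                    lod = c(rep(1, 5), 4, rep(1, 7), 5, rep(1, 7)),
                    r2 = 0.1, additive = 0.2, saturated = FALSE)
  pk <- call_peaks(two, threshold = 3, merge_radius = 10)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_cM, 13)   # the higher of two maxima 8 cM apart
  pk2 <- call_peaks(two, threshold = 3, merge_radius = 5)
  expect_equal(nrow(pk2), 2)

  # equal-LOD tie collapses to the smaller cM
  tie <- data.frame(chrom = "c1", pos_cM = 0:20,
                    lod = c(rep(1, 5), 4, rep(1, 7), 4, rep(1, 7)),
                    r2 = 0.1, additive = 0.2, saturated = FALSE)
  expect_equal(call_peaks(tie, threshold = 3, merge_radius = 10)$peak_cM, 5)
})

test_that("support intervals cover a planted QTL and interpolate bp", {
  found <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    g <- pop$geno[, "M_chr2_020"]
    y <- sqrt(0.25) * as.numeric(scale(g)) + sqrt(0.75) * rnorm(length(g))
    names(y) <- rownames(pop$geno)
    cof <- select_cofactors(y, pop$geno, pop$map, grid, P = P)
    prof <- cim_scan(y, pop$geno, pop$map, grid, cofactors = cof, P = P)
    thr <- permutation_threshold(y, pop$geno, pop$map, grid, n_perm = 100,
                                 seed = s, cofactors = cof, P = P)
    pk <- call_peaks(prof, thr, map = pop$map)
    truth_cm <- pop$map$cM[pop$map$marker == "M_chr2_020"]
    hit <- any(pk$chrom == "chr2" & pk$ci_lo - 1e-9 <= truth_cm &
                 pk$ci_hi + 1e-9 >= truth_cm)
    if (hit) found <- found + 1
    if (nrow(pk)) {
      expect_true(all(pk$ci_lo <= pk$peak_cM & pk$peak_cM <= pk$ci_hi))
      expect_true(all(pk$bp_lo <= pk$bp_hi))
    }
  }
  expect_gte(found, 9)
})
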