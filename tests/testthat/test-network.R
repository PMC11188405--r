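test_that("TOM matches hand-derived values on small graphs", {
  # three nodes, all pairwise adjacency 0.5: TOM = (0.25 + 0.5)/(1 + 1 - 0.5)
  A <- matrix(0.5, 3, 3); diag(A) <- 0
  tom <- tom_similarity(A)
  expect_equal(unname(tom[upper.tri(tom)]), rep(0.5, 3), tolerance = 1e-12)
  # one perfect edge among three nodes
  B <- matrix(0, 3, 3); B[1, 2] <- B[2, 1] <- 1
  tb <- tom_similarity(B)
  expect_equal(tb[1, 2], 1)
  expect_equal(tb[1, 3], 0)
  # isolated nodes: identity
  expect_equal(tom_similarity(matrix(0, 4, 4)), diag(4))
})

test_that("TOM is a similarity: symmetric, unit diagonal, entries in [0,1]", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
    tom <- tom_similarity(A)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
  bad <- matrix(runif(9), 3, 3); diag(bad) <- 0
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft power selection finds a scale-free regime on hub-structured data", {
  bl <- block_expr(c(40, 60, 80, 30, 50), 100, loading = 0.75,
                   n_noise = 300, seed = 3)
  sp <- pick_soft_power(bl$expr)
  expect_gte(sp$fit, 0.8)
  expect_true(sp$power %in% 1:20)
  expect_equal(nrow(sp$report), 20)
  # uncorrelated noise at beta = 1: homogeneous connectivity, poor fit
  noise <- block_expr(integer(0), 60, n_noise = 200, seed = 4)$expr
  fit1 <- suppressWarnings(pick_soft_power(noise, powers = 1)$report$fit)
  expect_lt(fit1, 0.4)
  expect_error(pick_soft_power(noise[1:2, ]), "at least 50")
})

test_that("planted modules are recovered by tree cut and size rule", {
  bl <- block_expr(c(50, 50), 80, loading = 0.8, n_noise = 0, seed = 5)
  ac <- abs(cor(t(bl$expr)))^6; diag(ac) <- 0
  memb <- cluster_modules(tom_similarity(ac), min_size = 30)
  expect_equal(length(unique(memb[memb != 0])), 2)
  expect_equal(ari(memb, bl$labels), 1.0)

  # a 29-member block cannot form a module at min_size 30
  small <- block_expr(29, 80, loading = 0.8, n_noise = 40, seed = 6)
  ac2 <- abs(cor(t(small$expr)))^6; diag(ac2) <- 0
  memb2 <- cluster_modules(tom_similarity(ac2), min_size = 30)
  expect_true(all(memb2 == 0))

  # pure noise stays unassigned
  unassigned <- vapply(1:5, function(s) {
    nz <- block_expr(integer(0), 80, n_noise = 100, seed = 10 + s)$expr
    acn <- abs(cor(t(nz)))^6; diag(acn) <- 0
    mean(cluster_modules(tom_similarity(acn), min_size = 30) == 0)
  }, numeric(1))
  expect_true(all(unassigned >= 0.9))
})

test_that("the eigengene is the leading PC, unit variance, mean-aligned", {
  set.seed(16)
  lines <- sprintf("L%02d", 1:40)
  prof <- rnorm(40)
  X <- matrix(rep(prof, each = 5), 5, 40, dimnames = list(NULL, lines))
  me <- module_eigengene(X)
  expect_equal(as.vector(me), as.numeric(scale(prof)), tolerance = 1e-9)
  expect_equal(stats::sd(me), 1, tolerance = 1e-12)
  expect_equal(attr(me, "var_explained"), 1, tolerance = 1e-12)

  # antisymmetric module {x, -x}: mean profile degenerate, falls back to
  # aligning with the first member
  x <- rnorm(40)
  Xa <- rbind(x, -x); colnames(Xa) <- lines
  mea <- module_eigengene(Xa)
  expect_gt(cor(mea, x), 0.99)

  # maximality: variance captured along the ME beats random unit directions
  Xr <- matrix(rnorm(30 * 40), 30, 40, dimnames = list(NULL, lines))
  Xs <- t(scale(t(Xr)))
  mer <- module_eigengene(Xr)
  proj_var <- function(s) sum((Xs %*% s)^2) / sum(s^2)
  best_rand <- max(vapply(1:2000, function(i) proj_var(rnorm(40)),
                          numeric(1)))
  expect_gte(proj_var(as.numeric(mer)), best_rand)
})

test_that("module merging is greedy on eigengene correlation and terminates", {
  set.seed(17)
  n <- 60; lines <- sprintf("L%02d", 1:n)
  z <- rnorm(n)
  mk_block <- function(zz, size, lam = 0.9) {
    lam * matrix(zz, size, n, byrow = TRUE) +
      sqrt(1 - lam^2) * matrix(rnorm(size * n), size, n)
  }
  # modules 1 and 2 share a latent (ME cor ~ 0.8); module 3 independent
  X <- rbind(mk_block(z, 10), mk_block(z, 10), mk_block(rnorm(n), 10))
  dimnames(X) <- list(sprintf("T%03d", 1:30), lines)
  memb <- stats::setNames(rep(1:3, each = 10), rownames(X))
  ms <- module_set(X, memb)
  expect_gte(cor(ms$eigengenes[, "ME1"], ms$eigengenes[, "ME2"]), 0.75)
  merged <- merge_modules(ms, X, similarity_cut = 0.75)
  expect_equal(ncol(merged$eigengenes), 2)
  expect_equal(nrow(merged$merge_history), 1)
  cc <- cor(merged$eigengenes)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.75))

  # far-apart modules stay untouched
  X2 <- rbind(mk_block(rnorm(n), 10), mk_block(rnorm(n), 10))
  dimnames(X2) <- list(sprintf("T%03d", 1:20), lines)
  ms2 <- module_set(X2, stats::setNames(rep(1:2, each = 10), rownames(X2)))
  expect_equal(nrow(merge_modules(ms2, X2)$merge_history), 0)

  # a correlation chain collapses through iterative recomputation
  z1 <- rnorm(n); z2 <- 0.85 * z1 + sqrt(1 - 0.85^2) * rnorm(n)
  z3 <- 0.85 * z2 + sqrt(1 - 0.85^2) * rnorm(n)
  X3 <- rbind(mk_block(z1, 10, 0.95), mk_block(z2, 10, 0.95),
              mk_block(z3, 10, 0.95))
  dimnames(X3) <- list(sprintf("T%03d", 1:30), lines)
  ms3 <- module_set(X3, stats::setNames(rep(1:3, each = 10), rownames(X3)))
  merged3 <- merge_modules(ms3, X3, similarity_cut = 0.75)
  expect_lte(ncol(merged3$eigengenes), 2)
})

test_that("module-trait association returns exact r and t-distribution p", {
  st <- tiny_study(seed = 20, n_lines = 96)
  ac <- abs(cor(t(st$expr)))^6; diag(ac) <- 0
  memb <- cluster_modules(tom_similarity(ac), min_size = 30)
  ms <- module_set(st$expr, memb)
  # a trait equal to an eigengene correlates perfectly
  traits <- data.frame(me_copy = ms$eigengenes[, 1],
                       noise = rnorm(96),
                       flat = rep(1, 96),
                       row.names = rownames(ms$eigengenes))
  mta <- module_trait_association(ms, traits)
  row1 <- mta[mta$module == "ME1" & mta$trait == "me_copy", ]
  expect_equal(row1$r, 1, tolerance = 1e-12)
  expect_lt(row1$p, 1e-100)
  # constant trait reported as missing, not an error
  expect_true(all(is.na(mta$r[mta$trait == "flat"])))
  # p matches the closed form from r and n
  rn <- mta[mta$trait == "noise" & mta$module == "ME1", ]
  tt <- rn$r * sqrt((rn$n - 2) / (1 - rn$r^2))
  expect_equal(rn$p, 2 * pt(-abs(tt), rn$n - 2), tolerance = 1e-12)
})

test_that("null module-trait correlations stay small at n = 96", {
  st <- tiny_study(seed = 21, n_lines = 96)
  ac <- abs(cor(t(st$expr)))^6; diag(ac) <- 0
  ms <- module_set(st$expr,
                   cluster_modules(tom_similarity(ac), min_size = 30))
  set.seed(99)
  rs <- vapply(1:40, function(i) {
    tr <- data.frame(x = rnorm(96), row.names = rownames(ms$eigengenes))
    abs(module_trait_association(ms, tr)$r[1])
  }, numeric(1))
  expect_gte(mean(rs < 0.3), 0.95)
})

test_that("hard-threshold edges use |r| and respect planted block structure", {
  set.seed(23)
  x <- rnorm(60)
  X <- rbind(a = x, b = -0.9 * x + sqrt(1 - 0.81) * rnorm(60),
             c = rnorm(60))
  colnames(X) <- sprintf("L%02d", 1:60)
  net <- hard_threshold_edges(X, cut = 0.75)
  expect_true(any(net$edges$node_a == "a" & net$edges$node_b == "b"))
  expect_true(all(net$edges$r[net$edges$node_a == "a" &
                                net$edges$node_b == "b"] < 0))
  # independent blocks yield no cross-block edges
  bl <- block_expr(c(20, 20, 20), 80, loading = 0.9, seed = 24)
  net2 <- hard_threshold_edges(bl$expr, cut = 0.75)
  blocks <- bl$labels
  names(blocks) <- rownames(bl$expr)
  cross <- blocks[net2$edges$node_a] != blocks[net2$edges$node_b]
  expect_equal(sum(cross), 0)
  expect_equal(length(net2$degrees), nrow(bl$expr))
  # all-zero correlation structure: no edges at all
  z <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("t", 1:5), NULL))
  expect_equal(nrow(hard_threshold_edges(diag(5) %*% z * 0 + z, cut = 1.01)$edges), 0)
})
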