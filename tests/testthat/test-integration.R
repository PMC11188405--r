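test_that("colocalization combines interval overlap and peak radius, symmetrically", {
  pa <- data.frame(chrom = c("A09", "A09", "C08"), peak_cM = c(150, 30, 150),
                   ci_lo = c(140, 25, 140), ci_hi = c(160, 35, 160),
                   label = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  pb <- data.frame(chrom = c("A09", "C08"), peak_cM = c(155, 150),
                   ci_lo = c(150, 145), ci_hi = c(175, 155),
                   label = c("m1", "m2"), stringsAsFactors = FALSE)
  cl <- colocalize(pa, pb, radius_cM = 10)
  expect_true(any(cl$label_a == "p1" & cl$label_b == "m1"))  # 5 cM apart
  expect_true(any(cl$label_a == "p3" & cl$label_b == "m2"))  # same chrom
  expect_false(any(cl$label_a == "p2"))                      # 125 cM away
  # symmetric
  cl_rev <- colocalize(pb, pa, radius_cM = 10)
  expect_equal(nrow(cl), nrow(cl_rev))
  # interval-overlap branch alone: peaks 22 cM apart but intervals touch
  xa <- data.frame(chrom = "A09", peak_cM = 150, ci_lo = 140, ci_hi = 160,
                   label = "a", stringsAsFactors = FALSE)
  xb <- data.frame(chrom = "A09", peak_cM = 172, ci_lo = 158, ci_hi = 175,
                   label = "b", stringsAsFactors = FALSE)
  ov <- colocalize(xa, xb)
  expect_equal(ov$overlap_type, "interval-overlap")
  expect_equal(ov$distance_cM, 22)
  # a peak colocalizes with itself
  expect_equal(nrow(colocalize(xa, xa)), 1)
  # different chromosome never colocalizes
  xc <- xb; xc$chrom <- "C08"
  expect_equal(nrow(colocalize(xa, xc)), 0)
})

test_that("network QTL shares the scan engine and finds module drivers", {
  st <- tiny_study(seed = 40, n_lines = 200, n_transcripts = 150,
                   hub_r2 = 0.5)
  grid <- build_grid(st$map, 1)
  P <- expected_genotype_matrix(st$geno, st$map, grid)
  ac <- abs(cor(t(st$expr)))^6; diag(ac) <- 0
  ms <- module_set(st$expr, cluster_modules(tom_similarity(ac), min_size = 30))
  expect_gte(ncol(ms$eigengenes), 1)
  nq <- network_qtl(ms, st$geno, st$map, grid, n_perm = 100, seed = 3, P = P)
  hub_cm <- st$truth$eqtl$marker[1]
  hub_pos <- st$map$cM[st$map$marker == hub_cm]
  expect_true(any(nq$chrom == "chr1" & abs(nq$peak_cM - hub_pos) <= 10))
  expect_true(all(grepl("^qModule\\d+_", nq$label)))

  # engine identity: the ME scanned directly gives the same profile
  y <- ms$eigengenes[, 1]
  cof <- select_cofactors(y, st$geno, st$map, grid, P = P)
  prof_direct <- cim_scan(y, st$geno, st$map, grid, cofactors = cof, P = P)
  expect_equal(max(prof_direct$lod),
               max(nq$lod[nq$module == 1]), tolerance = 1e-9)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  universe <- sprintf("g%04d", 1:1000)
  members <- universe[1:20]
  categories <- data.frame(
    transcript = c(universe[11:30], universe[500:979]),
    category = c(rep("hit", 20), rep("flat", 480)),
    stringsAsFactors = FALSE)
  en <- enrichment_fisher(members, categories, universe)
  hit <- en[en$category == "hit", ]
  # overlap 10 of set 20, category 20, universe 1000
  expect_equal(hit$p, hyper_tail(10, 20, 20, 1000), tolerance = 1e-12)
  expect_lt(hit$p, 1e-6)
  # proportionally represented category shows no enrichment
  flat <- en[en$category == "flat", ]
  expect_gte(flat$p, 0.4)
  # category fully inside the set: exact hypergeometric endpoint
  cat2 <- data.frame(transcript = universe[1:10], category = "inside")
  en2 <- enrichment_fisher(members, cat2, universe)
  expect_equal(en2$p, hyper_tail(10, 20, 10, 1000), tolerance = 1e-12)
  # randomized small tables against the oracle
  set.seed(44)
  for (i in 1:25) {
    N <- sample(50:200, 1); S <- sample(5:30, 1); K <- sample(5:30, 1)
    uni <- sprintf("u%03d", 1:N)
    mem <- sample(uni, S)
    ct <- data.frame(transcript = sample(uni, K), category = "c")
    a <- sum(mem %in% ct$transcript)
    expect_equal(enrichment_fisher(mem, ct, uni)$p,
                 hyper_tail(a, S, K, N), tolerance = 1e-12)
  }
  expect_error(enrichment_fisher(members, categories, character()), "universe")
})

test_that("causal subnetwork assembly gates on BH-significant modules", {
  set.seed(46)
  n <- 100; lines <- sprintf("L%03d", 1:n)
  mk <- function(size, z, lam = 0.9) {
    lam * matrix(z, size, n, byrow = TRUE) +
      sqrt(1 - lam^2) * matrix(rnorm(size * n), size, n)
  }
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  X <- rbind(mk(50, z1), mk(80, z2), mk(120, z3))
  dimnames(X) <- list(sprintf("T%04d", 1:250), lines)
  memb <- stats::setNames(rep(1:3, c(50, 80, 120)), rownames(X))
  ms <- module_set(X, memb)
  # trait driven by all three latents: all modules qualify
  traits <- data.frame(
    target = as.numeric(scale(z1 + z2 + z3)) + rnorm(n, sd = 0.4),
    row.names = lines)
  mta <- module_trait_association(ms, traits)
  edges <- hard_threshold_edges(X, cut = 0.75)
  causal <- assemble_causal_network(mta, ms, edges, "target")
  expect_equal(sort(causal$modules), 1:3)
  expect_equal(causal$n_nodes, 250)
  expect_equal(causal$n_components, 3)   # independent modules stay disconnected
  cross <- memb[causal$edges$node_a] != memb[causal$edges$node_b]
  expect_equal(sum(cross), 0)
  # no qualifying module: empty result with a warning
  traits2 <- data.frame(target = rnorm(n), row.names = lines)
  mta2 <- module_trait_association(ms, traits2)
  expect_warning(c2 <- assemble_causal_network(mta2, ms, edges, "target"),
                 "no module")
  expect_equal(c2$n_nodes, 0L)
})

test_that("causal-gene tiers follow the cis/colocalization evidence rules", {
  ms <- list(membership = stats::setNames(c(1L, 1L, 2L), c("gA", "gB", "gC")),
             eigengenes = NULL)
  class(ms) <- "module_set"
  causal <- list(members = c("gA", "gB"))
  records <- data.frame(
    transcript = c("gA", "gB"),
    chrom = c("A09", "C01"),
    peak_cM = c(150, 40), marker = c("mk1", "mk2"),
    marker_bp = c(27e6, 10e6), lod = c(8, 6), r2 = c(0.2, 0.15),
    additive = 0.1, ci_lo = c(145, 35), ci_hi = c(155, 45),
    class = c("cis", "cis"), distance_bp = c(1e6, 2e6),
    stringsAsFactors = FALSE)
  pqtl <- data.frame(chrom = "A09", peak_cM = 148, ci_lo = 140, ci_hi = 158,
                     label = "qtarget_A09_1", stringsAsFactors = FALSE)
  mta <- data.frame(module = c("ME1", "ME2"), trait = "target",
                    r = c(0.6, -0.1), p = c(1e-8, 0.5), n = 96)
  out <- prioritize_causal_genes(causal, ms, records, pqtl, mta, "target")
  expect_equal(nrow(out), 2)
  # gA: cis eQTL colocalizing with the pQTL
  expect_equal(out$tier[out$transcript == "gA"], "cis-colocal")
  expect_equal(out$coloc_pqtl[out$transcript == "gA"], "qtarget_A09_1")
  # gB: cis eQTL on a chromosome with no pQTL -> module evidence only
  expect_equal(out$tier[out$transcript == "gB"], "module-only")
  # gC is outside the causal members and absent
  expect_false("gC" %in% out$transcript)
  # ordering: cis-colocal first
  expect_equal(out$tier[1], "cis-colocal")
  expect_equal(out$module_trait_r[out$transcript == "gA"], 0.6)
})
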