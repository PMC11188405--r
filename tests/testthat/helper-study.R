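# Shared fixtures: small synthetic studies and an adjusted Rand index
# (mclust's implementation serves as the independent clustering oracle).

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# single-module study with a module-driven trait; small enough for unit tests
tiny_study <- function(seed = 1, n_lines = 120, n_transcripts = 200,
                       loading = 0.8, hub_r2 = 0.5, trait_r2 = 0.3) {
  cfg <- sim_config(
    n_lines = n_lines, n_transcripts = n_transcripts,
    modules = list(list(size = 50, chrom = "chr1", cM = 50,
                        loading = loading, hub_r2 = hub_r2)),
    trait_qtl = list(list(type = "module", id = 1, r2 = trait_r2)),
    seed = seed)
  simulate_study(cfg)
}

# plain population (no expression) for scan-engine tests
tiny_pop <- function(seed = 1, n_lines = 150, spacing = 2) {
  cfg <- sim_config(n_lines = n_lines, marker_spacing = spacing,
                    n_transcripts = 60, seed = seed)
  set.seed(seed)
  simulate_dh_population(cfg)
}

# expression matrix of k equicorrelated blocks plus noise transcripts
block_expr <- function(sizes, n_lines, loading = 0.8, n_noise = 0, seed = 1) {
  set.seed(seed)
  rows <- list(); labels <- integer()
  for (b in seq_along(sizes)) {
    z <- rnorm(n_lines)
    rows[[b]] <- loading * matrix(z, sizes[b], n_lines, byrow = TRUE) +
      sqrt(1 - loading^2) * matrix(rnorm(sizes[b] * n_lines), sizes[b])
    labels <- c(labels, rep(b, sizes[b]))
  }
  if (n_noise > 0) {
    rows[[length(rows) + 1]] <- matrix(rnorm(n_noise * n_lines), n_noise)
    labels <- c(labels, rep(0L, n_noise))
  }
  X <- do.call(rbind, rows)
  dimnames(X) <- list(sprintf("T%04d", seq_len(nrow(X))),
                      sprintf("L%03d", seq_len(n_lines)))
  list(expr = X, labels = labels)
}

# independent single-marker regression LOD (the brute-force scan oracle)
single_marker_lod <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ g))^2)
  (n / 2) * log10(rss0 / rss1)
}

# hand-rolled BH step-up (independent of stats::p.adjust)
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# one-sided enrichment p as an explicit hypergeometric sum
hyper_tail <- function(a, set_size, cat_size, universe) {
  kk <- a:min(set_size, cat_size)
  sum(stats::dhyper(kk, cat_size, universe - cat_size, set_size))
}
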