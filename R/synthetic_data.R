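#' Configuration for a synthetic DH systems-genetics study
#'
#' Defines the generative model: a doubled-haploid population segregating two
#' parental alleles across a small genome, co-expression modules driven by a
#' hub-marker genotype through a latent factor, cis-regulated transcripts,
#' and a target trait built from module activity plus direct marker effects
#' and Gaussian noise.  Defaults mirror a 96-line DH design on a compact
#' 3-chromosome genome dense enough for a 4-Mb cis rule to be meaningful.
#'
#' @param n_lines Number of DH lines (default 96).
#' @param chromosomes Data frame: `chrom`, `length_cM`, `length_bp`
#'   (default 3 x 100 cM x 40 Mb).
#' @param marker_spacing Marker spacing in cM (default 2).
#' @param n_transcripts Total transcripts (default 1000).
#' @param modules List of module specs, each
#'   `list(size, chrom, cM, loading, hub_r2)`: `size` member transcripts
#'   loading on a latent factor driven (fraction `hub_r2` of variance) by the
#'   genotype at the marker nearest (`chrom`, `cM`).  The first member is the
#'   module's hub gene, physically placed at that marker (a cis gene).
#' @param cis_genes Data frame `chrom`, `cM`, `r2`: standalone cis-regulated
#'   transcripts (marker effect scaled to the target R-squared).
#' @param trait_qtl List of trait components, each
#'   `list(type = "module"/"marker", id, r2)`; `id` is a module index or
#'   `list(chrom, cM)` / marker name.  R-squared values must sum below 1.
#' @param n_sibling,sibling_share Correlated sibling traits sharing the
#'   target's architecture (defaults 2 and 0.9).
#' @param n_decoy Independent pure-noise traits (default 2).
#' @param missing_rate Genotype missingness rate (default 0).
#' @param expression_scale `"log2"` (default) or `"linear"` (exponentiated,
#'   with a low-expressed fraction for exercising intensity filtering).
#' @param low_frac In linear mode, fraction of background transcripts emitted
#'   near background intensity (default 0.1).
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 96,
                       chromosomes = data.frame(
                         chrom = c("chr1", "chr2", "chr3"),
                         length_cM = 100, length_bp = 40e6,
                         stringsAsFactors = FALSE),
                       marker_spacing = 2,
                       n_transcripts = 1000,
                       modules = list(),
                       cis_genes = NULL,
                       trait_qtl = list(),
                       n_sibling = 2, sibling_share = 0.9, n_decoy = 2,
                       missing_rate = 0,
                       expression_scale = c("log2", "linear"),
                       low_frac = 0.1,
                       seed = 1) {
  expression_scale <- match.arg(expression_scale)
  cfg <- list(n_lines = n_lines, chromosomes = chromosomes,
              marker_spacing = marker_spacing, n_transcripts = n_transcripts,
              modules = modules, cis_genes = cis_genes, trait_qtl = trait_qtl,
              n_sibling = n_sibling, sibling_share = sibling_share,
              n_decoy = n_decoy, missing_rate = missing_rate,
              expression_scale = expression_scale, low_frac = low_frac,
              seed = seed)
  if (n_lines < 2) stop("need at least 2 lines")
  if (marker_spacing <= 0) stop("marker_spacing must be > 0")
  for (m in modules) {
    if (m$loading <= 0 || m$loading >= 1) stop("module loading must lie in (0, 1)")
    if (m$hub_r2 < 0 || m$hub_r2 > 1) stop("hub_r2 must lie in [0, 1]")
  }
  r2s <- vapply(trait_qtl, function(q) q$r2, numeric(1))
  if (length(r2s) && sum(r2s) >= 1) {
    stop("trait effect R-squared values must sum to < 1 (got ", sum(r2s), ")")
  }
  n_planted <- sum(vapply(modules, function(m) m$size, numeric(1))) +
    (if (is.null(cis_genes)) 0 else nrow(cis_genes))
  if (n_planted > n_transcripts) stop("planted transcripts exceed n_transcripts")
  class(cfg) <- "sim_config"
  cfg
}

#' Nearest mapped marker to a genomic position
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome label.
#' @param cM Genetic position.
#' @return The name of the nearest marker on that chromosome.
#' @export
nearest_marker <- function(map, chrom, cM) {
  mk <- map[map$chrom == chrom, , drop = FALSE]
  if (!nrow(mk)) stop("no markers on chromosome ", chrom)
  mk$marker[which.min(abs(mk$cM - cM))]
}

#' Simulate a doubled haploid mapping population
#'
#' Each line is a single F1 gamete: per chromosome, a Markov walk over the
#' marker grid with transition probability equal to the Haldane recombination
#' fraction of the inter-marker distance.  Both genotype classes are
#' homozygous, coded 0 (parent 1) / 1 (parent 2); physical positions are
#' assigned proportionally to genetic position.
#'
#' @param config A `sim_config`.
#' @return List: `map` (a `genetic_map`), `geno` (lines x markers matrix).
#' @export
simulate_dh_population <- function(config) {
  chrs <- config$chromosomes
  if (!nrow(chrs)) stop("no chromosomes configured")
  maps <- list(); genos <- list()
  n <- config$n_lines
  for (ci in seq_len(nrow(chrs))) {
    len <- chrs$length_cM[ci]
    pos <- seq(0, len, by = config$marker_spacing)
    if (length(pos) == 0) stop("chromosome with zero markers")
    m <- length(pos)
    G <- matrix(0, n, m)
    G[, 1] <- stats::rbinom(n, 1, 0.5)
    if (m > 1) {
      r <- haldane_d_to_r(diff(pos))
      for (j in 2:m) {
        flip <- stats::rbinom(n, 1, r[j - 1])
        G[, j] <- ifelse(flip == 1, 1 - G[, j - 1], G[, j - 1])
      }
    }
    maps[[ci]] <- data.frame(
      marker = sprintf("M_%s_%03d", chrs$chrom[ci], seq_len(m)),
      chrom = chrs$chrom[ci], cM = pos,
      bp = round(1 + pos / max(len, 1e-9) * (chrs$length_bp[ci] - 1)),
      stringsAsFactors = FALSE)
    genos[[ci]] <- G
  }
  map <- validate_genetic_map(do.call(rbind, maps))
  geno <- do.call(cbind, genos)
  dimnames(geno) <- list(sprintf("L%03d", seq_len(n)), map$marker)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < config$missing_rate,
                   nrow(geno))
    geno[drop] <- NA_real_
  }
  list(map = map, geno = geno)
}

#' Simulate modular expression data with genetic drivers
#'
#' Module transcripts follow a one-factor model
#' `x = loading * z + sqrt(1 - loading^2) * e` with the latent
#' `z = sqrt(hub_r2) * scale(g_hub) + sqrt(1 - hub_r2) * eta`; standalone cis
#' genes get an additive marker effect scaled to their target R-squared;
#' background transcripts are pure noise.  Hub and cis genes are physically
#' placed at/near their marker; everything else is positioned uniformly.
#'
#' @param config A `sim_config`.
#' @param pop Output of [simulate_dh_population()].
#' @return List: `expr` (transcripts x lines), `gene_pos` (data frame
#'   `transcript`, `chrom`, `bp`), `latents` (lines x modules), `truth`
#'   (list: `membership`, `eqtl` data frame of planted cis drivers).
#' @export
simulate_expression <- function(config, pop) {
  map <- pop$map; geno <- pop$geno
  n <- nrow(geno)
  ntx <- config$n_transcripts
  ids <- sprintf("T%04d", seq_len(ntx))
  expr <- matrix(stats::rnorm(ntx * n), ntx, n, dimnames = list(ids, rownames(geno)))
  membership <- stats::setNames(rep(0L, ntx), ids)
  gchrom <- sample(map$chrom, ntx, replace = TRUE)
  gbp <- vapply(gchrom, function(ch) {
    stats::runif(1, 1, config$chromosomes$length_bp[
      match(ch, config$chromosomes$chrom)])
  }, numeric(1))
  truth_eqtl <- list()
  latents <- NULL
  scale01 <- function(g) {
    g <- ifelse(is.na(g), mean(g, na.rm = TRUE), g)
    as.numeric(scale(g))
  }
  cursor <- 0
  for (mi in seq_along(config$modules)) {
    ms <- config$modules[[mi]]
    hub <- nearest_marker(map, ms$chrom, ms$cM)
    g <- scale01(geno[, hub])
    z <- sqrt(ms$hub_r2) * g + sqrt(1 - ms$hub_r2) * stats::rnorm(n)
    z <- as.numeric(scale(z))
    rows <- cursor + seq_len(ms$size)
    lam <- ms$loading
    expr[rows, ] <- lam * matrix(z, ms$size, n, byrow = TRUE) +
      sqrt(1 - lam^2) * matrix(stats::rnorm(ms$size * n), ms$size, n)
    membership[rows] <- mi
    # first member is the hub gene, physically at the hub marker (cis)
    hub_row <- rows[1]
    gchrom[hub_row] <- ms$chrom
    gbp[hub_row] <- map$bp[map$marker == hub]
    truth_eqtl[[length(truth_eqtl) + 1]] <- data.frame(
      transcript = ids[hub_row], marker = hub, chrom = ms$chrom,
      marker_bp = map$bp[map$marker == hub], class = "cis",
      r2 = lam^2 * ms$hub_r2, module = mi, stringsAsFactors = FALSE)
    latents <- cbind(latents, z)
    cursor <- cursor + ms$size
  }
  if (!is.null(latents)) {
    dimnames(latents) <- list(rownames(geno),
                              paste0("module", seq_along(config$modules)))
  }
  if (!is.null(config$cis_genes) && nrow(config$cis_genes)) {
    for (gi in seq_len(nrow(config$cis_genes))) {
      spec <- config$cis_genes[gi, ]
      mk <- nearest_marker(map, spec$chrom, spec$cM)
      g <- scale01(geno[, mk])
      row <- cursor + 1
      expr[row, ] <- sqrt(spec$r2) * g + sqrt(1 - spec$r2) * stats::rnorm(n)
      mbp <- map$bp[map$marker == mk]
      gchrom[row] <- spec$chrom
      gbp[row] <- max(1, mbp + round(stats::runif(1, -2e6, 2e6)))
      truth_eqtl[[length(truth_eqtl) + 1]] <- data.frame(
        transcript = ids[row], marker = mk, chrom = spec$chrom,
        marker_bp = mbp, class = "cis", r2 = spec$r2, module = 0L,
        stringsAsFactors = FALSE)
      cursor <- cursor + 1
    }
  }
  gene_pos <- data.frame(transcript = ids, chrom = gchrom,
                         bp = round(gbp), stringsAsFactors = FALSE)
  if (config$expression_scale == "linear") {
    base <- rep(8, ntx)
    bg <- which(membership == 0)
    nlow <- floor(config$low_frac * length(bg))
    if (nlow > 0) base[bg[seq_len(nlow)]] <- 3
    expr <- 2^(expr + base)
  } else {
    expr <- expr + 8
  }
  truth_eqtl <- if (length(truth_eqtl)) do.call(rbind, truth_eqtl) else
    data.frame(transcript = character(), marker = character(),
               chrom = character(), marker_bp = numeric(), class = character(),
               r2 = numeric(), module = integer(), stringsAsFactors = FALSE)
  list(expr = expr, gene_pos = gene_pos, latents = latents,
       truth = list(membership = membership, eqtl = truth_eqtl))
}

#' Simulate trait panel from module activity and direct QTL effects
#'
#' The target trait is a variance-component sum of module latents and direct
#' marker effects plus Gaussian noise; sibling traits share the target's
#' genetic core at correlation `sibling_share` (emulating a panel of
#' correlated fibre fractions mapping to the same loci); decoy traits are
#' independent noise.
#'
#' @param config A `sim_config`.
#' @param pop Output of [simulate_dh_population()].
#' @param latents Module latent matrix from [simulate_expression()] (may be
#'   `NULL` when no modules are configured).
#' @return List: `traits` (lines x traits data frame: `target`,
#'   `target_sib*`, `decoy*`), `truth` (data frame of planted components:
#'   `type`, `id`, `marker`, `chrom`, `cM`, `r2`).
#' @export
simulate_traits <- function(config, pop, latents = NULL) {
  map <- pop$map; geno <- pop$geno
  n <- nrow(geno)
  y <- numeric(n)
  total_r2 <- 0
  truth <- list()
  for (q in config$trait_qtl) {
    if (q$type == "module") {
      if (is.null(latents) || q$id > ncol(latents)) {
        stop("trait component refers to module ", q$id, " which was not simulated")
      }
      comp <- latents[, q$id]
      ms <- config$modules[[q$id]]
      mk <- nearest_marker(map, ms$chrom, ms$cM)
      truth[[length(truth) + 1]] <- data.frame(
        type = "module", id = as.character(q$id), marker = mk,
        chrom = ms$chrom, cM = map$cM[map$marker == mk], r2 = q$r2,
        stringsAsFactors = FALSE)
    } else {
      mk <- if (is.character(q$id)) q$id else
        nearest_marker(map, q$id$chrom, q$id$cM)
      g <- geno[, mk]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      comp <- as.numeric(scale(g))
      truth[[length(truth) + 1]] <- data.frame(
        type = "marker", id = mk, marker = mk,
        chrom = map$chrom[map$marker == mk],
        cM = map$cM[map$marker == mk], r2 = q$r2, stringsAsFactors = FALSE)
    }
    y <- y + sqrt(q$r2) * as.numeric(scale(comp))
    total_r2 <- total_r2 + q$r2
  }
  y <- y + sqrt(max(0, 1 - total_r2)) * stats::rnorm(n)
  traits <- data.frame(target = y, row.names = rownames(geno))
  if (config$n_sibling > 0) {
    ys <- as.numeric(scale(y))
    for (k in seq_len(config$n_sibling)) {
      rho <- config$sibling_share
      traits[[paste0("target_sib", k)]] <-
        rho * ys + sqrt(1 - rho^2) * stats::rnorm(n)
    }
  }
  if (config$n_decoy > 0) {
    for (k in seq_len(config$n_decoy)) {
      traits[[paste0("decoy", k)]] <- stats::rnorm(n)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), id = character(), marker = character(),
               chrom = character(), cM = numeric(), r2 = numeric(),
               stringsAsFactors = FALSE)
  list(traits = traits, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator under the config's seed: DH population, modular
#' expression with genetic drivers, and the trait panel, returning the data
#' and the complete ground truth for recovery analysis.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_study`: `config`, `map`, `geno`, `expr`,
#'   `gene_pos`, `traits`, `latents`, `truth` (list: `membership`, `eqtl`,
#'   `trait_qtl`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pop <- simulate_dh_population(config)
  ex <- simulate_expression(config, pop)
  tr <- simulate_traits(config, pop, ex$latents)
  structure(list(config = config, map = pop$map, geno = pop$geno,
                 expr = ex$expr, gene_pos = ex$gene_pos,
                 traits = tr$traits, latents = ex$latents,
                 truth = list(membership = ex$truth$membership,
                              eqtl = ex$truth$eqtl,
                              trait_qtl = tr$truth)),
            class = "sim_study")
}
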