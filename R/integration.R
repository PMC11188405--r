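#' Network QTL: QTL mapping of module eigengenes
#'
#' Treats each module eigengene as a quantitative trait and maps it with the
#' shared scan engine (composite interval mapping by default) against a
#' module-specific permutation threshold.  Peaks are labelled
#' `qModule<k>_<chrom>_<i>`.
#'
#' @param ms A `module_set`.
#' @param geno,map,grid As in [interval_mapping_scan()].
#' @param n_perm Permutations per module (default 300).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; each module uses `seed + module label`.
#' @param engine `"CIM"` (default) or `"IM"`.
#' @param window,max_cofactors,merge_radius Engine settings as elsewhere.
#' @param P Optional precomputed [expected_genotype_matrix()].
#' @return Data frame of module QTL peaks with columns `module`, `label`,
#'   `threshold` plus the [call_peaks()] columns.
#' @export
network_qtl <- function(ms, geno, map, grid, n_perm = 300, alpha = 0.05,
                        seed = NULL, engine = c("CIM", "IM"), window = 10,
                        max_cofactors = 5, merge_radius = 10, P = NULL) {
  stopifnot(inherits(ms, "module_set"))
  engine <- match.arg(engine)
  if (is.null(P)) P <- expected_genotype_matrix(geno, map, grid)
  res <- list()
  for (j in seq_len(ncol(ms$eigengenes))) {
    lab <- colnames(ms$eigengenes)[j]
    k <- as.integer(sub("^ME", "", lab))
    y <- ms$eigengenes[, j]
    cof <- if (engine == "CIM") {
      select_cofactors(y, geno, map, grid, max_cofactors = max_cofactors, P = P)
    } else character()
    prof <- cim_scan(y, geno, map, grid, cofactors = cof, window = window, P = P)
    thr <- permutation_threshold(y, geno, map, grid, n_perm = n_perm,
                                 alpha = alpha,
                                 seed = if (is.null(seed)) NULL else seed + k,
                                 cofactors = cof, window = window, P = P)
    pk <- call_peaks(prof, thr, merge_radius = merge_radius, map = map)
    if (nrow(pk)) {
      pk$module <- k
      pk$threshold <- thr$threshold
      # per-chromosome running index in the conventional QTL naming style
      pk$label <- NA_character_
      for (ch in unique(pk$chrom)) {
        ii <- which(pk$chrom == ch)
        pk$label[ii] <- sprintf("qModule%d_%s_%d", k, ch, seq_along(ii))
      }
      res[[length(res) + 1]] <- pk
    }
  }
  if (!length(res)) {
    return(data.frame(module = integer(), label = character(),
                      chrom = character(), peak_cM = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), lod = numeric(),
                      r2 = numeric(), additive = numeric(),
                      allele_parent = character(), bp_lo = numeric(),
                      bp_hi = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Colocalization of two peak sets
#'
#' Two peaks colocalize when they lie on the same chromosome and either
#' their support intervals overlap or their peak positions are within
#' `radius_cM` (OR-combined).  The relation is symmetric.
#'
#' @param peaks_a,peaks_b Peak data frames with columns `chrom`, `peak_cM`,
#'   `ci_lo`, `ci_hi` and a `label` column (labels are generated from row
#'   numbers when absent).
#' @param radius_cM Peak-distance radius in cM (default 10).
#' @return Data frame: `label_a`, `label_b`, `chrom`, `overlap_type`
#'   (`interval-overlap` or `peaks-within-radius`, interval overlap reported
#'   first when both hold), `distance_cM`.
#' @export
colocalize <- function(peaks_a, peaks_b, radius_cM = 10) {
  lab <- function(p, pre) if ("label" %in% names(p)) p$label else
    paste0(pre, seq_len(nrow(p)))
  la <- lab(peaks_a, "a"); lb <- lab(peaks_b, "b")
  out <- list()
  for (i in seq_len(nrow(peaks_a))) {
    for (j in seq_len(nrow(peaks_b))) {
      if (peaks_a$chrom[i] != peaks_b$chrom[j]) next
      d <- abs(peaks_a$peak_cM[i] - peaks_b$peak_cM[j])
      ovl <- peaks_a$ci_lo[i] <= peaks_b$ci_hi[j] &&
             peaks_b$ci_lo[j] <= peaks_a$ci_hi[i]
      near <- d <= radius_cM
      if (!ovl && !near) next
      out[[length(out) + 1]] <- data.frame(
        label_a = la[i], label_b = lb[j], chrom = peaks_a$chrom[i],
        overlap_type = if (ovl) "interval-overlap" else "peaks-within-radius",
        distance_cM = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(label_a = character(), label_b = character(),
                      chrom = character(), overlap_type = character(),
                      distance_cM = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assemble the trait-associated causal subnetwork
#'
#' Modules significantly associated with the given trait (BH across the
#' module x trait grid at `alpha`) contribute their member transcripts; the
#' hard-threshold edge list is restricted to edges between those members.
#'
#' @param mta Module-trait table from [module_trait_association()].
#' @param ms The `module_set`.
#' @param edges Edge list from [hard_threshold_edges()] (the full list or its
#'   `$edges` component).
#' @param trait Trait name to gate on.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return List: `modules` (qualifying labels), `members`, `edges` (induced
#'   subgraph), `n_nodes`, `n_edges`, `n_components`.
#' @export
assemble_causal_network <- function(mta, ms, edges, trait, alpha = 0.05) {
  stopifnot(inherits(ms, "module_set"))
  if (is.list(edges) && !is.data.frame(edges)) edges <- edges$edges
  mta$p_adj <- stats::p.adjust(mta$p, method = "BH")
  sig <- mta[mta$trait == trait & !is.na(mta$p_adj) & mta$p_adj < alpha, ,
             drop = FALSE]
  mods <- as.integer(sub("^ME", "", sig$module))
  if (!length(mods)) {
    warning("no module associated with trait '", trait, "' at BH ", alpha)
    return(list(modules = integer(), members = character(),
                edges = edges[0, , drop = FALSE], n_nodes = 0L,
                n_edges = 0L, n_components = 0L))
  }
  members <- names(ms$membership)[ms$membership %in% mods]
  sub <- edges[edges$node_a %in% members & edges$node_b %in% members, ,
               drop = FALSE]
  ncomp <- if (nrow(sub)) {
    g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                       directed = FALSE,
                                       vertices = members)
    igraph::count_components(g)
  } else length(members)
  list(modules = sort(mods), members = members, edges = sub,
       n_nodes = length(members), n_edges = nrow(sub), n_components = ncomp)
}

#' Category enrichment in a gene set (one-sided Fisher exact test)
#'
#' For each functional category, tests whether the gene set is enriched
#' relative to the universe on the 2x2 membership table, with the
#' hypergeometric (one-sided, "greater") Fisher exact p-value.  Raw p < 0.05
#' is the classical claim; BH-adjusted values are reported alongside.
#'
#' @param members Character vector: the gene set (must be within `universe`).
#' @param categories Data frame: `transcript`, `category`.
#' @param universe Character vector of all eligible transcripts (defaults in
#'   the pipeline to everything surviving expression filtering).
#' @return Data frame: `category`, `n_set`, `n_category`, `odds_ratio`, `p`,
#'   `p_adj`, sorted by p.
#' @export
enrichment_fisher <- function(members, categories, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(members %in% universe)) stop("all members must be in the universe")
  categories <- categories[categories$transcript %in% universe, , drop = FALSE]
  cats <- unique(categories$category)
  out <- lapply(cats, function(cg) {
    incat <- unique(categories$transcript[categories$category == cg])
    a <- sum(members %in% incat)
    b <- length(members) - a
    c_ <- length(setdiff(incat, members))
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    data.frame(category = cg, n_set = a, n_category = length(incat),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Prioritize candidate causal genes by eQTL colocalization
#'
#' Within the trait-associated causal subnetwork, each gene with an eQTL is
#' tiered by evidence strength: `cis-colocal` (cis eQTL colocalizing with a
#' trait pQTL — the strongest claim: the gene's own regulatory variation
#' tracks the trait locus), `trans-colocal` (trans eQTL colocalizing with a
#' pQTL), `module-only` (membership without colocalizing eQTL evidence).
#' Genes outside the qualifying modules are absent.
#'
#' @param causal Output of [assemble_causal_network()].
#' @param ms The `module_set` (for module labels).
#' @param records Classified eQTL records ([classify_cis_trans()]).
#' @param trait_peaks Phenotype QTL peaks (with `label` column, or labels are
#'   generated).
#' @param mta Module-trait table; the gene's module-trait `r` for the gated
#'   trait is reported.
#' @param trait Trait name used in `mta` lookup.
#' @param radius_cM Colocalization radius (default 10).
#' @return Data frame: `transcript`, `module`, `tier`, `eqtl_class`,
#'   `eqtl_lod`, `coloc_pqtl`, `module_trait_r`, ordered by tier then LOD.
#' @export
prioritize_causal_genes <- function(causal, ms, records, trait_peaks, mta,
                                    trait, radius_cM = 10) {
  members <- causal$members
  if (!"label" %in% names(trait_peaks) && nrow(trait_peaks)) {
    trait_peaks$label <- paste0("pQTL_", seq_len(nrow(trait_peaks)))
  }
  tiers <- c("cis-colocal" = 1, "trans-colocal" = 2, "module-only" = 3)
  rows <- list()
  for (tx in members) {
    mod <- ms$membership[[tx]]
    r_mt <- mta$r[mta$trait == trait & mta$module == paste0("ME", mod)]
    r_mt <- if (length(r_mt)) r_mt[1] else NA_real_
    rec <- records[records$transcript == tx, , drop = FALSE]
    tier <- "module-only"; cls <- NA_character_; lod <- NA_real_
    coloc_lab <- NA_character_
    if (nrow(rec)) {
      cl <- colocalize(rec, trait_peaks, radius_cM = radius_cM)
      best_i <- order(factor(ifelse(rec$class == "cis", "cis", "trans"),
                             levels = c("cis", "trans")), -rec$lod)[1]
      cls <- rec$class[best_i]; lod <- rec$lod[best_i]
      if (nrow(cl)) {
        rec$rowlab <- if ("label" %in% names(rec)) rec$label else
          paste0("a", seq_len(nrow(rec)))
        hit <- rec[rec$rowlab %in% cl$label_a, , drop = FALSE]
        if (any(hit$class == "cis")) {
          tier <- "cis-colocal"
          hb <- hit[hit$class == "cis", ][which.max(hit$lod[hit$class == "cis"]), ]
        } else {
          tier <- "trans-colocal"
          hb <- hit[which.max(hit$lod), ]
        }
        cls <- hb$class; lod <- hb$lod
        coloc_lab <- cl$label_b[match(hb$rowlab, cl$label_a)]
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      transcript = tx, module = mod, tier = tier, eqtl_class = cls,
      eqtl_lod = lod, coloc_pqtl = coloc_lab, module_trait_r = r_mt,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(transcript = character(), module = integer(),
                      tier = character(), eqtl_class = character(),
                      eqtl_lod = numeric(), coloc_pqtl = character(),
                      module_trait_r = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(tiers[out$tier], -ifelse(is.na(out$eqtl_lod), -Inf,
                                            out$eqtl_lod)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
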