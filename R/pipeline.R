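#' Pipeline configuration with study defaults
#'
#' Central parameter block for the full systems-genetics workflow.  Defaults
#' follow the classical study design this pipeline automates: 1-cM walking
#' speed, 10-cM CIM window, permutation thresholds at the 5% level, soft
#' powers 1-20, minimum module size 30, eigengene merge at 0.75, hard edge
#' cutoff |r| = 0.75, 4-Mb cis window, 10-cM QTL merging, intensity floor 20
#' with a 30% detection frequency, and a 2-fold / FDR 0.05 differential
#' expression rule.  Unknown parameter names are rejected.
#'
#' @param ... Name-value overrides of the defaults listed above.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    walk_cM = 1, window_cM = 10, n_perm = 1000, alpha = 0.05,
    powers = 1:20, fit_cut = 0.8, min_module_size = 30, cut_height = 0.95,
    merge_similarity = 0.75, min_kme = 0.5, hard_cut = 0.75, cis_window_bp = 4e6,
    merge_radius_cM = 10, intensity_floor = 20, min_frequency = 0.30,
    fc_cut = 2, fdr = 0.05, max_cofactors = 5,
    gpt_transcripts = 100, gpt_perm_each = 10,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Deterministic per-stage seed derivation
#'
#' Derives independent, reproducible seeds for named pipeline stages from a
#' single root seed, so stages can be rerun in isolation.
#'
#' @param root Integer root seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 10007 + h) %% .Machine$integer.max)
}

#' Run the full systems-genetics workflow on a study
#'
#' Convenience driver binding the stages together on in-memory study data
#' (as produced by [simulate_study()] or assembled from the file readers):
#' phenotype QTL mapping (CIM with permutation threshold), network
#' construction (soft power, TOM, modules, merge), module-trait association,
#' network QTL on trait-associated modules, the eQTL scan with global
#' permutation threshold and cis/trans classification, and causal-gene
#' prioritization against the target trait's pQTL.
#'
#' @param study A list with `map`, `geno`, `expr` (log2 scale), `gene_pos`,
#'   `traits` (a `sim_study` works directly when generated on the log2
#'   scale).
#' @param trait Name of the trait to dissect (default `"target"`).
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress (default FALSE).
#' @return List of class `sysgen_result` with elements `grid`, `pqtl`
#'   (peaks, with `label`), `pqtl_threshold`, `soft_power`, `modules`
#'   (`module_set`), `module_trait`, `network_qtl`, `gpt`, `eqtl` (classified
#'   records), `edges`, `causal` (subnetwork), `causal_genes`, `config`.
#' @export
run_sysgen_study <- function(study, trait = "target",
                             config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  map <- study$map; geno <- validate_genotypes(study$geno, map)
  grid <- build_grid(map, step = config$walk_cM)
  P <- expected_genotype_matrix(geno, map, grid)

  say("phenotype QTL scan: ", trait)
  y <- study$traits[[trait]]
  names(y) <- rownames(study$traits)
  cof <- select_cofactors(y, geno, map, grid,
                          max_cofactors = config$max_cofactors, P = P)
  prof <- cim_scan(y, geno, map, grid, cofactors = cof,
                   window = config$window_cM, P = P)
  thr <- permutation_threshold(y, geno, map, grid, n_perm = config$n_perm,
                               alpha = config$alpha,
                               seed = stage_seed(config$seed, "pqtl"),
                               cofactors = cof, window = config$window_cM,
                               P = P)
  pqtl <- call_peaks(prof, thr, merge_radius = config$merge_radius_cM,
                     map = map)
  if (nrow(pqtl)) {
    pqtl$label <- NA_character_
    for (ch in unique(pqtl$chrom)) {
      ii <- which(pqtl$chrom == ch)
      pqtl$label[ii] <- sprintf("q%s_%s_%d", trait, ch, seq_along(ii))
    }
  }

  say("network construction")
  sp <- pick_soft_power(study$expr, powers = config$powers,
                        fit_cut = config$fit_cut)
  ac <- abs(stats::cor(t(study$expr)))^sp$power
  diag(ac) <- 0
  tom <- tom_similarity(ac)
  memb <- cluster_modules(tom, min_size = config$min_module_size,
                          cut_height = config$cut_height)
  memb <- rescue_membership(study$expr, memb, min_kme = config$min_kme)
  ms <- module_set(study$expr, memb)
  ms <- merge_modules(ms, study$expr,
                      similarity_cut = config$merge_similarity)
  mta <- module_trait_association(ms, study$traits)
  edges <- hard_threshold_edges(study$expr, cut = config$hard_cut)

  say("network QTL")
  nq <- network_qtl(ms, geno, map, grid, n_perm = max(100, config$n_perm %/% 5),
                    alpha = config$alpha,
                    seed = stage_seed(config$seed, "network_qtl"),
                    window = config$window_cM,
                    max_cofactors = config$max_cofactors,
                    merge_radius = config$merge_radius_cM, P = P)

  say("eQTL scan")
  gpt <- global_permutation_threshold(
    study$expr, geno, map, grid,
    n_transcripts = config$gpt_transcripts,
    n_perm_each = config$gpt_perm_each, alpha = config$alpha,
    seed = stage_seed(config$seed, "gpt"), P = P)
  eq <- eqtl_scan_all(study$expr, geno, map, grid, gpt,
                      merge_radius = config$merge_radius_cM, P = P)
  eq <- classify_cis_trans(eq, study$gene_pos,
                           window_bp = config$cis_window_bp)

  say("integration")
  causal <- assemble_causal_network(mta, ms, edges, trait,
                                    alpha = config$alpha)
  genes <- prioritize_causal_genes(causal, ms, eq, pqtl, mta, trait,
                                   radius_cM = config$merge_radius_cM)

  structure(list(grid = grid, pqtl = pqtl, pqtl_threshold = thr,
                 pqtl_profile = prof, soft_power = sp, modules = ms,
                 module_trait = mta, network_qtl = nq, gpt = gpt, eqtl = eq,
                 edges = edges, causal = causal, causal_genes = genes,
                 config = config),
            class = "sysgen_result")
}
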