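#' Global permutation threshold for genome-wide eQTL scanning
#'
#' Scanning thousands of transcripts individually with full permutation tests
#' is infeasible, so a pooled threshold is used: a random sample of
#' transcripts is drawn without replacement, each is permuted across lines
#' `n_perm_each` times and rescanned (interval mapping), and the genome-wide
#' maximum LOD of every permutation is pooled.  The threshold is the
#' `1 - alpha` quantile of the pooled maxima and is applied to all transcript
#' scans.
#'
#' @param expr Numeric matrix, transcripts x lines (log2 e-traits).
#' @param geno,map,grid As in [interval_mapping_scan()].
#' @param n_transcripts Number of transcripts to sample (default 100).
#' @param n_perm_each Permutations per sampled transcript (default 10);
#'   `n_transcripts * n_perm_each` must be >= 200.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer RNG seed.
#' @param P Optional precomputed [expected_genotype_matrix()].
#' @return Object of class `global_threshold`: list with `threshold`,
#'   `maxima`, `n_transcripts`, `n_perm_each`, `alpha`, `seed`.
#' @export
global_permutation_threshold <- function(expr, geno, map, grid,
                                         n_transcripts = 100,
                                         n_perm_each = 10, alpha = 0.05,
                                         seed = NULL, P = NULL) {
  expr <- as.matrix(expr)
  n_transcripts <- min(n_transcripts, nrow(expr))
  if (n_transcripts * n_perm_each < 200) {
    stop("n_transcripts * n_perm_each must be >= 200 for a stable pooled quantile")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(P)) P <- expected_genotype_matrix(geno, map, grid)
  if (!is.null(seed)) set.seed(seed)
  picks <- sample(nrow(expr), n_transcripts)
  n <- nrow(geno)
  Yp <- matrix(NA_real_, n, n_transcripts * n_perm_each)
  col <- 0
  for (i in picks) {
    y <- as.numeric(expr[i, ])
    for (k in seq_len(n_perm_each)) {
      col <- col + 1
      Yp[, col] <- sample(y)
    }
  }
  maxima <- .scan_max_lod(Yp, P, map, grid)
  thr <- stats::quantile(maxima, probs = 1 - alpha, type = 7, names = FALSE)
  structure(list(threshold = thr, maxima = maxima,
                 n_transcripts = n_transcripts, n_perm_each = n_perm_each,
                 alpha = alpha, seed = seed),
            class = "global_threshold")
}

#' Genome-wide per-transcript eQTL scan
#'
#' Scans every transcript against the genome, calls peaks above the global
#' threshold with 10-cM merging, and annotates each eQTL with its nearest
#' mapped marker.  Interval mapping is the default engine; composite interval
#' mapping (per-transcript forward-BIC cofactors) is available via
#' `engine = "CIM"`.
#'
#' @inheritParams global_permutation_threshold
#' @param threshold LOD threshold (scalar or a `global_threshold`).
#' @param engine `"IM"` (default) or `"CIM"`.
#' @param merge_radius Peak merge radius in cM (default 10).
#' @param window CIM cofactor exclusion window in cM (default 10).
#' @param max_cofactors CIM cofactor cap (default 5).
#' @param verbose Log per-chromosome eQTL counts (default FALSE).
#' @return Data frame of eQTL records: `transcript`, `chrom`, `peak_cM`,
#'   `marker`, `marker_bp`, `lod`, `r2`, `additive`, plus peak support
#'   columns `ci_lo`, `ci_hi`.  Zero-variance transcripts are skipped.
#' @export
eqtl_scan_all <- function(expr, geno, map, grid, threshold,
                          engine = c("IM", "CIM"), merge_radius = 10,
                          window = 10, max_cofactors = 5, P = NULL,
                          verbose = FALSE) {
  engine <- match.arg(engine)
  if (inherits(threshold, "global_threshold")) threshold <- threshold$threshold
  expr <- as.matrix(expr)
  if (is.null(P)) P <- expected_genotype_matrix(geno, map, grid)
  keep_tx <- apply(expr, 1, function(x) stats::sd(x, na.rm = TRUE) > 0 &&
                     sum(!is.na(x)) >= 10)
  if (any(!keep_tx) && verbose) {
    message(sum(!keep_tx), " zero-variance/under-observed transcript(s) skipped")
  }
  expr <- expr[keep_tx, , drop = FALSE]
  recs <- list()
  complete <- !anyNA(expr)
  if (engine == "IM" && complete) {
    # all transcripts at once through the matrix path
    Y <- t(expr)
    res <- .hk_group_scan(Y, P, matrix(1, nrow(Y), 1))
    syy <- colSums(scale(Y, scale = FALSE)^2)
    for (t_i in seq_len(nrow(expr))) {
      prof <- data.frame(chrom = grid$chrom, pos_cM = grid$pos_cM,
                         lod = res$lod[, t_i],
                         r2 = pmin(pmax(1 - res$rss1[, t_i] / syy[t_i], 0), 1),
                         additive = -res$beta[, t_i] / 2,
                         saturated = res$saturated[, t_i],
                         stringsAsFactors = FALSE)
      pk <- call_peaks(prof, threshold, merge_radius = merge_radius, map = map)
      if (nrow(pk)) {
        pk$transcript <- rownames(expr)[t_i]
        recs[[length(recs) + 1]] <- pk
      }
    }
  } else {
    for (t_i in seq_len(nrow(expr))) {
      y <- as.numeric(expr[t_i, ]); names(y) <- colnames(expr)
      cof <- if (engine == "CIM") {
        select_cofactors(y, geno, map, grid, max_cofactors = max_cofactors, P = P)
      } else character()
      prof <- cim_scan(y, geno, map, grid, cofactors = cof, window = window, P = P)
      pk <- call_peaks(prof, threshold, merge_radius = merge_radius, map = map)
      if (nrow(pk)) {
        pk$transcript <- rownames(expr)[t_i]
        recs[[length(recs) + 1]] <- pk
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(transcript = character(), chrom = character(),
                      peak_cM = numeric(), marker = character(),
                      marker_bp = numeric(), lod = numeric(), r2 = numeric(),
                      additive = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  # nearest mapped marker to each peak
  nm <- vapply(seq_len(nrow(out)), function(i) {
    mk <- map[map$chrom == out$chrom[i], , drop = FALSE]
    j <- which.min(abs(mk$cM - out$peak_cM[i]))
    c(mk$marker[j], mk$bp[j])
  }, character(2))
  out$marker <- nm[1, ]
  out$marker_bp <- as.numeric(nm[2, ])
  if (verbose) {
    cnt <- table(out$chrom)
    message("eQTL per chromosome: ",
            paste(names(cnt), cnt, sep = "=", collapse = ", "))
  }
  out[, c("transcript", "chrom", "peak_cM", "marker", "marker_bp", "lod",
          "r2", "additive", "ci_lo", "ci_hi")]
}

#' Classify eQTL as cis or trans
#'
#' An eQTL is cis when the regulated gene's physical position is known, lies
#' on the same chromosome as the peak's nearest marker, and gene-marker
#' distance is at most `window_bp` (default 4 Mb); any other placed gene is
#' trans; genes without a position are `unplaced`.
#'
#' @param records eQTL records from [eqtl_scan_all()].
#' @param gene_pos Data frame: `transcript`, `chrom`, `bp` (gene midpoint,
#'   1-based; transcripts absent from the table are unplaced).
#' @param window_bp cis distance cutoff in bp (default 4e6).
#' @return `records` with added columns `class` (`cis`/`trans`/`unplaced`)
#'   and `distance_bp` (`NA` across chromosomes or when unplaced).
#' @export
classify_cis_trans <- function(records, gene_pos, window_bp = 4e6) {
  i <- match(records$transcript, gene_pos$transcript)
  gchrom <- gene_pos$chrom[i]
  gbp <- gene_pos$bp[i]
  same <- !is.na(gchrom) & gchrom == records$chrom
  dist <- ifelse(same, abs(gbp - records$marker_bp), NA_real_)
  records$class <- ifelse(is.na(gchrom), "unplaced",
                          ifelse(same & dist <= window_bp, "cis", "trans"))
  records$distance_bp <- dist
  records
}

#' Trans-eQTL hotspot counts
#'
#' Counts trans-eQTL per (chromosome, cM bin) and tests each bin for
#' enrichment against the genome-wide mean bin count with a Poisson upper
#' tail, BH-adjusted.
#'
#' @param records Classified eQTL records.
#' @param map A `genetic_map` (defines chromosome extents).
#' @param bin_cM Bin width in cM (default 10).
#' @return Data frame: `chrom`, `bin_lo`, `bin_hi`, `count`, `p`, `p_adj`
#'   (empty when there are no trans records).
#' @export
hotspot_counts <- function(records, map, bin_cM = 10) {
  tr <- records[records$class == "trans", , drop = FALSE]
  if (nrow(tr) == 0) {
    return(data.frame(chrom = character(), bin_lo = numeric(),
                      bin_hi = numeric(), count = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (ch in unique(map$chrom)) {
    hi <- max(map$cM[map$chrom == ch])
    br <- seq(0, hi + bin_cM, by = bin_cM)
    pos <- tr$peak_cM[tr$chrom == ch]
    cnt <- if (length(pos)) tabulate(findInterval(pos, br, rightmost.closed = TRUE),
                                     nbins = length(br) - 1) else
      integer(length(br) - 1)
    out[[ch]] <- data.frame(chrom = ch, bin_lo = br[-length(br)],
                            bin_hi = br[-1], count = cnt,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  lambda <- mean(tab$count)
  tab$p <- stats::ppois(tab$count - 1, lambda = lambda, lower.tail = FALSE)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  rownames(tab) <- NULL
  tab
}
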