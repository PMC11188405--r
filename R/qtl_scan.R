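#' @keywords internal
#' Residualized single-regressor scan: for each column x of X and each trait
#' column y of Y, LOD for adding x to the null design Z.
#' Returns lod (ncol(X) x ncol(Y)), beta, rss0 (per trait), rss1.
.hk_group_scan <- function(Y, X, Z, lod_max = 300) {
  n <- nrow(Y)
  qz <- qr(Z)
  Ry <- qr.resid(qz, Y)
  Rx <- qr.resid(qz, X)
  rss0 <- colSums(Ry^2)
  den <- colSums(Rx^2)
  num <- crossprod(Rx, Ry)                    # P x T
  gain <- num^2 / ifelse(den > 1e-12, den, Inf)
  rss1 <- sweep(-gain, 2, rss0, "+")
  saturated <- rss1 <= sweep(matrix(1e-12, nrow(rss1), ncol(rss1)), 2, rss0, "*")
  rss1[rss1 < 0] <- 0
  lod <- (n / 2) * (sweep(-log10(pmax(rss1, .Machine$double.xmin)), 2,
                          log10(rss0), "+"))
  lod[saturated] <- lod_max
  lod[lod < 0] <- 0
  beta <- num / ifelse(den > 1e-12, den, Inf)
  list(lod = lod, beta = beta, rss0 = rss0, rss1 = rss1, saturated = saturated)
}

#' @keywords internal
#' Align a trait vector with genotype rows and drop missing values.
.prep_trait <- function(trait, geno) {
  if (!is.null(names(trait)) && !is.null(rownames(geno))) {
    trait <- trait[rownames(geno)]
  }
  if (length(trait) != nrow(geno)) {
    stop("trait length does not match number of lines")
  }
  keep <- !is.na(trait)
  if (sum(keep) < 10) stop("fewer than 10 lines with non-missing trait")
  if (stats::var(trait[keep]) <= 0) stop("zero-variance trait")
  list(y = as.numeric(trait[keep]), keep = keep)
}

#' Interval mapping scan (Haley-Knott regression)
#'
#' At every grid position the trait is regressed on the conditional expected
#' QTL genotype given the flanking markers; `LOD = (n/2) log10(RSS0/RSS1)`
#' against the intercept-only null.  This is the engine shared by phenotype
#' QTL, eQTL and network-QTL scans; composite interval mapping ([cim_scan()])
#' is the same engine with background cofactors.
#'
#' @param trait Numeric trait values per line (names matched against
#'   `rownames(geno)` when present); missing values dropped pairwise.
#' @param geno Validated DH genotype matrix.
#' @param map The `genetic_map`.
#' @param grid Evaluation grid from [build_grid()].
#' @param P Optional precomputed [expected_genotype_matrix()] (reused across
#'   many traits for speed).
#' @return A `scan_profile` data frame: `chrom`, `pos_cM`, `lod`, `r2`
#'   (`1 - RSS1/TSS`), `additive` (half the parent-0 minus parent-1 class
#'   difference; positive = trait-increasing allele from parent 0), and
#'   `saturated` (TRUE where the fit is numerically perfect and the LOD is
#'   reported at its guard ceiling).
#' @export
interval_mapping_scan <- function(trait, geno, map, grid, P = NULL) {
  cim_scan(trait, geno, map, grid, cofactors = character(), P = P)
}

#' Composite interval mapping scan
#'
#' Interval mapping with background marker cofactors: both the null and the
#' full model include the cofactor markers, excluding any cofactor within
#' `window` cM of the test position on the same chromosome, so that a linked
#' cofactor does not absorb the local QTL signal.
#'
#' @inheritParams interval_mapping_scan
#' @param cofactors Character vector of cofactor marker names (empty reduces
#'   to plain interval mapping).
#' @param window Exclusion window in cM around the test position (default 10).
#' @return A `scan_profile` data frame (see [interval_mapping_scan()]).
#' @export
cim_scan <- function(trait, geno, map, grid, cofactors = character(),
                     window = 10, P = NULL) {
  if (window < 0) stop("window must be >= 0")
  pt <- .prep_trait(trait, geno)
  if (is.null(P)) P <- expected_genotype_matrix(geno, map, grid)
  Pk <- P[pt$keep, , drop = FALSE]
  y <- matrix(pt$y, ncol = 1)
  n <- length(pt$y)
  syy <- sum((pt$y - mean(pt$y))^2)

  npos <- nrow(grid)
  lod <- numeric(npos); beta <- numeric(npos); sat <- logical(npos)
  r2 <- numeric(npos)

  if (length(cofactors) == 0) {
    res <- .hk_group_scan(y, Pk, matrix(1, n, 1))
    lod <- res$lod[, 1]; beta <- res$beta[, 1]; sat <- res$saturated[, 1]
    r2 <- 1 - res$rss1[, 1] / syy
  } else {
    bad <- setdiff(cofactors, map$marker)
    if (length(bad)) stop("unknown cofactor marker(s): ", paste(bad, collapse = ", "))
    C <- .marker_codes(Pk, map, grid, cofactors)
    cof_chr <- map$chrom[match(cofactors, map$marker)]
    cof_cm  <- map$cM[match(cofactors, map$marker)]
    # active cofactors per position (window exclusion), grouped by mask
    mask <- vapply(seq_len(npos), function(j) {
      excl <- cof_chr == grid$chrom[j] & abs(cof_cm - grid$pos_cM[j]) <= window
      paste(as.integer(!excl), collapse = "")
    }, character(1))
    for (mk in unique(mask)) {
      act <- as.logical(as.integer(strsplit(mk, "")[[1]]))
      jj <- which(mask == mk)
      Z <- cbind(1, C[, act, drop = FALSE])
      res <- .hk_group_scan(y, Pk[, jj, drop = FALSE], Z)
      lod[jj] <- res$lod[, 1]; beta[jj] <- res$beta[, 1]
      sat[jj] <- res$saturated[, 1]
      r2[jj] <- 1 - res$rss1[, 1] / syy
    }
  }
  out <- data.frame(chrom = grid$chrom, pos_cM = grid$pos_cM,
                    lod = lod, r2 = pmin(pmax(r2, 0), 1),
                    additive = -beta / 2, saturated = sat,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_profile", "data.frame")
  attr(out, "n") <- n
  out
}

#' @keywords internal
#' Expected genotype codes at marker positions (imputes missing genotypes
#' through flanking-marker conditioning); columns named by marker.
.marker_codes <- function(P, map, grid, markers = map$marker) {
  j <- match(markers, grid$at_marker)
  if (anyNA(j)) stop("grid does not include marker position(s): ",
                     paste(markers[is.na(j)], collapse = ", "))
  M <- P[, j, drop = FALSE]
  colnames(M) <- markers
  M
}

#' Forward cofactor selection for composite interval mapping
#'
#' Forward selection of background markers on the marker-regression model,
#' scored by the extended BIC (EBIC: penalty `k (log n + 2 gamma log m)` for
#' `k` markers chosen among `m` candidates), which keeps the selection honest
#' when the best of a hundred-plus correlated markers is taken at every step;
#' `ebic_gamma = 0` recovers the classical BIC.  Selection stops when no
#' marker improves the criterion or when `max_cofactors` is reached.
#' Deterministic: ties are broken by map order.
#'
#' @inheritParams interval_mapping_scan
#' @param max_cofactors Maximum number of cofactors (default 5; 0 returns an
#'   empty set, reducing CIM to IM).
#' @param ebic_gamma EBIC candidate-count penalty weight (default 1).
#' @return Character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(trait, geno, map, grid, max_cofactors = 5,
                             ebic_gamma = 1, P = NULL) {
  if (max_cofactors < 0) stop("max_cofactors must be >= 0")
  if (max_cofactors == 0) return(character())
  pt <- .prep_trait(trait, geno)
  if (is.null(P)) P <- expected_genotype_matrix(geno, map, grid)
  M <- .marker_codes(P[pt$keep, , drop = FALSE], map, grid)
  y <- pt$y; n <- length(y)
  m <- nrow(map)
  pen <- function(k) k * (log(n) + 2 * ebic_gamma * log(m))
  selected <- character()
  Z <- matrix(1, n, 1)
  rss_cur <- sum((y - mean(y))^2)
  crit_cur <- n * log(rss_cur / n) + pen(0)
  repeat {
    cand <- setdiff(map$marker, selected)
    if (!length(cand) || length(selected) >= max_cofactors) break
    qz <- qr(Z)
    ry <- qr.resid(qz, y)
    Rm <- qr.resid(qz, M[, cand, drop = FALSE])
    den <- colSums(Rm^2)
    num <- as.numeric(crossprod(Rm, ry))
    rss_new <- sum(ry^2) - num^2 / ifelse(den > 1e-10, den, Inf)
    crit_new <- n * log(pmax(rss_new, 1e-300) / n) + pen(length(selected) + 1)
    best <- which.min(crit_new)          # first minimum = map order tie-break
    if (crit_new[best] >= crit_cur) break
    selected <- c(selected, cand[best])
    Z <- cbind(Z, M[, cand[best]])
    crit_cur <- crit_new[best]
  }
  selected
}

#' Permutation-based genome-wide significance threshold
#'
#' Trait values are shuffled across lines (genotypes fixed), the genome is
#' rescanned under the same model (including cofactors, when given), and the
#' genome-wide maximum LOD of each permutation is recorded.  The threshold is
#' the empirical `1 - alpha` quantile (type-7 interpolation) of the maxima.
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (>= 20; >= 100 recommended).
#' @param alpha Significance level in (0, 1]; `alpha = 1` returns the minimum
#'   of the maxima.
#' @param seed Integer RNG seed recorded with the result.
#' @return An object of class `perm_threshold`: list with `threshold`,
#'   `maxima`, `n_perm`, `alpha`, `seed`.
#' @export
permutation_threshold <- function(trait, geno, map, grid, n_perm = 1000,
                                  alpha = 0.05, seed = NULL,
                                  cofactors = character(), window = 10,
                                  P = NULL) {
  if (n_perm < 20) stop("n_perm < 20: permutation quantile too unstable")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  pt <- .prep_trait(trait, geno)
  if (is.null(P)) P <- expected_genotype_matrix(geno, map, grid)
  Pk <- P[pt$keep, , drop = FALSE]
  n <- length(pt$y)
  if (!is.null(seed)) set.seed(seed)
  Yp <- vapply(seq_len(n_perm), function(i) sample(pt$y), numeric(n))
  maxima <- .scan_max_lod(Yp, Pk, map, grid, cofactors, window)
  thr <- stats::quantile(maxima, probs = 1 - alpha, type = 7, names = FALSE)
  structure(list(threshold = thr, maxima = maxima, n_perm = n_perm,
                 alpha = alpha, seed = seed),
            class = "perm_threshold")
}

#' @keywords internal
#' Genome-wide max LOD for each trait column of Y (no missing values in Y).
.scan_max_lod <- function(Y, Pk, map, grid, cofactors = character(),
                          window = 10) {
  n <- nrow(Y)
  if (length(cofactors) == 0) {
    res <- .hk_group_scan(Y, Pk, matrix(1, n, 1))
    return(apply(res$lod, 2, max))
  }
  C <- .marker_codes(Pk, map, grid, cofactors)
  cof_chr <- map$chrom[match(cofactors, map$marker)]
  cof_cm  <- map$cM[match(cofactors, map$marker)]
  npos <- nrow(grid)
  mask <- vapply(seq_len(npos), function(j) {
    excl <- cof_chr == grid$chrom[j] & abs(cof_cm - grid$pos_cM[j]) <= window
    paste(as.integer(!excl), collapse = "")
  }, character(1))
  mx <- rep(-Inf, ncol(Y))
  for (mk in unique(mask)) {
    act <- as.logical(as.integer(strsplit(mk, "")[[1]]))
    jj <- which(mask == mk)
    Z <- cbind(1, C[, act, drop = FALSE])
    res <- .hk_group_scan(Y, Pk[, jj, drop = FALSE], Z)
    mx <- pmax(mx, apply(res$lod, 2, max))
  }
  mx
}

#' Call QTL peaks from a scan profile
#'
#' Local maxima at or above the threshold; maxima on the same chromosome
#' within `merge_radius` cM are collapsed to the highest (ties to the smaller
#' cM), and a maximum only counts as a distinct QTL if it is prominent: the
#' LOD must dip at least `lod_drop` below it in the valley separating it from
#' every higher peak on the chromosome (otherwise it is a shoulder of that
#' peak's linkage ridge, not a second locus).  Support intervals use the
#' 1.5-LOD drop rule, clipped to chromosome ends; physical intervals are
#' interpolated from flanking markers' bp.
#'
#' @param profile A `scan_profile`.
#' @param threshold LOD significance threshold (scalar or `perm_threshold`).
#' @param merge_radius Merge radius in cM (default 10).
#' @param lod_drop Support-interval drop from the peak LOD (default 1.5).
#' @param map Optional `genetic_map` for bp interpolation of the support
#'   interval (columns `bp_lo`/`bp_hi` are `NA` without it).
#' @param parents Length-2 labels reported as the source of the
#'   trait-increasing allele for codes 0 and 1.
#' @return Data frame of peaks: `chrom`, `peak_cM`, `ci_lo`, `ci_hi`, `lod`,
#'   `r2`, `additive`, `allele_parent`, `bp_lo`, `bp_hi` (possibly 0 rows).
#' @export
call_peaks <- function(profile, threshold, merge_radius = 10, lod_drop = 1.5,
                       map = NULL, parents = c("P1", "P2")) {
  if (inherits(threshold, "perm_threshold")) threshold <- threshold$threshold
  if (merge_radius < 0) stop("merge_radius must be >= 0")
  empty <- data.frame(chrom = character(), peak_cM = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), lod = numeric(),
                      r2 = numeric(), additive = numeric(),
                      allele_parent = character(), bp_lo = numeric(),
                      bp_hi = numeric(), stringsAsFactors = FALSE)
  rows <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, , drop = FALSE]
    v <- pr$lod; m <- length(v)
    if (m == 0) next
    is_max <- vapply(seq_len(m), function(i) {
      (i == 1 || v[i] >= v[i - 1]) && (i == m || v[i] >= v[i + 1])
    }, logical(1))
    cand <- which(is_max & v >= threshold)
    if (!length(cand)) next
    cand <- cand[order(-v[cand], pr$pos_cM[cand])]
    kept <- integer()
    for (i in cand) {
      if (length(kept)) {
        if (any(abs(pr$pos_cM[kept] - pr$pos_cM[i]) <= merge_radius)) next
        # prominence: must dip lod_drop below the candidate on the way to
        # every higher peak, else it is a ridge shoulder
        saddle_ok <- vapply(kept, function(k) {
          rng <- if (k < i) k:i else i:k
          min(v[rng]) <= v[i] - lod_drop
        }, logical(1))
        if (!all(saddle_ok)) next
      }
      kept <- c(kept, i)
    }
    for (i in kept) {
      lim <- v[i] - lod_drop
      lo <- i; while (lo > 1 && v[lo - 1] >= lim) lo <- lo - 1
      hi <- i; while (hi < m && v[hi + 1] >= lim) hi <- hi + 1
      ci <- c(pr$pos_cM[lo], pr$pos_cM[hi])
      bp <- if (is.null(map)) c(NA_real_, NA_real_) else
        interpolate_bp(map, ch, ci)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, peak_cM = pr$pos_cM[i], ci_lo = ci[1], ci_hi = ci[2],
        lod = v[i], r2 = pr$r2[i], additive = pr$additive[i],
        allele_parent = ifelse(pr$additive[i] >= 0, parents[1], parents[2]),
        bp_lo = bp[1], bp_hi = bp[2], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(factor(out$chrom, levels = unique(profile$chrom)),
                   out$peak_cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpolate physical position (bp) from genetic position (cM)
#'
#' Linear interpolation between flanking mapped markers on the same
#' chromosome; positions beyond the terminal markers are clamped to the
#' terminal markers' bp.
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome label.
#' @param cM Genetic position(s) to interpolate.
#' @return Numeric bp values.
#' @export
interpolate_bp <- function(map, chrom, cM) {
  mk <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(mk) == 0) return(rep(NA_real_, length(cM)))
  if (nrow(mk) == 1) return(rep(mk$bp, length(cM)))
  stats::approx(mk$cM, mk$bp, xout = pmin(pmax(cM, min(mk$cM)), max(mk$cM)),
                ties = mean, rule = 2)$y
}
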