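#' Within-array MA-lowess normalization for two-colour arrays
#'
#' Computes `M = log2(R/G)` and `A = (log2 R + log2 G)/2`, fits a lowess
#' curve of M on A, and subtracts it, removing smooth intensity-dependent dye
#' bias.  Dye-swap arrays have their M values sign-flipped first so arrays can
#' be pooled on a common test/reference orientation.
#'
#' @param R,G Positive channel intensities per probe (test and reference dye).
#' @param dye_swap Logical: was this array hybridized with dyes swapped?
#' @param span Lowess smoother span in (0, 1] (default 0.3).
#' @param probes Optional probe ids used in error messages.
#' @return Data frame with columns `A`, `M` (normalized) and `M_raw`.
#' @export
lowess_ma_normalize <- function(R, G, dye_swap = FALSE, span = 0.3,
                                probes = NULL) {
  if (length(R) != length(G)) stop("R and G must have equal length")
  if (length(R) < 50) stop("need at least 50 probes for lowess normalization")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  bad <- which(!(R > 0) | !(G > 0))
  if (length(bad)) {
    nm <- if (!is.null(probes)) probes[bad[1]] else bad[1]
    stop("non-positive intensity at probe ", nm)
  }
  M <- log2(R / G)
  if (dye_swap) M <- -M
  A <- (log2(R) + log2(G)) / 2
  fit <- stats::lowess(A, M, f = span)
  Mhat <- stats::approx(fit$x, fit$y, xout = A, ties = mean, rule = 2)$y
  data.frame(A = A, M = M - Mhat, M_raw = M)
}

#' Between-array quantile normalization
#'
#' Forces every column (array/line) onto the same empirical distribution: the
#' row means of the column-wise order statistics.  Ranks within each column
#' are preserved; ties receive the mean of the tied target values.  Backed by
#' \code{limma::normalizeQuantiles}.
#'
#' @param mat Numeric matrix, probes x arrays, non-negative intensities.
#' @return Matrix of the same dimensions with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 columns to quantile-normalize")
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensities are not allowed")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Probe filtering, intensity flooring and log2 transform
#'
#' On the linear (pre-log) scale: a probe is kept iff the fraction of samples
#' with intensity strictly above `floor` is at least `min_frequency`
#' (low-signal probes are removed); surviving values below `floor` are raised
#' to `floor` as background, then log2-transformed.
#'
#' @param mat Numeric matrix, probes x samples, linear scale.
#' @param floor Background intensity floor (default 20).
#' @param min_frequency Minimum fraction of samples above `floor` for a probe
#'   to be retained (default 0.30).
#' @return A list: `matrix` (log2 scale, all values >= `log2(floor)`),
#'   `removed` (character vector of removed probe ids), `n_removed`.
#' @export
filter_and_floor <- function(mat, floor = 20, min_frequency = 0.30) {
  mat <- as.matrix(mat)
  frac <- rowMeans(mat > floor, na.rm = TRUE)
  keep <- !is.na(frac) & frac >= min_frequency
  removed <- rownames(mat)[!keep] %||% which(!keep)
  out <- mat[keep, , drop = FALSE]
  out[out < floor] <- floor
  list(matrix = log2(out), removed = as.character(removed),
       n_removed = sum(!keep))
}

#' Average replicate arrays per line
#'
#' Arithmetic mean on the log2 scale across the replicate columns of each
#' line; missing replicate values are ignored.
#'
#' @param mat Numeric matrix (log2), probes x replicate arrays.
#' @param replicate_map Character vector mapping each column of `mat` to its
#'   line id (length `ncol(mat)`).
#' @return Matrix probes x lines (columns in first-appearance order).
#' @export
average_replicates <- function(mat, replicate_map) {
  mat <- as.matrix(mat)
  if (length(replicate_map) != ncol(mat)) {
    stop("replicate_map must name a line for every column")
  }
  lines <- unique(replicate_map)
  out <- matrix(NA_real_, nrow(mat), length(lines),
                dimnames = list(rownames(mat), lines))
  for (l in lines) {
    cols <- which(replicate_map == l)
    if (!length(cols)) stop("line ", l, " has zero replicate columns")
    out[, l] <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Parental differential expression (pooled-variance t test)
#'
#' Per-transcript two-sample Student t statistic (pooled variance) between
#' the two groups of log2 expression columns, Benjamini-Hochberg adjusted
#' p-values, and signed fold change `sign(d) * 2^|d|` where
#' `d = mean(A) - mean(B)` on the log2 scale.  A transcript is flagged
#' significant when `p_adj < fdr` and `|fold change| >= fc_cut`.
#'
#' @param groupA,groupB Numeric matrices (log2), transcripts x replicates,
#'   identical rownames; >= 2 replicates each.
#' @param fdr BH-adjusted significance level (default 0.05).
#' @param fc_cut Fold-change cutoff on the linear scale (default 2).
#' @return Data frame: `transcript`, `t`, `p`, `p_adj`, `fc`, `flag`.
#' @export
differential_expression <- function(groupA, groupB, fdr = 0.05, fc_cut = 2) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) < 2 || ncol(groupB) < 2) {
    stop("need at least 2 replicates per group")
  }
  if (nrow(groupA) != nrow(groupB)) stop("groups must share transcripts")
  nA <- ncol(groupA); nB <- ncol(groupB)
  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  vA <- apply(groupA, 1, stats::var); vB <- apply(groupB, 1, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  d <- mA - mB
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  df <- nA + nB - 2
  p <- 2 * stats::pt(-abs(t), df = df)
  p[se == 0 & d == 0] <- 1  # degenerate: no variance, no difference
  p_adj <- stats::p.adjust(p, method = "BH")
  fc <- sign(d) * 2^abs(d)
  data.frame(transcript = rownames(groupA) %||% seq_len(nrow(groupA)),
             t = t, p = p, p_adj = p_adj, fc = fc,
             flag = p_adj < fdr & abs(fc) >= fc_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
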