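#' Soft-thresholding power selection for a weighted co-expression network
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed and
#' the scale-free topology fit of the connectivity distribution is scored as
#' the signed R-squared of the log10-log10 regression of binned degree
#' frequency on binned mean degree (positive when the distribution decays, as
#' a scale-free network requires).  The chosen power is the smallest whose fit
#' reaches `fit_cut`; if none does, the best-fitting power is returned with a
#' warning.
#'
#' @param expr Numeric matrix, transcripts x lines (log2 scale).
#' @param powers Candidate integer powers (default 1:20).
#' @param fit_cut Scale-free fit threshold (default 0.8).
#' @param n_bins Equal-width connectivity bins for the fit (default 10).
#' @param min_mean_k Minimum mean connectivity for a power to be eligible
#'   (default 1): beyond it the adjacency has decayed to near-zero and the
#'   fit index rewards an empty network.
#' @return List of class `soft_power_report`: `report` (data frame with
#'   `power`, `fit`, `mean_k`), `power` (chosen), `fit` (its fit value).
#' @export
pick_soft_power <- function(expr, powers = 1:20, fit_cut = 0.8, n_bins = 10,
                            min_mean_k = 1) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 50) stop("need at least 50 transcripts for soft-power selection")
  if (ncol(expr) < 10) stop("need at least 10 lines")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant transcript(s) dropped before correlation")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  rep_rows <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    data.frame(power = b, fit = scale_free_fit(k, n_bins = n_bins),
               mean_k = mean(k))
  })
  report <- do.call(rbind, rep_rows)
  hit <- which(!is.na(report$fit) & report$fit >= fit_cut &
                 report$mean_k >= min_mean_k)
  if (length(hit)) {
    chosen <- report$power[hit[1]]
  } else {
    # fallback: among powers that keep the network connected (mean
    # connectivity below ~1 means adjacency has decayed to nothing and
    # module contrast is lost regardless of the fit index), take the
    # smallest power whose fit is within 0.05 of the best usable fit —
    # nearly equal fits should not push beta toward the degenerate end
    usable <- which(report$mean_k >= min_mean_k & !is.na(report$fit))
    if (!length(usable)) usable <- which(!is.na(report$fit))
    if (!length(usable)) stop("scale-free fit undefined at every power")
    near <- usable[report$fit[usable] >= max(report$fit[usable]) - 0.05]
    chosen <- report$power[near[1]]
    warning("no candidate power reached fit >= ", fit_cut,
            "; returning best usable fit (power ", chosen, ")")
  }
  structure(list(report = report, power = chosen,
                 fit = report$fit[report$power == chosen]),
            class = "soft_power_report")
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Signed R-squared of `log10(p(k))` on `log10(mean k)` over equal-width
#' connectivity bins; positive when frequency decays with connectivity
#' (negative slope), the signature of a scale-free degree distribution.
#'
#' @param k Connectivity (degree) values.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Signed fit index in `[-1, 1]` (`NA` if fewer than 3 usable bins).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins) return(NA_real_)
  if (max(k) - min(k) < 1e-12) return(NA_real_)  # degenerate: all k equal
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9
  bin <- cut(k, breaks = br)
  pk <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  km <- tapply(k, bin, mean)
  use <- pk > 0 & !is.na(km) & km > 0
  if (sum(use) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[use]) ~ log10(km[use]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_j a_ij`; diagonal 1.  High TOM
#' means two nodes are directly connected and share neighbours.
#'
#' @param adjacency Symmetric matrix, entries in `[0, 1]`, zero diagonal.
#' @return TOM similarity matrix (symmetric, unit diagonal, entries in
#'   `[0, 1]`).
#' @export
tom_similarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A) || !isSymmetric(A, tol = 1e-10)) {
    stop("adjacency must be a symmetric matrix")
  }
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (any(A < 0 | A > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect co-expression modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' `cut_height` times the maximum merge height; branches smaller than
#' `min_size` are relabelled 0 (unassigned).  Retained modules are labelled
#' 1, 2, ... by decreasing size.
#'
#' @param tom TOM similarity matrix from [tom_similarity()].
#' @param min_size Minimum module size (default 30).
#' @param cut_height Fraction of the maximum merge height at which the tree
#'   is cut (default 0.95).
#' @return Named integer vector: module label per transcript (0 =
#'   unassigned), with the `hclust` tree in attribute `"tree"`.
#' @export
cluster_modules <- function(tom, min_size = 30, cut_height = 0.95) {
  n <- nrow(tom)
  if (n < min_size) {
    lab <- stats::setNames(rep(0L, n), rownames(tom))
    return(lab)
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  # numerically tied merges can leave sub-eps height inversions; monotonize
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  h <- cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  lab <- ifelse(raw %in% keep, raw, 0L)
  # relabel by decreasing size, deterministic
  kept_sizes <- sort(table(lab[lab != 0]), decreasing = TRUE)
  newlab <- stats::setNames(seq_along(kept_sizes), names(kept_sizes))
  out <- ifelse(lab == 0, 0L, as.integer(newlab[as.character(lab)]))
  names(out) <- rownames(tom)
  attr(out, "tree") <- tree
  out
}

#' Rescue unassigned transcripts by module membership (kME)
#'
#' The static tree cut can strand genuine module members in the unassigned
#' class when adjacency contrast is weak.  This step — the analogue of the
#' partitioning-around-medoids stage of dynamic hybrid tree cutting —
#' assigns each unassigned transcript to the module whose eigengene it
#' correlates with most strongly, provided `|kME| >= min_kme`; everything
#' else stays unassigned.
#'
#' @param expr Numeric matrix, transcripts x lines.
#' @param membership Named integer module labels (0 = unassigned).
#' @param min_kme Minimum absolute eigengene correlation for rescue
#'   (default 0.5).
#' @return Updated membership vector.
#' @export
rescue_membership <- function(expr, membership, min_kme = 0.5) {
  membership <- membership[rownames(expr)]
  mods <- sort(unique(membership[membership != 0]))
  if (!length(mods)) return(membership)
  ME <- vapply(mods, function(m) {
    as.numeric(module_eigengene(expr[membership == m, , drop = FALSE]))
  }, numeric(ncol(expr)))
  un <- which(membership == 0)
  if (length(un)) {
    kme <- stats::cor(t(expr[un, , drop = FALSE]), ME)
    best <- max.col(abs(kme), ties.method = "first")
    ok <- abs(kme[cbind(seq_along(un), best)]) >= min_kme
    membership[un[ok]] <- mods[best[ok]]
  }
  membership
}

#' Module eigengene
#'
#' First principal component of the row-standardized module expression
#' matrix, scaled to unit variance across lines and sign-oriented so that its
#' correlation with the module's mean expression profile is positive (falling
#' back to the first member transcript when the mean profile is degenerate).
#'
#' @param mod_expr Numeric matrix, module transcripts x lines (>= 2 rows).
#' @return Numeric eigengene per line with attribute `"var_explained"`, the
#'   fraction of standardized module variance captured.
#' @export
module_eigengene <- function(mod_expr) {
  X <- as.matrix(mod_expr)
  if (nrow(X) < 2) stop("module must contain at least 2 transcripts")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance transcript(s) dropped from module")
    X <- X[sds > 0, , drop = FALSE]
    if (nrow(X) < 2) stop("fewer than 2 informative transcripts in module")
  }
  Xs <- t(scale(t(X)))
  sv <- svd(Xs, nu = 0, nv = 1)
  me <- sv$v[, 1]
  mean_prof <- colMeans(Xs)
  ref <- if (stats::sd(mean_prof) > 1e-12) mean_prof else Xs[1, ]
  if (stats::cor(me, ref) < 0) me <- -me
  me <- as.numeric(scale(me))
  names(me) <- colnames(X)
  attr(me, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  me
}

#' Build a module set (membership + eigengenes)
#'
#' @param expr Numeric matrix, transcripts x lines.
#' @param membership Named integer module labels (0 = unassigned), as from
#'   [cluster_modules()].
#' @return Object of class `module_set`: list with `membership`,
#'   `eigengenes` (lines x modules matrix, columns `ME1`, `ME2`, ...),
#'   `var_explained`, `merge_history` (empty data frame until
#'   [merge_modules()]).
#' @export
module_set <- function(expr, membership) {
  expr <- as.matrix(expr)
  membership <- membership[rownames(expr)]
  mods <- sort(unique(membership[membership != 0]))
  ME <- matrix(NA_real_, ncol(expr), length(mods))
  dimnames(ME) <- list(colnames(expr), paste0("ME", mods))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    me <- module_eigengene(expr[membership == mods[i], , drop = FALSE])
    ME[, i] <- me
    ve[i] <- attr(me, "var_explained")
  }
  structure(list(membership = membership, eigengenes = ME,
                 var_explained = ve,
                 merge_history = data.frame(absorbed = integer(),
                                            surviving = integer(),
                                            cor = numeric())),
            class = "module_set")
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' at or above `similarity_cut`, recomputing eigengenes after each merge,
#' until no pair remains.  The larger module's label survives (ties: smaller
#' label); every merge is recorded.
#'
#' @param ms A `module_set`.
#' @param expr The expression matrix the module set was built from.
#' @param similarity_cut Eigengene correlation threshold (default 0.75).
#' @return The merged `module_set` with a filled `merge_history`.
#' @export
merge_modules <- function(ms, expr, similarity_cut = 0.75) {
  stopifnot(inherits(ms, "module_set"))
  membership <- ms$membership
  history <- ms$merge_history
  repeat {
    cur <- module_set(expr, membership)
    ME <- cur$eigengenes
    if (ncol(ME) < 2) break
    cc <- stats::cor(ME)
    diag(cc) <- -Inf
    mx <- max(cc)
    if (mx < similarity_cut) break
    idx <- which(cc == mx, arr.ind = TRUE)[1, ]
    labs <- as.integer(sub("^ME", "", colnames(ME)[idx]))
    sizes <- c(sum(membership == labs[1]), sum(membership == labs[2]))
    surv <- if (sizes[1] > sizes[2]) labs[1]
            else if (sizes[2] > sizes[1]) labs[2] else min(labs)
    gone <- setdiff(labs, surv)
    membership[membership == gone] <- surv
    history <- rbind(history,
                     data.frame(absorbed = gone, surviving = surv, cor = mx))
  }
  out <- module_set(expr, membership)
  out$merge_history <- history
  out
}

#' Module-trait association
#'
#' Pearson correlation between each module eigengene and each trait, with
#' two-sided p-values from the t distribution on `n - 2` degrees of freedom;
#' missing trait values are pairwise-deleted.
#'
#' @param ms A `module_set`.
#' @param traits Data frame or matrix, lines x traits (rownames = line ids
#'   matching the eigengene rows).
#' @param min_shared Minimum shared lines per pair (default 5).
#' @return Data frame: `module`, `trait`, `r`, `p`, `n` (constant traits
#'   yield `NA`).
#' @export
module_trait_association <- function(ms, traits, min_shared = 5) {
  stopifnot(inherits(ms, "module_set"))
  ME <- ms$eigengenes
  traits <- as.matrix(traits)
  common <- intersect(rownames(ME), rownames(traits))
  if (length(common) < min_shared) stop("fewer than ", min_shared, " shared lines")
  ME <- ME[common, , drop = FALSE]; traits <- traits[common, , drop = FALSE]
  out <- expand.grid(module = colnames(ME), trait = colnames(traits),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    x <- ME[, out$module[i]]; y <- traits[, out$trait[i]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    out$n[i] <- n
    if (n < min_shared || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) next
    r <- stats::cor(x[ok], y[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    out$r[i] <- r
    out$p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  out
}

#' Hard-threshold co-expression edge list
#'
#' Undirected edges between transcript pairs with `|cor| >= cut`; node
#' degrees and the scale-free fit of the degree distribution are reported
#' (not enforced).
#'
#' @param expr Numeric matrix, transcripts x lines.
#' @param cut Absolute correlation cutoff (default 0.75).
#' @return List: `edges` (data frame `node_a`, `node_b`, `r`), `degrees`
#'   (named integer vector over all transcripts), `powerlaw_fit` (signed
#'   R-squared, `NA` when too few connected nodes).
#' @export
hard_threshold_edges <- function(expr, cut = 0.75) {
  expr <- as.matrix(expr)
  cc <- stats::cor(t(expr))
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  idx <- which(abs(cc) >= cut & upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(node_a = rownames(cc)[idx[, 1]],
                      node_b = colnames(cc)[idx[, 2]],
                      r = cc[idx], stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(nrow(cc)), rownames(cc))
  if (nrow(edges)) {
    tb <- table(c(edges$node_a, edges$node_b))
    deg[names(tb)] <- as.integer(tb)
  }
  list(edges = edges, degrees = deg,
       powerlaw_fit = scale_free_fit(deg[deg > 0], n_bins = 5))
}
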