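#' Map functions: genetic distance to recombination fraction
#'
#' Convert genetic distances (cM) to recombination fractions and back.
#' The Haldane map function assumes no crossover interference, which makes
#' flanking-marker conditioning exact for doubled haploid (DH) gametes; it is
#' the package default throughout. Kosambi is provided for distance/fraction
#' conversion only.
#'
#' @param d Genetic distance(s) in centimorgans, `d >= 0` (`Inf` allowed and
#'   saturates at `r = 0.5`).
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return `haldane_d_to_r()` and `kosambi_d_to_r()` return recombination
#'   fractions in `[0, 0.5)`; the `*_r_to_d()` inverses return distances in cM.
#' @examples
#' haldane_d_to_r(10)            # 0.0906...
#' haldane_r_to_d(haldane_d_to_r(25))  # 25
#' @export
haldane_d_to_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("genetic distance must be >= 0")
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane_d_to_r
#' @export
haldane_r_to_d <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) stop("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_d_to_r
#' @export
kosambi_d_to_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("genetic distance must be >= 0")
  0.5 * tanh(2 * d / 100)
}

#' @rdname haldane_d_to_r
#' @export
kosambi_r_to_d <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) stop("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Construct and validate a genetic map
#'
#' A genetic map is a data frame with one row per marker carrying both the
#' genetic (cM) and physical (bp) coordinate systems used downstream for QTL
#' support intervals and the cis/trans rule.
#'
#' @param chrom Chromosome label per marker.
#' @param marker Unique marker names.
#' @param cM Genetic position, non-decreasing within each chromosome.
#' @param bp Physical position, 1-based integer-valued, `>= 1`.
#' @return A `data.frame` of class `genetic_map` with columns
#'   `marker`, `chrom`, `cM`, `bp`, ordered by chromosome then cM.
#' @export
genetic_map <- function(chrom, marker, cM, bp) {
  map <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                    cM = as.numeric(cM), bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  validate_genetic_map(map)
}

#' @rdname genetic_map
#' @param map A data frame with columns `marker`, `chrom`, `cM`, `bp`.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker", "chrom", "cM", "bp")
  if (!all(need %in% names(map))) {
    stop("genetic map must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$marker)) stop("marker names must be unique")
  if (any(map$cM < 0)) stop("cM positions must be >= 0")
  if (any(map$bp < 1)) stop("bp positions must be >= 1 (1-based)")
  map <- map[order(factor(map$chrom, levels = unique(map$chrom)), map$cM), ,
             drop = FALSE]
  for (ch in unique(map$chrom)) {
    pos <- map$cM[map$chrom == ch]
    if (is.unsorted(pos)) stop("cM positions must be non-decreasing within chromosome ", ch)
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Validate a DH genotype matrix against a genetic map
#'
#' Doubled haploid lines are fully homozygous: genotype codes are 0 (allele of
#' the first parent), 1 (allele of the second parent) or `NA`.  Any other code
#' (in particular a heterozygote) violates the DH contract and is an error.
#'
#' @param geno Numeric matrix, lines x markers, rownames = line ids,
#'   colnames = marker names.
#' @param map A `genetic_map`; column order of `geno` is checked (and
#'   reordered if needed) to match the map's marker order.
#' @return The validated (possibly column-reordered) genotype matrix.
#' @export
validate_genotypes <- function(geno, map = NULL) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  bad <- !(geno %in% c(0, 1) | is.na(geno))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid DH genotype code '%s' at line '%s', marker '%s' (allowed: 0, 1, NA)",
                 format(geno[idx[1], idx[2]]),
                 rownames(geno)[idx[1]] %||% idx[1],
                 colnames(geno)[idx[2]] %||% idx[2]))
  }
  if (!is.null(map)) {
    if (!all(map$marker %in% colnames(geno))) {
      stop("genotype matrix is missing markers present in the map")
    }
    geno <- geno[, map$marker, drop = FALSE]
    all_na <- colMeans(is.na(geno)) >= 1
    if (any(all_na)) {
      stop("marker(s) entirely missing: ", paste(colnames(geno)[all_na], collapse = ", "))
    }
  }
  storage.mode(geno) <- "double"
  geno
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conditional QTL genotype probability for DH lines
#'
#' Probability that a putative QTL position carries the parent-0 allele given
#' the genotypes at the flanking markers, under the Haldane (no-interference)
#' gamete model for a DH line.  With both flanks observed as parent-0 the
#' closed form is `p0 = (1-rL)(1-rR) / [(1-rL)(1-rR) + rL*rR]`.  A missing
#' flank conditions on the observed side only; both missing gives 0.5.
#'
#' @param g_left,g_right Flanking genotype codes in \{0, 1, NA\} (vectorised).
#' @param r_left,r_right Recombination fractions to the flanks, in `[0, 0.5)`
#'   (0.5 allowed as the unlinked limit).
#' @return Probability `p0` of the parent-0 class at the test position.
#' @export
dh_qtl_probabilities <- function(g_left, g_right, r_left, r_right) {
  n <- max(length(g_left), length(g_right), length(r_left), length(r_right))
  g_left  <- rep_len(g_left, n);  g_right <- rep_len(g_right, n)
  r_left  <- rep_len(r_left, n);  r_right <- rep_len(r_right, n)
  ok <- function(g) all(g %in% c(0, 1) | is.na(g))
  if (!ok(g_left) || !ok(g_right)) {
    stop("DH genotype codes must be 0, 1 or NA (no heterozygotes)")
  }
  if (any(r_left < 0 | r_left > 0.5) || any(r_right < 0 | r_right > 0.5)) {
    stop("recombination fractions must lie in [0, 0.5]")
  }
  # P(flank | QTL class 0): stays parental with prob 1-r
  tL0 <- ifelse(is.na(g_left),  NA_real_, ifelse(g_left == 0, 1 - r_left, r_left))
  tR0 <- ifelse(is.na(g_right), NA_real_, ifelse(g_right == 0, 1 - r_right, r_right))
  p0 <- ifelse(is.na(tL0) & is.na(tR0), 0.5,
        ifelse(is.na(tL0), tR0,
        ifelse(is.na(tR0), tL0,
               tL0 * tR0 / (tL0 * tR0 + (1 - tL0) * (1 - tR0)))))
  p0
}

#' Build an evaluation grid along the genetic map
#'
#' Positions every `step` cM from the first to the last marker of each
#' chromosome, with every marker position inserted exactly once (ties broken
#' toward marker positions).  Each grid point records its flanking markers and
#' the Haldane recombination fractions to them.
#'
#' @param map A `genetic_map`.
#' @param step Walking speed in cM (> 0); default 1 cM.
#' @param map_function `"haldane"` (default) or `"kosambi"` for the
#'   distance-to-fraction conversion stored on the grid.
#' @return Data frame of class `eval_grid`: `chrom`, `pos_cM`, `left`,
#'   `right` (row indices into `map`), `r_left`, `r_right`, `at_marker`
#'   (marker name or `NA`).
#' @export
build_grid <- function(map, step = 1, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  d2r <- if (map_function == "haldane") haldane_d_to_r else kosambi_d_to_r
  if (step <= 0) stop("step must be > 0")
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    mpos <- map$cM[idx]
    if (length(idx) < 2) {
      warning("chromosome ", ch, " has fewer than 2 markers; single-position grid")
      pos <- mpos
    } else {
      # walk restarts at each marker so markers are always evaluated exactly
      pos <- unlist(lapply(seq_len(length(mpos) - 1), function(i) {
        seg <- seq(mpos[i], mpos[i + 1], by = step)
        seg[seg < mpos[i + 1] - 1e-8]
      }))
      pos <- c(pos, mpos[length(mpos)])
      pos <- pos[c(TRUE, diff(pos) > 1e-8)]
    }
    li <- findInterval(pos, mpos, rightmost.closed = FALSE)
    li <- pmin(pmax(li, 1), length(idx))
    ri <- pmin(li + 1, length(idx))
    at <- abs(mpos[li] - pos) < 1e-8
    ri[at] <- li[at]
    at_r <- !at & abs(mpos[ri] - pos) < 1e-8
    li[at_r] <- ri[at_r]
    out[[ch]] <- data.frame(
      chrom = ch, pos_cM = pos,
      left = idx[li], right = idx[ri],
      r_left  = d2r(pos - mpos[li]),
      r_right = d2r(mpos[ri] - pos),
      at_marker = ifelse(li == ri, map$marker[idx[li]], NA_character_),
      stringsAsFactors = FALSE
    )
  }
  grid <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos_cM = numeric(), left = integer(),
               right = integer(), r_left = numeric(), r_right = numeric(),
               at_marker = character(), stringsAsFactors = FALSE)
  rownames(grid) <- NULL
  class(grid) <- c("eval_grid", "data.frame")
  grid
}

#' Expected QTL genotype at every grid position
#'
#' For each line and grid position, the conditional expectation of the
#' genotype code (0/1) given the nearest non-missing flanking markers — the
#' regressor used by Haley-Knott interval mapping.  Fully observed lines are
#' vectorised per position; lines with missing marker data condition on the
#' nearest observed marker on each side.
#'
#' @param geno Validated DH genotype matrix (lines x markers, map order).
#' @param map The `genetic_map` matching `geno` columns.
#' @param grid An `eval_grid` from [build_grid()].
#' @return Numeric matrix, lines x grid positions, entries in `[0, 1]`
#'   (`E[code] = P(parent-1 allele)`).
#' @export
expected_genotype_matrix <- function(geno, map, grid) {
  n <- nrow(geno)
  P <- matrix(NA_real_, n, nrow(grid), dimnames = list(rownames(geno), NULL))
  has_na <- rowSums(is.na(geno)) > 0
  for (ch in unique(grid$chrom)) {
    gsel <- which(grid$chrom == ch)
    midx <- which(map$chrom == ch)
    mpos <- map$cM[midx]
    G <- geno[, midx, drop = FALSE]
    # complete lines: flanks are common across lines at each position
    comp <- !has_na
    for (j in gsel) {
      lL <- match(grid$left[j], midx); lR <- match(grid$right[j], midx)
      p0 <- dh_qtl_probabilities(G[comp, lL], G[comp, lR],
                                 grid$r_left[j], grid$r_right[j])
      P[comp, j] <- 1 - p0
    }
    # lines with missing data: nearest non-missing flank per side
    for (i in which(has_na)) {
      obs <- which(!is.na(G[i, ]))
      if (length(obs) == 0) { P[i, gsel] <- 0.5; next }
      opos <- mpos[obs]
      for (j in gsel) {
        p <- grid$pos_cM[j]
        iL <- findInterval(p, opos)
        # an observed marker exactly at p is its own flank on both sides (r = 0)
        iR <- if (iL >= 1 && abs(opos[iL] - p) < 1e-8) iL else iL + 1
        gl <- if (iL >= 1) G[i, obs[iL]] else NA_real_
        rl <- if (iL >= 1) haldane_d_to_r(p - opos[iL]) else 0.5
        gr <- if (iR >= 1 && iR <= length(obs)) G[i, obs[iR]] else NA_real_
        rr <- if (iR >= 1 && iR <= length(obs)) haldane_d_to_r(abs(opos[iR] - p)) else 0.5
        P[i, j] <- 1 - dh_qtl_probabilities(gl, gr, rl, rr)
      }
    }
  }
  P
}
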