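#' Read and write study files
#'
#' Plain-text readers/writers for every format the pipeline consumes or
#' emits.  Coordinates are cM floats and 1-based inclusive bp internally;
#' BED input is 0-based half-open and converted to a 1-based midpoint at the
#' boundary.  Readers validate schemas and reject malformed cells with the
#' offending location.
#'
#' @param path File path.
#' @name study_io
NULL

#' @describeIn study_io Genetic map TSV with header `marker chrom cM bp`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_genetic_map(tab)
}

#' @describeIn study_io Write a genetic map TSV.
#' @param map A `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn study_io Genotype CSV: first column line id, remaining columns
#'   marker codes in \{0, 1, NA\}; invalid cells are reported with line id
#'   and marker name.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(tab[[1]])
  validate_genotypes(g)
}

#' @describeIn study_io Write a genotype CSV.
#' @param geno Genotype matrix.
#' @export
write_genotypes <- function(geno, path) {
  out <- data.frame(line = rownames(geno), geno, check.names = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn study_io Expression TSV: first column `transcript`, remaining
#'   columns line ids.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "transcript") stop("first column must be 'transcript'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$transcript
  m
}

#' @describeIn study_io Write an expression TSV.
#' @param expr Expression matrix, transcripts x lines.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(transcript = rownames(expr), expr, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn study_io Transcript positions from BED-like TSV
#'   `chrom start end transcript` (0-based half-open); returns a data frame
#'   `transcript`, `chrom`, `bp` with `bp` the 1-based interval midpoint.
#' @export
read_gene_positions <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "transcript"))
  if (any(tab$end <= tab$start)) {
    bad <- which(tab$end <= tab$start)[1]
    stop("empty/inverted BED interval at row ", bad)
  }
  data.frame(transcript = tab$transcript, chrom = tab$chrom,
             bp = floor((tab$start + 1 + tab$end) / 2),
             stringsAsFactors = FALSE)
}

#' @describeIn study_io Write transcript positions as BED (0-based
#'   half-open, a 1-bp feature at the stored midpoint).
#' @param gene_pos Data frame `transcript`, `chrom`, `bp`.
#' @export
write_gene_positions <- function(gene_pos, path) {
  bed <- data.frame(chrom = gene_pos$chrom, start = gene_pos$bp - 1,
                    end = gene_pos$bp, transcript = gene_pos$transcript)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @describeIn study_io Trait TSV: first column `line`, one column per trait.
#' @export
read_traits <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "line") stop("first column must be 'line'")
  rownames(tab) <- tab$line
  tab[, -1, drop = FALSE]
}

#' @describeIn study_io Write a trait TSV.
#' @param traits Data frame, lines x traits, rownames = line ids.
#' @export
write_traits <- function(traits, path) {
  out <- data.frame(line = rownames(traits), traits, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn study_io Write an edge list in Cytoscape SIF format
#'   (`nodeA cc nodeB`).
#' @param edges Data frame with `node_a`, `node_b`.
#' @export
write_sif <- function(edges, path) {
  utils::write.table(data.frame(edges$node_a, "cc", edges$node_b),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic study to a directory
#'
#' Emits every format the pipeline reads (map TSV, genotype CSV, expression
#' TSV, trait TSV, gene-position BED), the ground truth tables under
#' `truth/`, and the generating configuration as YAML.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_genetic_map(study$map, file.path(dir, "map.tsv"))
  write_genotypes(study$geno, file.path(dir, "genotypes.csv"))
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_traits(study$traits, file.path(dir, "traits.tsv"))
  write_gene_positions(study$gene_pos, file.path(dir, "gene_positions.bed"))
  utils::write.table(
    data.frame(transcript = names(study$truth$membership),
               module = study$truth$membership),
    file.path(dir, "truth", "membership.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$eqtl, file.path(dir, "truth", "eqtl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$trait_qtl,
                     file.path(dir, "truth", "trait_qtl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- study$config
  cfg$chromosomes <- as.list(as.data.frame(cfg$chromosomes))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
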