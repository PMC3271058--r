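#' Write a genotype panel as VCF 4.2
#'
#' One record per variant on a synthetic chromosome (named after the gene),
#' GT as the only FORMAT field, unphased genotypes, missing entries encoded
#' as "./.". Dosage 1 is written as "0/1" and dosage 2 as "1/1".
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param file output path (plain text).
#' @return invisibly, the file path.
#' @seealso \code{\link{readPanelVCF}}
#' @export
writePanelVCF <- function(panel, file) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  pos <- SummarizedExperiment::rowData(panel)$position
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", geneId(panel)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i)
    paste(c(geneId(panel), pos[i], rownames(d)[i], "A", "T", ".", "PASS",
            ".", "GT", gt[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a genotype panel from VCF
#'
#' Parses a single-gene VCF (GT field, "./." missing) back into a
#' \code{\linkS4class{GenotypePanel}}; the round trip with
#' \code{\link{writePanelVCF}} reproduces the dosage matrix exactly.
#'
#' @param file VCF path.
#' @param geneId gene label for the panel; defaults to the CHROM of the
#'   first record.
#' @param mafThreshold active rare threshold.
#' @return a \code{\linkS4class{GenotypePanel}}.
#' @export
readPanelVCF <- function(file, geneId = NULL, mafThreshold = 0.01) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count1 <- function(x) {
    out <- rep(NA_integer_, length(x))
    known <- !is.na(x) & !grepl("\\.", x)
    out[known] <- vapply(strsplit(x[known], "[/|]"), function(a)
      sum(a == "1"), integer(1))
    out
  }
  d <- matrix(count1(as.vector(gt)), nrow(gt), ncol(gt),
              dimnames = dimnames(gt))
  if (is.null(geneId)) geneId <- as.character(v@fix[1, "CHROM"])
  GenotypePanel(d, geneId, mafThreshold = mafThreshold,
                positions = as.integer(v@fix[, "POS"]))
}

#' Write a panel as a dosage-matrix TSV
#'
#' Individuals in rows, variants in columns, header row of variant ids,
#' first column of individual ids, "NA" for missing entries.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeDosageTSV <- function(panel, file) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- t(dosages(panel))
  df <- data.frame(individual = rownames(d), d, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a dosage-matrix TSV into a panel
#'
#' @param file TSV written by \code{\link{writeDosageTSV}} (or of the same
#'   layout).
#' @param geneId gene label for the panel.
#' @param mafThreshold active rare threshold.
#' @return a \code{\linkS4class{GenotypePanel}}.
#' @export
readDosageTSV <- function(file, geneId = "gene", mafThreshold = 0.01) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ind <- df[[1]]
  d <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(d) <- "integer"
  colnames(d) <- ind
  GenotypePanel(d, geneId, mafThreshold = mafThreshold)
}

#' Read gene profiles from a YAML config block
#'
#' The config lists one block per gene under \code{genes:}, each with
#' fields \code{gene_id, n_variants, n_rare, median_maf, missing_rate,
#' coding_length_bp, singleton_fraction, carrier_count_dist} (the histogram
#' as a list of counts for 0, 1, 2, ... carried rare variants).
#'
#' @param file YAML path.
#' @return named list of \code{\linkS4class{GeneProfile}}.
#' @seealso \code{\link{writeGeneProfiles}}, \code{\link{defaultGeneProfiles}}
#' @export
readGeneProfiles <- function(file) {
  cfg <- yaml::read_yaml(file)
  blocks <- if (!is.null(cfg$genes)) cfg$genes else cfg
  out <- lapply(blocks, function(b) {
    ccd <- as.integer(unlist(b$carrier_count_dist))
    names(ccd) <- as.character(seq_along(ccd) - 1L)
    GeneProfile(b$gene_id, b$n_variants, b$n_rare, b$median_maf,
                b$missing_rate, b$coding_length_bp, b$singleton_fraction,
                ccd)
  })
  names(out) <- vapply(out, geneId, "")
  out
}

#' Write gene profiles to a YAML config block
#'
#' @param profiles list of \code{\linkS4class{GeneProfile}}.
#' @param file output YAML path.
#' @return invisibly, the file path.
#' @export
writeGeneProfiles <- function(profiles, file) {
  blocks <- lapply(profiles, function(p) list(
    gene_id = p@geneId, n_variants = p@nVariants, n_rare = p@nRare,
    median_maf = p@medianMAF, missing_rate = p@missingRate,
    coding_length_bp = p@codingLength,
    singleton_fraction = p@singletonFraction,
    carrier_count_dist = as.list(unname(p@carrierCountDist))))
  yaml::write_yaml(list(genes = unname(blocks)), file, precision = 12L)
  invisible(file)
}

#' Write phenotype replicates as TSV
#'
#' Long format: individual id, replicate, y, label (empty when the
#' phenotype is continuous).
#'
#' @param phenos list of \code{\linkS4class{PhenotypeSet}} (or one).
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writePhenotypeTSV <- function(phenos, file) {
  if (is(phenos, "PhenotypeSet")) phenos <- list(phenos)
  rows <- lapply(phenos, function(ph) {
    lab <- if (length(ph@labels)) as.character(ph@labels) else ""
    data.frame(individual = if (is.null(names(ph@y)))
                 sprintf("I%04d", seq_along(ph@y)) else names(ph@y),
               replicate = ph@replicateId, y = ph@y, label = lab)
  })
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
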