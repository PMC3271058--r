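#' Dosage matrix of a panel
#'
#' Returns the variants x individuals minor-allele dosage matrix
#' (0/1/2, NA = missing).
#'
#' @param x a \code{GenotypePanel}.
#' @return integer matrix, variants in rows, individuals in columns.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Per-variant minor-allele frequencies
#'
#' MAFs computed on non-missing entries, as stored in \code{rowData}.
#'
#' @param x a \code{GenotypePanel}.
#' @return numeric vector, one MAF per variant.
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' Gene label of an object
#'
#' @param x a \code{GenotypePanel} or \code{GeneProfile}.
#' @return single character gene id.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' Rare-variant flags of a panel
#'
#' @param x a \code{GenotypePanel}.
#' @param threshold MAF threshold; defaults to the panel's active threshold
#'   (stored in metadata, 0.01 unless changed).
#' @return logical vector, TRUE for variants with MAF <= threshold.
#' @export
setGeneric("isRare", function(x, threshold = NULL) standardGeneric("isRare"))

#' Number of individuals in a panel
#'
#' @param x a \code{GenotypePanel}.
#' @return integer.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Phenotype values
#'
#' @param x a \code{PhenotypeSet}.
#' @return numeric vector of continuous trait values.
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' Case/control labels
#'
#' @param x a \code{PhenotypeSet}.
#' @return factor with levels case/control/excluded, or a length-zero
#'   factor when the phenotype has not been dichotomized.
#' @export
setGeneric("caseLabels", function(x) standardGeneric("caseLabels"))

#' Indices of causal variants
#'
#' @param x a \code{CausalAssignment}.
#' @return integer vector of variant indices.
#' @export
setGeneric("causalIndex", function(x) standardGeneric("causalIndex"))

#' Per-causal-variant mean shifts
#'
#' @param x a \code{CausalAssignment}.
#' @return numeric vector of signed carrier mean shifts (SD units).
#' @export
setGeneric("effectMeans", function(x) standardGeneric("effectMeans"))
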