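#' Sample identifiers of a container
#' @param x object.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Population label per sample
#' @param x object.
#' @return named character vector (sample id -> population), `NA` for
#'   unlabelled samples.
#' @export
setGeneric("populationOf", function(x) standardGeneric("populationOf"))

#' Group label per population
#' @param x object.
#' @return named character vector (population -> group); empty if no grouping.
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))

#' Inter-haplotype mutational step distances
#'
#' Number of differing characters between haplotype signatures, counting each
#' substitution column and each indel event as one mutational step.
#' Characters undefined for either haplotype (terminal-gap missing data) do
#' not contribute.
#'
#' @param x a \linkS4class{HaplotypeTable}.
#' @param type \code{"all"} (substitutions + indel events) or
#'   \code{"substitution"} (substitution columns only, as used by nucleotide
#'   diversity).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("stepDistances", function(x, type = c("all", "substitution"))
  standardGeneric("stepDistances"))

#' Haplotype id per sample
#' @param x a \linkS4class{HaplotypeTable}.
#' @return named character vector sample id -> haplotype id.
#' @export
setGeneric("haplotypeOf", function(x) standardGeneric("haplotypeOf"))

#' Haplotype-by-population count matrix
#' @param x a \linkS4class{HaplotypeTable}.
#' @return integer matrix haplotype x population.
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' Admixture proportions of a clustering result
#' @param x a \linkS4class{ClusterResult}.
#' @return samples x K matrix, rows summing to 1.
#' @export
setGeneric("admixtureQ", function(x) standardGeneric("admixtureQ"))

#' Cluster allele frequencies of a clustering result
#' @param x a \linkS4class{ClusterResult}.
#' @return list over loci of K x alleles frequency matrices.
#' @export
setGeneric("alleleFreqP", function(x) standardGeneric("alleleFreqP"))

#' Estimated model log-probability
#' @param x a \linkS4class{ClusterResult}.
#' @return numeric scalar ln P(D) estimate.
#' @export
setGeneric("logProbData", function(x) standardGeneric("logProbData"))
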