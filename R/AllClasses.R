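#' @import methods
NULL

#' Gapped plastome alignment with population labels
#'
#' The central container of the package: an equal-width, gapped multiple
#' sequence alignment of plastomes (or marker regions) stored as a
#' \linkS4class{DNAStringSet}, together with an optional sample-to-population
#' map and an optional population-to-group map. Every downstream analysis
#' (hotspot scanning, haplotype collapsing, differentiation statistics,
#' networks) consumes this object.
#'
#' @slot seqs \code{DNAStringSet} of equal width; names are sample identifiers.
#' @slot population named character vector mapping sample id to population.
#' @slot group named character vector mapping population to group.
#' @name PlastomeAlignment-class
#' @exportClass PlastomeAlignment
setClass("PlastomeAlignment",
  slots = c(seqs = "DNAStringSet", population = "character", group = "character"))

setValidity("PlastomeAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return("all sequences must have identical length (is this an alignment?)")
  if (w[1] < 1L) return("alignment width must be >= 1")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) return("sample ids must be non-empty")
  if (anyDuplicated(ids)) return("sample ids must be unique")
  if (length(object@population)) {
    labelled <- names(object@population)
    if (is.null(labelled) || any(!nzchar(labelled)))
      return("population labels must be named by sample id")
    if (!all(labelled %in% ids))
      return("every labelled sample id must exist in the alignment")
    if (any(!nzchar(object@population)))
      return("population names must be non-empty")
  }
  TRUE
})

#' Haplotype table with variant signatures and per-population counts
#'
#' The bridge from an alignment to population statistics: each distinct joint
#' state over the analyzed polymorphic characters (substitution columns plus
#' binary indel-event characters) is one haplotype. Haplotypes are numbered
#' H1, H2, ... by decreasing global count (ties by first occurrence among
#' samples sorted by id), which makes the numbering reproducible under input
#' order permutation.
#'
#' @slot signatures character matrix (haplotype x character) of states; `NA`
#'   marks a character undefined for a haplotype (terminal-gap missing data).
#' @slot charType character vector: \code{"substitution"} or \code{"indel"}.
#' @slot charColumn integer vector of 1-based alignment columns (leftmost
#'   column for indel characters) in the trimmed alignment.
#' @slot counts integer matrix haplotype x population.
#' @slot sampleHaplotype named character vector sample id -> haplotype id.
#' @slot nTotal total number of samples.
#' @slot lEffective number of gap-free analyzed sites used as the length
#'   denominator of nucleotide diversity.
#' @name HaplotypeTable-class
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  slots = c(signatures = "matrix", charType = "character",
            charColumn = "integer", counts = "matrix",
            sampleHaplotype = "character", nTotal = "integer",
            lEffective = "integer"))

setValidity("HaplotypeTable", function(object) {
  if (sum(object@counts) != object@nTotal)
    return("counts must sum to nTotal")
  if (nrow(object@signatures) != nrow(object@counts))
    return("signatures and counts must have one row per haplotype")
  if (ncol(object@signatures) != length(object@charType))
    return("one charType per signature column required")
  if (length(object@sampleHaplotype) != object@nTotal)
    return("every sample must map to exactly one haplotype")
  if (!all(object@sampleHaplotype %in% rownames(object@counts)))
    return("sample haplotype ids must appear in the table")
  TRUE
})

#' Median-joining haplotype network
#'
#' @slot nodes data.frame with columns \code{id}, \code{kind} (\code{observed}
#'   or \code{median}) and \code{frequency} (sample count for observed nodes,
#'   \code{NA} for medians).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (mutational steps).
#' @slot states character matrix of node state vectors (rows follow nodes).
#' @slot epsilon relaxation parameter of the underlying minimum spanning
#'   network.
#' @name HaplotypeNetwork-class
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame",
            states = "matrix", epsilon = "numeric"))

setValidity("HaplotypeNetwork", function(object) {
  if (nrow(object@nodes) > 1L) {
    if (nrow(object@edges) == 0L) return("network with >1 node must have edges")
    if (any(object@edges$weight < 1)) return("edge weights must be >= 1")
    g <- igraph::graph_from_data_frame(object@edges, directed = FALSE,
                                       vertices = object@nodes$id)
    if (!igraph::is_connected(g)) return("network must be connected")
  }
  if (!all(object@nodes$kind %in% c("observed", "median")))
    return("node kind must be observed or median")
  TRUE
})

#' Admixture-model clustering result
#'
#' Output of the haploid Gibbs sampler: posterior-mean admixture proportions,
#' per-cluster allele frequencies, the model log-probability estimate
#' \code{lnpd = mean(lnL) - var(lnL)/2} over post-burn-in sweeps, and the
#' per-sweep log-likelihood trace.
#'
#' @slot K number of clusters.
#' @slot Q samples x K matrix of admixture proportions (rows sum to 1).
#' @slot P list over loci of K x alleles frequency matrices (rows sum to 1).
#' @slot lnpd estimated ln P(D).
#' @slot trace per-sweep log-likelihoods (post-burn-in).
#' @slot burnin,iters sweep counts used.
#' @slot alpha0 Dirichlet admixture prior.
#' @slot lambda allele-frequency prior.
#' @slot seed integer seed (NA if none supplied).
#' @slot model model description string (records the independent
#'   allele-frequency prior).
#' @name ClusterResult-class
#' @exportClass ClusterResult
setClass("ClusterResult",
  slots = c(K = "integer", Q = "matrix", P = "list", lnpd = "numeric",
            trace = "numeric", burnin = "integer", iters = "integer",
            alpha0 = "numeric", lambda = "numeric", seed = "integer",
            model = "character"))

setValidity("ClusterResult", function(object) {
  if (ncol(object@Q) != object@K) return("Q must have K columns")
  if (any(abs(rowSums(object@Q) - 1) > 1e-9)) return("Q rows must sum to 1")
  for (pl in object@P)
    if (any(abs(rowSums(pl) - 1) > 1e-9)) return("P rows must sum to 1")
  if (!is.finite(object@lnpd)) return("lnpd must be finite")
  TRUE
})

#' Synthetic plastome specification
#'
#' Describes the quadripartite reference plastome to simulate: the lengths of
#' the large single-copy (LSC), small single-copy (SSC) and inverted-repeat
#' (IR) regions, a background GC fraction, and AT-biased mutational hotspot
#' intervals where SNPs, indels and cpSSRs co-occur. Layout is
#' LSC | IRA | SSC | IRB with IRB the reverse complement of IRA.
#'
#' @slot lscLength,sscLength,irLength region lengths in bp.
#' @slot gcBackground background GC fraction in (0,1).
#' @slot hotspots data.frame with columns \code{start}, \code{end} (1-based
#'   closed, on the full genome), \code{gc_local}, \code{snp_rate},
#'   \code{indel_rate}.
#' @slot ssrSeeds data.frame with columns \code{hotspot} (row index into
#'   \code{hotspots}), \code{motif}, \code{units}.
#' @name PlastomeSpec-class
#' @exportClass PlastomeSpec
setClass("PlastomeSpec",
  slots = c(lscLength = "integer", sscLength = "integer", irLength = "integer",
            gcBackground = "numeric", hotspots = "data.frame",
            ssrSeeds = "data.frame"))

setValidity("PlastomeSpec", function(object) {
  total <- object@lscLength + object@sscLength + 2L * object@irLength
  if (object@lscLength < 1L || object@sscLength < 0L || object@irLength < 0L)
    return("region lengths must be positive (SSC/IR may be 0)")
  if (object@gcBackground <= 0 || object@gcBackground >= 1)
    return("gcBackground must lie in (0,1)")
  h <- object@hotspots
  if (nrow(h)) {
    if (any(h$start < 1) || any(h$end > total) || any(h$end < h$start))
      return("hotspot intervals must lie within [1, total length]")
    rates <- c(h$snp_rate, h$indel_rate)
    if (any(rates < 0) || any(rates > 1)) return("rates must lie in [0,1]")
    if (any(h$gc_local <= 0) || any(h$gc_local >= 1))
      return("gc_local must lie in (0,1)")
    o <- order(h$start)
    if (nrow(h) > 1L && any(h$start[o][-1] <= h$end[o][-nrow(h)]))
      return("hotspot intervals must not overlap")
  }
  s <- object@ssrSeeds
  if (nrow(s) && (any(s$hotspot < 1) || any(s$hotspot > nrow(h))))
    return("ssrSeeds must reference existing hotspots")
  TRUE
})

#' Synthetic demography specification
#'
#' Describes the structured sample to simulate on top of a reference plastome:
#' populations (demes) with sample sizes and group labels, the size of the
#' shared haplotype pool, the expected mutational divergence between deme
#' founders and the ancestor, the expected within-deme divergence, and an
#' admixture proportion mixing haplotypes across demes.
#'
#' @slot populations data.frame with columns \code{name}, \code{n_samples},
#'   \code{group}.
#' @slot haplotypePoolSize total number of distinct haplotype lineages.
#' @slot divergenceSteps expected mutational steps from the ancestor to each
#'   deme founder.
#' @slot localSteps expected mutational steps from a deme founder to each of
#'   its satellite haplotypes.
#' @slot admixture probability in [0,1] that a sample draws its haplotype
#'   from another deme's pool.
#' @name DemographySpec-class
#' @exportClass DemographySpec
setClass("DemographySpec",
  slots = c(populations = "data.frame", haplotypePoolSize = "integer",
            divergenceSteps = "numeric", localSteps = "numeric",
            admixture = "numeric"))

setValidity("DemographySpec", function(object) {
  p <- object@populations
  if (!all(c("name", "n_samples", "group") %in% names(p)))
    return("populations needs columns name, n_samples, group")
  if (nrow(p) < 1L) return("at least one population required")
  if (any(p$n_samples < 1L)) return("n_samples must be >= 1 per population")
  if (anyDuplicated(p$name)) return("population names must be unique")
  if (object@admixture < 0 || object@admixture > 1)
    return("admixture must lie in [0,1]")
  if (object@haplotypePoolSize < nrow(p))
    return("haplotypePoolSize must be >= number of populations")
  if (object@divergenceSteps < 0 || object@localSteps < 0)
    return("divergence steps must be >= 0")
  TRUE
})
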