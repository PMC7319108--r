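#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

#' Construct a PlastomeAlignment
#'
#' @param seqs a named \code{DNAStringSet} or named character vector of
#'   equal-length, gapped sequences. Input is case-insensitive; sequences are
#'   stored uppercase.
#' @param population named character vector (sample id -> population) or a
#'   population-map data.frame with columns \code{sample_id},
#'   \code{population} and optionally \code{group}.
#' @param group named character vector (population -> group).
#' @return a \linkS4class{PlastomeAlignment}.
#' @examples
#' aln <- PlastomeAlignment(c(s1 = "ACGT-ACG", s2 = "ACGTTACG"),
#'                          population = c(s1 = "popA", s2 = "popB"))
#' sampleIDs(aln)
#' @export
PlastomeAlignment <- function(seqs, population = character(), group = character()) {
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  if (is.data.frame(population)) {
    pm <- population
    population <- setNames(as.character(pm$population), pm$sample_id)
    if ("group" %in% names(pm) && !length(group)) {
      g <- unique(pm[, c("population", "group")])
      group <- setNames(as.character(g$group), g$population)
    }
  }
  new("PlastomeAlignment", seqs = seqs,
      population = population, group = group)
}

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "PlastomeAlignment", function(x) names(x@seqs))

#' @rdname populationOf
#' @export
setMethod("populationOf", "PlastomeAlignment", function(x) {
  ids <- sampleIDs(x)
  out <- setNames(rep(NA_character_, length(ids)), ids)
  if (length(x@population)) out[names(x@population)] <- x@population
  out
})

#' @rdname groupOf
#' @export
setMethod("groupOf", "PlastomeAlignment", function(x) x@group)

#' Alignment width (columns)
#' @param x a \linkS4class{PlastomeAlignment}.
#' @return integer number of alignment columns.
#' @export
alignmentWidth <- function(x) Biostrings::width(x@seqs)[1]

#' Alignment as a character matrix
#'
#' @param x a \linkS4class{PlastomeAlignment}.
#' @param samples optional character vector restricting (and ordering) rows.
#' @return character matrix, one row per sample, one column per alignment
#'   column.
#' @export
alignmentMatrix <- function(x, samples = NULL) {
  s <- x@seqs
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(s))
    if (length(missing)) stopf("unknown samples: %s", paste(missing, collapse = ", "))
    s <- s[samples]
  }
  m <- do.call(rbind, strsplit(as.character(s), "", fixed = TRUE))
  rownames(m) <- names(s)
  m
}

setMethod("show", "PlastomeAlignment", function(object) {
  cat(sprintf("PlastomeAlignment: %d samples x %d columns\n",
              length(object@seqs), alignmentWidth(object)))
  pop <- populationOf(object)
  if (any(!is.na(pop)))
    cat(sprintf("  populations: %s\n",
                paste(sort(unique(pop[!is.na(pop)])), collapse = ", ")))
  if (length(object@group))
    cat(sprintf("  groups: %s\n", paste(sort(unique(object@group)), collapse = ", ")))
})

setMethod("[", "PlastomeAlignment", function(x, i, j, ..., drop = TRUE) {
  s <- x@seqs[i]
  pop <- x@population[names(x@population) %in% names(s)]
  PlastomeAlignment(s, population = pop, group = x@group)
})

#' Read a gapped FASTA alignment
#'
#' Reads an aligned FASTA file (gaps as \code{-}) into a
#' \linkS4class{PlastomeAlignment}. Sequences are uppercased; file order is
#' preserved; unequal sequence lengths, duplicated ids and empty files are
#' errors.
#'
#' @param path FASTA file path.
#' @param population optional population map (see
#'   \code{\link{PlastomeAlignment}}).
#' @return a \linkS4class{PlastomeAlignment}.
#' @export
readFastaAlignment <- function(path, population = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- tryCatch(readDNAStringSet(path),
                   error = function(e) stopf("not a readable FASTA file: %s", path))
  if (length(seqs) == 0L) stopf("empty FASTA file: %s", path)
  if (length(seqs) < 2L) stopf("an alignment needs at least 2 records: %s", path)
  # keep only the first whitespace token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate sequence ids in %s", path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stopf("sequences in %s have unequal lengths; input must be aligned", path)
  PlastomeAlignment(seqs, population = population)
}

#' Write an alignment to FASTA
#'
#' @param x a \linkS4class{PlastomeAlignment}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(x, path) {
  writeXStringSet(x@seqs, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a TSV with header columns \code{sample_id}, \code{population} and
#' optionally \code{group}; one row per sample.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{sample_id}, \code{population} and,
#'   when present, \code{group}.
#' @export
readPopulationMap <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pm <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "population")
  if (!all(required %in% names(pm)))
    stopf("population map must have columns: %s", paste(required, collapse = ", "))
  if (anyDuplicated(pm$sample_id))
    stopf("duplicate sample_id in population map: %s",
          paste(unique(pm$sample_id[duplicated(pm$sample_id)]), collapse = ", "))
  if (any(!nzchar(pm$population)) || any(is.na(pm$population)))
    stopf("population names must be non-empty")
  keep <- intersect(c("sample_id", "population", "group"), names(pm))
  pm[, keep, drop = FALSE]
}

#' Write a population map
#' @param pm data.frame with columns \code{sample_id}, \code{population}
#'   and optionally \code{group}.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePopulationMap <- function(pm, path) {
  write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
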