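#' Collapse aligned sequences into haplotypes
#'
#' Implements the marker-region haplotyping rules used for chloroplast
#' phylogeography: terminal (5'/3') gaps are treated as missing data, columns
#' inside mononucleotide runs of at least \code{monoRunMin} bp in any sample
#' are excluded (mononucleotide cpSSR stutter is not counted as variation),
#' each maximal internal gap run is recoded as a single binary
#' presence/absence character (an indel is one mutation event regardless of
#' its length, and identical-extent runs shared by samples are one event),
#' and a haplotype is a distinct joint state over the substitution columns
#' plus the indel characters.
#'
#' @param aln a trimmed \linkS4class{PlastomeAlignment} with population
#'   labels (unlabelled samples are placed in population
#'   \code{"unassigned"}).
#' @param excludeMononucleotideRepeats mask mononucleotide runs (default
#'   TRUE).
#' @param monoRunMin run-length cutoff in bp (default 8, matching the
#'   mononucleotide cpSSR detection threshold).
#' @return a \linkS4class{HaplotypeTable}. Inter-haplotype mutational step
#'   distances are available via \code{\link{stepDistances}}.
#' @examples
#' aln <- PlastomeAlignment(c(a = "AAT", b = "AAT", c = "ACT"),
#'                          population = c(a = "p1", b = "p1", c = "p2"))
#' ht <- collapseHaplotypes(aln)
#' haplotypeCounts(ht)
#' stepDistances(ht)
#' @export
collapseHaplotypes <- function(aln, excludeMononucleotideRepeats = TRUE,
                               monoRunMin = 8L) {
  stopifnot(is(aln, "PlastomeAlignment"))
  m <- alignmentMatrix(aln)
  n <- nrow(m); L <- ncol(m)

  # terminal gaps -> missing (sample does not vote at those columns)
  for (i in seq_len(n)) {
    nonGap <- which(m[i, ] != "-")
    if (!length(nonGap)) { m[i, ] <- NA_character_; next }
    if (nonGap[1] > 1L) m[i, seq_len(nonGap[1] - 1L)] <- NA_character_
    if (nonGap[length(nonGap)] < L)
      m[i, (nonGap[length(nonGap)] + 1L):L] <- NA_character_
  }

  # mask mononucleotide runs >= monoRunMin in any sample
  masked <- logical(L)
  if (excludeMononucleotideRepeats) {
    for (i in seq_len(n)) {
      r <- rle(m[i, ])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      long <- which(r$lengths >= monoRunMin & r$values %in% DNA_BASES4)
      for (j in long) masked[starts[j]:ends[j]] <- TRUE
    }
  }
  keep <- which(!masked)
  mm <- m[, keep, drop = FALSE]

  # indel characters: unique maximal internal gap-run extents
  gap <- !is.na(mm) & mm == "-"
  events <- gapEvents(ifelse(gap, "-", "N"))
  indelStates <- NULL
  if (nrow(events)) {
    indelStates <- matrix(NA_character_, n, nrow(events))
    for (e in seq_len(nrow(events))) {
      span <- events$start[e]:events$end[e]
      for (i in seq_len(n)) {
        if (anyNA(mm[i, span])) { indelStates[i, e] <- NA_character_; next }
        runHere <- all(gap[i, span]) &&
          (events$start[e] == 1L || !gap[i, events$start[e] - 1L]) &&
          (events$end[e] == ncol(mm) || !gap[i, events$end[e] + 1L])
        indelStates[i, e] <- if (runHere) "1" else "0"
      }
    }
  }

  # substitution characters: columns with >= 2 distinct bases
  isBase <- !is.na(mm) & mm != "-"
  subCols <- integer()
  for (j in seq_len(ncol(mm))) {
    b <- unique(mm[isBase[, j], j])
    if (length(b) >= 2L) subCols <- c(subCols, j)
  }
  subStates <- mm[, subCols, drop = FALSE]
  subStates[subStates == "-"] <- NA_character_   # gapped sample: missing base

  states <- cbind(subStates, indelStates)
  charType <- c(rep("substitution", length(subCols)),
                rep("indel", if (is.null(indelStates)) 0L else ncol(indelStates)))
  charColumn <- as.integer(c(keep[subCols],
                             if (nrow(events)) keep[events$start] else integer()))
  if (!ncol(states)) {
    warnf("no polymorphic characters after filtering; all samples form one haplotype")
    states <- matrix(character(), n, 0)
  }

  # canonical sample order: sorted ids; haplotype ids by decreasing count
  ids <- rownames(m)
  ord <- order(ids)
  key <- if (ncol(states)) apply(states[ord, , drop = FALSE], 1, function(s)
    paste(ifelse(is.na(s), "?", s), collapse = "\r")) else rep("", n)
  firstSeen <- unique(key)
  grp <- match(key, firstSeen)
  cnt <- tabulate(grp, nbins = length(firstSeen))
  hapOrder <- order(-cnt, seq_along(firstSeen))
  hapIdOf <- integer(length(firstSeen))
  hapIdOf[hapOrder] <- seq_along(firstSeen)
  hapIds <- paste0("H", hapIdOf[grp])            # per sorted sample
  sampleHap <- setNames(hapIds, ids[ord])[ids]   # back to input order

  nHap <- length(firstSeen)
  signatures <- matrix(NA_character_, nHap, ncol(states),
                       dimnames = list(paste0("H", seq_len(nHap)), NULL))
  for (g in seq_along(firstSeen)) {
    rowIdx <- ord[which(grp == g)[1]]
    signatures[hapIdOf[g], ] <- states[rowIdx, ]
  }

  pop <- populationOf(aln)
  pop[is.na(pop)] <- "unassigned"
  popLevels <- unique(pop[names(sampleHap)][order(names(sampleHap))])
  counts <- table(factor(sampleHap, levels = paste0("H", seq_len(nHap))),
                  factor(pop[names(sampleHap)], levels = popLevels))
  counts <- matrix(as.integer(counts), nrow = nHap,
                   dimnames = list(paste0("H", seq_len(nHap)), popLevels))

  # Pi denominator: retained columns that are gap-free and fully resolved
  lEff <- sum(colSums(isBase) == n)

  new("HaplotypeTable", signatures = signatures, charType = charType,
      charColumn = charColumn, counts = counts,
      sampleHaplotype = sampleHap, nTotal = as.integer(n),
      lEffective = as.integer(lEff))
}

#' @rdname stepDistances
#' @export
setMethod("stepDistances", "HaplotypeTable", function(x, type = c("all", "substitution")) {
  type <- match.arg(type)
  s <- x@signatures
  if (type == "substitution")
    s <- s[, x@charType == "substitution", drop = FALSE]
  hammingDistances(s)
})

# pairwise count of characters where both states are defined and differ
hammingDistances <- function(s) {
  n <- nrow(s)
  d <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
  if (n < 2L || !ncol(s)) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(s[i, ]) & !is.na(s[j, ])
    d[i, j] <- d[j, i] <- sum(s[i, ok] != s[j, ok])
  }
  d
}

#' @rdname haplotypeOf
#' @export
setMethod("haplotypeOf", "HaplotypeTable", function(x) x@sampleHaplotype)

#' @rdname haplotypeCounts
#' @export
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes, %d samples, %d populations\n",
              nrow(object@counts), object@nTotal, ncol(object@counts)))
  cat(sprintf("  characters: %d substitution, %d indel; effective length %d bp\n",
              sum(object@charType == "substitution"),
              sum(object@charType == "indel"), object@lEffective))
})

#' Nei's unbiased haplotype (gene) diversity
#'
#' \eqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with
#' \eqn{p_i = c_i / n} the haplotype frequencies.
#'
#' @param counts numeric vector of per-haplotype sample counts.
#' @return haplotype diversity in [0,1]; \code{NA} with a warning when the
#'   total sample size is below 2.
#' @examples
#' haplotypeDiversity(c(3, 1, 1, 2))   # 0.8095
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) {
    warnf("haplotype diversity undefined for n < 2")
    return(NA_real_)
  }
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity from a haplotype table
#'
#' \eqn{\pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j d_{ij} / L} where
#' \eqn{d_{ij}} counts substitution differences only (indel characters are
#' excluded from both the distances and the length denominator).
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param counts optional count vector overriding the table's global counts
#'   (e.g. a single population's column).
#' @return nucleotide diversity per site; \code{NA} with a warning when the
#'   effective length is 0 or fewer than 2 samples are counted.
#' @export
nucleotideDiversity <- function(table, counts = NULL) {
  stopifnot(is(table, "HaplotypeTable"))
  if (is.null(counts)) counts <- rowSums(table@counts)
  n <- sum(counts)
  if (table@lEffective < 1L) {
    warnf("effective length is 0; nucleotide diversity undefined")
    return(NA_real_)
  }
  if (n < 2) {
    warnf("nucleotide diversity undefined for n < 2")
    return(NA_real_)
  }
  d <- stepDistances(table, type = "substitution")
  p <- counts / n
  acc <- 0
  nh <- length(p)
  if (nh >= 2L)
    for (i in seq_len(nh - 1L)) for (j in (i + 1L):nh)
      acc <- acc + 2 * p[i] * p[j] * d[i, j]
  unname((n / (n - 1)) * acc / table@lEffective)
}

#' Per-haplotype frequency report
#'
#' Global and per-population haplotype frequencies as percentages (2
#' decimals).
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @return data.frame with columns \code{haplotype}, \code{count},
#'   \code{global_pct}, then one count column per population.
#' @export
haplotypeFrequencyReport <- function(table) {
  stopifnot(is(table, "HaplotypeTable"))
  cnt <- table@counts
  tot <- rowSums(cnt)
  out <- data.frame(haplotype = rownames(cnt), count = as.integer(tot),
                    global_pct = round(100 * tot / table@nTotal, 2),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cnt))
}

#' Per-population diversity summary
#'
#' Haplotype diversity and nucleotide diversity per population plus a total
#' row over all samples.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @return data.frame with columns \code{population}, \code{n},
#'   \code{n_haplotypes}, \code{Hd}, \code{Pi}.
#' @export
diversityByPopulation <- function(table) {
  stopifnot(is(table, "HaplotypeTable"))
  cnt <- table@counts
  rows <- lapply(colnames(cnt), function(p) {
    ck <- cnt[, p]
    data.frame(population = p, n = sum(ck),
               n_haplotypes = sum(ck > 0),
               Hd = suppressWarnings(haplotypeDiversity(ck)),
               Pi = suppressWarnings(nucleotideDiversity(table, counts = ck)),
               stringsAsFactors = FALSE)
  })
  tot <- rowSums(cnt)
  rows[[length(rows) + 1L]] <- data.frame(
    population = "total", n = sum(tot), n_haplotypes = sum(tot > 0),
    Hd = suppressWarnings(haplotypeDiversity(tot)),
    Pi = suppressWarnings(nucleotideDiversity(table)),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
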