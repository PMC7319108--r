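#' Remove ambiguous alignment columns
#'
#' Drops every alignment column that contains a character outside
#' \{A, C, G, T, -\} in any sequence (IUPAC ambiguity codes, N, etc.), and
#' reports the mapping from retained columns back to original coordinates.
#'
#' @param aln a \linkS4class{PlastomeAlignment}.
#' @return a list with \code{alignment} (trimmed
#'   \linkS4class{PlastomeAlignment}) and \code{report} (data.frame with
#'   columns \code{trimmed_col}, \code{original_col}).
#' @export
trimAlignment <- function(aln) {
  stopifnot(is(aln, "PlastomeAlignment"))
  m <- alignmentMatrix(aln)
  ok <- colSums(matrix(m %in% c(DNA_BASES4, "-"), nrow = nrow(m))) == nrow(m)
  if (!any(ok)) stopf("all alignment columns are ambiguous; nothing left to analyze")
  keep <- which(ok)
  seqs <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- PlastomeAlignment(setNames(seqs, rownames(m)),
                           population = aln@population, group = aln@group)
  list(alignment = out,
       report = data.frame(trimmed_col = seq_along(keep), original_col = keep))
}

#' Profile alignment bins for GC, SNPs, indel events and cpSSRs
#'
#' Tiles the alignment columns into consecutive bins of \code{binLength}
#' (the final bin may be short) and records, per bin: GC fraction over
#' ingroup non-gap bases, the number of segregating sites (columns where two
#' or more distinct non-gap bases occur among the ingroup), the number of
#' indel events (maximal gap runs per sample, with identical-extent runs
#' shared by several samples counted once, each event assigned to the bin of
#' its leftmost column), and the number of cpSSR loci whose leftmost
#' alignment column falls in the bin.
#'
#' @param aln a trimmed \linkS4class{PlastomeAlignment}.
#' @param binLength bin width in alignment columns (default 400).
#' @param ingroup sample ids counted; defaults to all samples. An outgroup
#'   used only as alignment anchor should be excluded here.
#' @param ssrs optional cpSSR loci: a data.frame with column
#'   \code{aln_start} (e.g. the \code{clusters} element of
#'   \code{\link{screenPolymorphicSsrs}}).
#' @return data.frame with columns \code{bin_index}, \code{start}, \code{end},
#'   \code{gc}, \code{snp_count}, \code{indel_count}, \code{ssr_count}.
#' @export
profileBins <- function(aln, binLength = 400L, ingroup = sampleIDs(aln),
                        ssrs = NULL) {
  stopifnot(is(aln, "PlastomeAlignment"), binLength >= 1L)
  if (!length(ingroup)) stopf("ingroup must contain at least one sample")
  m <- alignmentMatrix(aln, samples = ingroup)
  L <- ncol(m)
  starts <- seq.int(1L, L, by = binLength)
  ends <- pmin(starts + binLength - 1L, L)
  binOfCol <- rep(seq_along(starts), times = ends - starts + 1L)

  present <- vapply(DNA_BASES4, function(b) colSums(m == b) > 0,
                    logical(L))                      # L x 4
  nDistinct <- rowSums(present)
  snpCol <- nDistinct >= 2L

  gcCount <- colSums(m == "G") + colSums(m == "C")
  baseCount <- colSums(matrix(m %in% DNA_BASES4, nrow = nrow(m)))

  events <- gapEvents(m)
  indelBin <- if (nrow(events)) tabulate(binOfCol[events$start],
                                         nbins = length(starts)) else
    integer(length(starts))

  ssrBin <- integer(length(starts))
  if (!is.null(ssrs) && nrow(ssrs)) {
    s <- ssrs$aln_start
    s <- s[s >= 1 & s <= L]
    ssrBin <- tabulate(binOfCol[s], nbins = length(starts))
  }

  gcBin <- as.numeric(rowsum(gcCount, binOfCol)) /
    ifelse(as.numeric(rowsum(baseCount, binOfCol)) > 0,
           as.numeric(rowsum(baseCount, binOfCol)), NA)
  data.frame(bin_index = seq_along(starts), start = starts, end = ends,
             gc = gcBin,
             snp_count = as.integer(rowsum(as.integer(snpCol), binOfCol)),
             indel_count = indelBin, ssr_count = ssrBin)
}

# Distinct maximal gap runs across samples of a character matrix: one row per
# unique (start, end) extent (identical-extent runs in several samples are one
# mutational event).
gapEvents <- function(m) {
  runs <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs[[i]] <- cbind(starts[r$values], ends[r$values])
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  all <- unique(do.call(rbind, runs))
  data.frame(start = all[, 1], end = all[, 2])[order(all[, 1], all[, 2]), ,
                                               drop = FALSE]
}

#' Detect perfect cpSSR loci in an ungapped sequence
#'
#' Reports every maximal perfect tandem repeat with motif length 1 to
#' \code{maxMotif} whose unit count meets its class threshold: 8 units for
#' mononucleotide and 5 units for multinucleotide motifs. Loci are reported
#' once at their smallest period (periodic motifs such as "AA" or "ATAT" are
#' never reported), and overlapping candidates are resolved leftmost-longest.
#'
#' @param seq ungapped sequence (character scalar over A/C/G/T,
#'   case-insensitive).
#' @param minMono minimum units for mononucleotide SSRs (default 8).
#' @param minMulti minimum units for multinucleotide SSRs (default 5).
#' @param maxMotif maximum motif length in bp (default 6).
#' @return data.frame with columns \code{start}, \code{end} (1-based closed,
#'   on the ungapped sequence), \code{motif}, \code{units}, \code{length}.
#' @examples
#' detectSsrs("GGAAAAAAAACC")          # (A)8
#' detectSsrs("GATATATATATC")          # (AT)5
#' @export
detectSsrs <- function(seq, minMono = 8L, minMulti = 5L, maxMotif = 6L) {
  s <- strsplit(toupper(seq), "")[[1]]
  if (any(!(s %in% DNA_BASES4)))
    stopf("sequence contains characters outside A/C/G/T")
  L <- length(s)
  cand <- list()
  for (p in seq_len(min(maxMotif, max(0L, L - 1L)))) {
    if (L <= p) break
    eq <- s[seq_len(L - p)] == s[(p + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    thr <- if (p == 1L) minMono else minMulti
    for (j in which(r$values)) {
      totalLen <- r$lengths[j] + p           # maximal repeat tract length
      units <- totalLen %/% p
      if (units < thr) next
      st <- starts[j]
      motif <- paste(s[st:(st + p - 1L)], collapse = "")
      if (!isPrimitiveMotif(motif)) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = st, end = st + units * p - 1L, motif = motif,
                   units = units, length = units * p, period = p,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      units = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -cand$length, cand$period), , drop = FALSE]
  keepEnd <- -1L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > keepEnd) {
      keep[i] <- TRUE
      keepEnd <- cand$end[i]
    }
  }
  out <- cand[keep, c("start", "end", "motif", "units", "length")]
  rownames(out) <- NULL
  out
}

# TRUE when the motif is not itself a repetition of a shorter unit.
isPrimitiveMotif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (strrep(substr(motif, 1L, d), p %/% d) == motif) return(FALSE)
  }
  TRUE
}

# Lexicographically smallest rotation: canonical motif label for clustering
# homologous SSRs whose detected phase differs between samples.
canonicalMotif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(motif)
  rots <- vapply(seq_len(p), function(i)
    paste0(substr(motif, i, p), substr(motif, 1L, i - 1L)), "")
  min(rots)
}

#' Tie-corrected Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the large-sample t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements \code{rho} and \code{p}; both \code{NA} (with a
#'   warning) when either vector is constant, which is distinct from a zero
#'   correlation.
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3L) stopf("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warnf("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Rank mutational hotspot regions from bin profiles
#'
#' Scores each bin by \code{snp_count + indel_count}, selects bins from the
#' top (ties broken by higher \code{snp_count}, then lower start coordinate)
#' and, when \code{mergeAdjacent}, fuses touching selected bins into single
#' regions (totals summed), continuing selection until \code{k} regions exist
#' or variable bins are exhausted.
#'
#' @param profiles bin profile data.frame from \code{\link{profileBins}}.
#' @param k number of regions to screen (default 27).
#' @param mergeAdjacent fuse adjacent selected bins into one region.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{snp_total}, \code{indel_total}, \code{rank} (1 = most variable).
#' @export
rankHotspots <- function(profiles, k = 27L, mergeAdjacent = TRUE) {
  stopifnot(nrow(profiles) > 0L, k >= 1L)
  score <- profiles$snp_count + profiles$indel_count
  cand <- which(score > 0)
  if (!length(cand)) {
    warnf("no variable bins; returning zero regions")
    return(data.frame(start = integer(), end = integer(),
                      snp_total = integer(), indel_total = integer(),
                      rank = integer()))
  }
  ord <- cand[order(-score[cand], -profiles$snp_count[cand],
                    profiles$start[cand])]
  selected <- integer()
  regionsOf <- function(sel) {
    sel <- sort(sel)
    if (!length(sel)) return(list())
    brk <- cumsum(c(1L, diff(sel) != 1L))
    split(sel, brk)
  }
  regs <- list()
  for (b in ord) {
    selected <- c(selected, b)
    regs <- if (mergeAdjacent) regionsOf(selected) else as.list(sort(selected))
    if (length(regs) >= k) break
  }
  if (length(regs) < k)
    warnf("only %d variable region(s) available (requested %d)", length(regs), k)
  out <- do.call(rbind, lapply(regs, function(bins)
    data.frame(start = profiles$start[min(bins)], end = profiles$end[max(bins)],
               snp_total = sum(profiles$snp_count[bins]),
               indel_total = sum(profiles$indel_count[bins]))))
  tot <- out$snp_total + out$indel_total
  out <- out[order(-tot, -out$snp_total, out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Map ungapped per-sample positions to alignment columns for one sample row.
ungappedToAlignment <- function(rowChars) which(rowChars != "-")

#' Screen polymorphic cpSSR loci across an alignment
#'
#' Detects SSRs on each ingroup sample's ungapped sequence, maps them to
#' alignment coordinates, clusters loci sharing a canonical motif and an
#' overlapping alignment span, recounts the tandem unit number of every
#' ingroup sample over each cluster's span, and flags a cluster polymorphic
#' when unit counts differ among samples.
#'
#' @param aln a trimmed \linkS4class{PlastomeAlignment}.
#' @param ingroup sample ids to screen (default all).
#' @param minMono,minMulti,maxMotif detection thresholds, see
#'   \code{\link{detectSsrs}}.
#' @return list of class \code{ssrScreen} with \code{clusters} (data.frame:
#'   \code{cluster}, \code{motif}, \code{aln_start}, \code{aln_end},
#'   \code{polymorphic}) and \code{alleles} (matrix cluster x sample of unit
#'   counts).
#' @export
screenPolymorphicSsrs <- function(aln, ingroup = sampleIDs(aln),
                                  minMono = 8L, minMulti = 5L, maxMotif = 6L) {
  m <- alignmentMatrix(aln, samples = ingroup)
  loci <- list()
  for (i in seq_len(nrow(m))) {
    cols <- ungappedToAlignment(m[i, ])
    if (length(cols) < 2L) next
    ss <- detectSsrs(paste(m[i, cols], collapse = ""),
                     minMono = minMono, minMulti = minMulti,
                     maxMotif = maxMotif)
    if (!nrow(ss)) next
    ss$aln_start <- cols[ss$start]
    ss$aln_end <- cols[ss$end]
    ss$sample <- rownames(m)[i]
    ss$canonical <- vapply(ss$motif, canonicalMotif, "")
    loci[[length(loci) + 1L]] <- ss
  }
  emptyOut <- structure(list(
    clusters = data.frame(cluster = integer(), motif = character(),
                          aln_start = integer(), aln_end = integer(),
                          polymorphic = logical()),
    alleles = matrix(integer(), 0, nrow(m),
                     dimnames = list(NULL, rownames(m)))),
    class = "ssrScreen")
  if (!length(loci)) return(emptyOut)
  loci <- do.call(rbind, loci)

  # single-linkage clustering: same canonical motif + overlapping span
  loci <- loci[order(loci$canonical, loci$aln_start), ]
  cl <- integer(nrow(loci)); cur <- 0L; curEnd <- -1L; curMotif <- ""
  for (i in seq_len(nrow(loci))) {
    if (loci$canonical[i] != curMotif || loci$aln_start[i] > curEnd) {
      cur <- cur + 1L
      curMotif <- loci$canonical[i]
      curEnd <- loci$aln_end[i]
    } else curEnd <- max(curEnd, loci$aln_end[i])
    cl[i] <- cur
  }
  loci$cluster <- cl

  clusters <- do.call(rbind, lapply(split(loci, loci$cluster), function(g)
    data.frame(cluster = g$cluster[1], motif = g$canonical[1],
               aln_start = min(g$aln_start), aln_end = max(g$aln_end),
               stringsAsFactors = FALSE)))
  alleles <- matrix(NA_integer_, nrow(clusters), nrow(m),
                    dimnames = list(NULL, rownames(m)))
  for (r in seq_len(nrow(clusters))) {
    span <- clusters$aln_start[r]:clusters$aln_end[r]
    for (i in seq_len(nrow(m))) {
      sub <- m[i, span]
      sub <- sub[sub != "-"]
      alleles[r, i] <- countTandemUnits(paste(sub, collapse = ""),
                                        clusters$motif[r])
    }
  }
  clusters$polymorphic <- apply(alleles, 1, function(a)
    length(unique(a[!is.na(a)])) > 1L)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, alleles = alleles), class = "ssrScreen")
}

# Longest tandem run of `motif` (any rotation) inside `seq`, in units.
countTandemUnits <- function(seq, motif) {
  p <- nchar(motif)
  if (nchar(seq) < p) return(0L)
  best <- 0L
  rots <- unique(vapply(seq_len(p), function(i)
    paste0(substr(motif, i, p), substr(motif, 1L, i - 1L)), ""))
  for (rot in rots) {
    hits <- gregexpr(sprintf("(?:%s)+", rot), seq)[[1]]
    if (hits[1] == -1L) next
    best <- max(best, max(attr(hits, "match.length")) %/% p)
  }
  as.integer(best)
}

#' @export
print.ssrScreen <- function(x, ...) {
  np <- sum(x$clusters$polymorphic)
  cat(sprintf("ssrScreen: %d cpSSR cluster(s), %d polymorphic\n",
              nrow(x$clusters), np))
  invisible(x)
}

#' Pairwise Spearman correlations among bin-profile tracks
#'
#' Convenience wrapper computing \code{\link{spearmanRho}} for every pair of
#' the GC, SNP, indel and SSR tracks of a bin profile.
#'
#' @param profiles data.frame from \code{\link{profileBins}}.
#' @return data.frame with columns \code{pair}, \code{rho}, \code{p}.
#' @export
binCorrelations <- function(profiles) {
  tracks <- list(gc = profiles$gc, snp = profiles$snp_count,
                 indel = profiles$indel_count, ssr = profiles$ssr_count)
  nm <- names(tracks)
  out <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    ok <- is.finite(tracks[[i]]) & is.finite(tracks[[j]])
    r <- suppressWarnings(spearmanRho(tracks[[i]][ok], tracks[[j]][ok]))
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(nm[i], nm[j], sep = "-"), rho = r$rho, p = r$p)
  }
  do.call(rbind, out)
}
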