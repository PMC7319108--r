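#' Build a synthetic plastome specification
#'
#' Defaults describe a Dendrobium-like plastome: LSC 84,719 bp, SSC 12,099 bp
#' and IRs of 25,984 bp (total 148,786 bp), background GC 0.375, and 27
#' AT-biased mutational hotspot intervals of ~400 bp spread over the
#' single-copy regions, six of which carry cpSSR seed loci. Hotspot SNP and
#' indel rates are per-site probabilities used by
#' \code{\link{simulatePopulationAlignment}} to weight mutation placement;
#' outside hotspots the background rate is one tenth of the smallest hotspot
#' rate, and the inverted repeats are kept mutation-free.
#'
#' @param lscLength,sscLength,irLength region lengths (bp).
#' @param gcBackground background GC fraction.
#' @param nHotspots number of hotspot intervals to lay out (ignored when
#'   `hotspots` is supplied).
#' @param hotspotLength hotspot interval width (bp).
#' @param snpRate,indelRate per-site rates inside hotspots.
#' @param gcLocal hotspot GC fraction (AT-biased default).
#' @param hotspots optional explicit hotspot data.frame (columns
#'   \code{start}, \code{end}, \code{gc_local}, \code{snp_rate},
#'   \code{indel_rate}).
#' @param ssrSeeds optional explicit SSR seed data.frame (columns
#'   \code{hotspot}, \code{motif}, \code{units}); the default plants six
#'   polymorphic-candidate seeds in the first six hotspots.
#' @return a \linkS4class{PlastomeSpec}.
#' @export
plastomeSpec <- function(lscLength = 84719L, sscLength = 12099L, irLength = 25984L,
                         gcBackground = 0.375, nHotspots = 27L,
                         hotspotLength = 400L, snpRate = 0.02,
                         indelRate = 0.008, gcLocal = 0.25,
                         hotspots = NULL, ssrSeeds = NULL) {
  lscLength <- as.integer(lscLength); sscLength <- as.integer(sscLength)
  irLength <- as.integer(irLength)
  if (is.null(hotspots)) {
    hotspots <- layoutHotspots(lscLength, sscLength, irLength, nHotspots,
                               hotspotLength, gcLocal, snpRate, indelRate)
  }
  if (is.null(ssrSeeds)) {
    nSeeds <- min(6L, nrow(hotspots))
    motifs <- c("A", "T", "AT", "TA", "AAT", "AT")[seq_len(nSeeds)]
    units <- c(10L, 9L, 6L, 6L, 5L, 7L)[seq_len(nSeeds)]
    keep <- units * nchar(motifs) + 4L <= (hotspots$end - hotspots$start + 1L)[seq_len(nSeeds)]
    ssrSeeds <- data.frame(hotspot = seq_len(nSeeds), motif = motifs,
                           units = units, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  new("PlastomeSpec", lscLength = lscLength, sscLength = sscLength,
      irLength = irLength, gcBackground = gcBackground,
      hotspots = hotspots, ssrSeeds = ssrSeeds)
}

# Evenly space hotspot intervals over LSC and SSC, proportionally to length.
layoutHotspots <- function(lsc, ssc, ir, n, len, gcLocal, snpRate, indelRate) {
  regions <- data.frame(start = c(1L, lsc + ir + 1L),
                        end = c(lsc, lsc + ir + ssc))
  regions <- regions[regions$end - regions$start + 1L >= len + 20L, , drop = FALSE]
  if (!nrow(regions) || n < 1L)
    return(data.frame(start = integer(), end = integer(), gc_local = numeric(),
                      snp_rate = numeric(), indel_rate = numeric()))
  sizes <- regions$end - regions$start + 1L
  alloc <- pmax(0L, round(n * sizes / sum(sizes)))
  alloc[1] <- alloc[1] + (n - sum(alloc))
  out <- list()
  for (r in seq_len(nrow(regions))) {
    k <- alloc[r]
    if (k < 1L) next
    # cap so intervals plus margins always fit
    k <- min(k, (sizes[r] - 20L) %/% (len + 20L))
    if (k < 1L) next
    anchors <- round(seq(regions$start[r] + 10L, regions$end[r] - len - 10L,
                         length.out = k))
    out[[r]] <- data.frame(start = as.integer(anchors),
                           end = as.integer(anchors + len - 1L),
                           gc_local = gcLocal, snp_rate = snpRate,
                           indel_rate = indelRate)
  }
  do.call(rbind, out)
}

#' Build a synthetic demography specification
#'
#' Defaults mirror a five-population sampling design of 9, 7, 2, 6 and 4
#' individuals (28 in all) in three groups, an 11-lineage haplotype pool,
#' founder divergence of 3 expected mutational steps, one expected within-deme
#' step, and a mild admixture proportion of 0.1.
#'
#' @param populations data.frame with columns \code{name}, \code{n_samples},
#'   \code{group}.
#' @param haplotypePoolSize total distinct haplotype lineages across demes.
#' @param divergenceSteps expected ancestor-to-founder mutational steps.
#' @param localSteps expected founder-to-satellite steps.
#' @param admixture probability a sample carries another deme's haplotype.
#' @return a \linkS4class{DemographySpec}.
#' @export
demographySpec <- function(populations = NULL, haplotypePoolSize = 11L,
                           divergenceSteps = 3, localSteps = 1,
                           admixture = 0.1) {
  if (is.null(populations))
    populations <- data.frame(
      name = paste0("pop", 1:5),
      n_samples = c(9L, 7L, 2L, 6L, 4L),
      group = c("g1", "g1", "g1", "g2", "g3"),
      stringsAsFactors = FALSE)
  new("DemographySpec", populations = populations,
      haplotypePoolSize = as.integer(haplotypePoolSize),
      divergenceSteps = divergenceSteps, localSteps = localSteps,
      admixture = admixture)
}

#' Simulate a quadripartite reference plastome
#'
#' Generates a random sequence with layout LSC | IRA | SSC | IRB where IRB is
#' the reverse complement of IRA, background base composition at
#' \code{gcBackground}, hotspot intervals at their local (AT-biased) GC, and
#' declared cpSSR seed motifs planted verbatim inside their hotspot
#' intervals.
#'
#' @param spec a \linkS4class{PlastomeSpec}.
#' @param seed integer seed; a fixed seed reproduces the sequence exactly.
#' @return a list of class \code{PlastomeReference} with elements
#'   \code{sequence} (character string), \code{regions} (LSC/IRA/SSC/IRB
#'   intervals), \code{hotspots} (absolute intervals with rates) and
#'   \code{ssrSeeds} (absolute coordinates, motif, units).
#' @export
simulateReferencePlastome <- function(spec, seed = NULL) {
  stopifnot(is(spec, "PlastomeSpec"))
  validObject(spec)
  lsc <- spec@lscLength; ssc <- spec@sscLength; ir <- spec@irLength
  total <- lsc + ssc + 2L * ir
  L0 <- lsc + ir + ssc                  # generated directly; IRB is mirrored
  h <- spec@hotspots
  if (nrow(h) && ir > 0L && any(h$end > L0))
    stopf("hotspot intervals may not overlap the second inverted repeat")
  withSeed(seed, {
    gcSite <- rep(spec@gcBackground, L0)
    if (nrow(h))
      for (i in seq_len(nrow(h))) gcSite[h$start[i]:h$end[i]] <- h$gc_local[i]
    pickGC <- runif(L0) < gcSite
    r <- runif(L0)
    chars <- ifelse(pickGC, ifelse(r < 0.5, "G", "C"),
                    ifelse(r < 0.5, "A", "T"))
    # plant SSR seeds, packing successive seeds of one hotspot left to right
    seeds <- spec@ssrSeeds
    seedCoords <- data.frame(start = integer(), end = integer(),
                             motif = character(), units = integer(),
                             stringsAsFactors = FALSE)
    if (nrow(seeds)) {
      nextFree <- setNames(h$start + 2L, as.character(seq_len(nrow(h))))
      for (i in seq_len(nrow(seeds))) {
        hs <- seeds$hotspot[i]
        m <- toupper(seeds$motif[i]); u <- seeds$units[i]
        len <- nchar(m) * u
        s0 <- nextFree[[as.character(hs)]]
        if (s0 + len - 1L > h$end[hs])
          stopf("SSR seed %d does not fit in hotspot %d", i, hs)
        chars[s0:(s0 + len - 1L)] <- strsplit(strrep(m, u), "")[[1]]
        # break the repeat on both flanks so planted unit counts are exact
        flank <- setdiff(DNA_BASES4, substr(m, nchar(m), nchar(m)))[1]
        if (s0 > 1L) chars[s0 - 1L] <- setdiff(DNA_BASES4, substr(m, 1L, 1L))[1]
        if (s0 + len <= L0) chars[s0 + len] <- flank
        nextFree[[as.character(hs)]] <- s0 + len + 2L
        seedCoords <- rbind(seedCoords,
          data.frame(start = s0, end = s0 + len - 1L, motif = m, units = u,
                     stringsAsFactors = FALSE))
      }
    }
    if (ir > 0L) {
      ira <- chars[(lsc + 1L):(lsc + ir)]
      chars <- c(chars, reverseComplementChars(ira))
    }
    regions <- data.frame(
      region = c("LSC", if (ir > 0L) "IRA", if (ssc > 0L) "SSC", if (ir > 0L) "IRB"),
      start = c(1L, if (ir > 0L) lsc + 1L, if (ssc > 0L) lsc + ir + 1L,
                if (ir > 0L) lsc + ir + ssc + 1L),
      end = c(lsc, if (ir > 0L) lsc + ir, if (ssc > 0L) lsc + ir + ssc,
              if (ir > 0L) total),
      stringsAsFactors = FALSE)
    structure(list(sequence = paste(chars, collapse = ""), regions = regions,
                   hotspots = h, ssrSeeds = seedCoords, spec = spec),
              class = "PlastomeReference")
  })
}

#' @export
print.PlastomeReference <- function(x, ...) {
  cat(sprintf("PlastomeReference: %d bp (%s)\n", nchar(x$sequence),
              paste(sprintf("%s %d bp", x$regions$region,
                            x$regions$end - x$regions$start + 1L), collapse = ", ")))
  cat(sprintf("  %d hotspot intervals, %d SSR seed loci\n",
              nrow(x$hotspots), nrow(x$ssrSeeds)))
  invisible(x)
}

# Per-site mutation weight vectors. Background is a tenth of the smallest
# positive hotspot rate; inverted repeats and SSR seed spans carry no
# point mutations.
mutationWeights <- function(reference) {
  L0 <- nchar(reference$sequence)
  h <- reference$hotspots
  mk <- function(col) {
    pos <- h[[col]][h[[col]] > 0]
    bg <- if (length(pos)) 0.1 * min(pos) else 0
    w <- rep(bg, L0)
    if (nrow(h))
      for (i in seq_len(nrow(h))) w[h$start[i]:h$end[i]] <- h[[col]][i]
    w
  }
  snpW <- mk("snp_rate"); indelW <- mk("indel_rate")
  reg <- reference$regions
  for (irName in c("IRA", "IRB")) {
    ir <- reg[reg$region == irName, ]
    if (nrow(ir)) {
      snpW[ir$start:ir$end] <- 0
      indelW[ir$start:ir$end] <- 0
    }
  }
  s <- reference$ssrSeeds
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    span <- max(1L, s$start[i] - 1L):min(L0, s$end[i] + 1L)
    snpW[span] <- 0; indelW[span] <- 0
  }
  list(snp = snpW, indel = indelW)
}

# Add Poisson(lambda) mutation events on top of an inherited event set.
mutateBranch <- function(events, lambda, w, refChars, seedSpans) {
  tot <- sum(w$snp) + sum(w$indel)
  m <- if (tot <= 0 || lambda <= 0) 0L else rpois(1L, lambda)
  if (m == 0L) return(events)
  L0 <- length(refChars)
  occupied <- function(s, e) {
    if (nrow(events$dels) && any(events$dels$start <= e & events$dels$end >= s))
      return(TRUE)
    any(events$snpPos >= s & events$snpPos <= e)
  }
  pSnp <- sum(w$snp) / tot
  for (k in seq_len(m)) {
    for (try in 1:25) {
      if (runif(1) < pSnp) {
        pos <- sample.int(L0, 1L, prob = w$snp)
        if (occupied(pos, pos)) next
        events$snpPos <- c(events$snpPos, pos)
        events$snpBase <- c(events$snpBase,
                            sample(setdiff(DNA_BASES4, refChars[pos]), 1L))
      } else {
        pos <- sample.int(L0, 1L, prob = w$indel)
        len <- sample.int(10L, 1L)
        e <- min(pos + len - 1L, L0)
        if (occupied(pos, e)) next
        events$dels <- rbind(events$dels, data.frame(start = pos, end = e))
      }
      break
    }
  }
  events
}

#' Simulate a structured population alignment over a reference plastome
#'
#' Builds a haplotype pool by a two-tier star mutation process (deme founders
#' diverge from the ancestral reference by on average
#' \code{divergenceSteps} mutational events; within-deme satellite haplotypes
#' diverge from their founder by on average \code{localSteps} events), varies
#' cpSSR seed repeat numbers among lineages by a stepwise process, assigns
#' each sample the haplotype of its deme's pool (or, with probability
#' \code{admixture}, a haplotype from another deme), and realizes all
#' mutations directly in the alignment coordinate frame: deletions become gap
#' runs of 1-10 columns in the carrier, SSR expansions become gap columns in
#' all non-carriers.
#'
#' @param reference a \code{PlastomeReference} from
#'   \code{\link{simulateReferencePlastome}}.
#' @param demography a \linkS4class{DemographySpec}.
#' @param seed integer seed.
#' @param ssrStepLambda Poisson intensity of the founder-level stepwise SSR
#'   unit change (satellites add +/-1 with probability 0.5).
#' @return a list of class \code{PopulationSim} with elements
#'   \code{alignment} (a \linkS4class{PlastomeAlignment}), \code{popmap},
#'   \code{truth} (sample, population, true haplotype lineage, source deme),
#'   \code{hotspotColumns} (hotspot intervals mapped to alignment columns),
#'   \code{ssrTruth} (samples x SSR-seed matrix of true repeat unit counts),
#'   \code{ssrSeedColumns} (seed loci in alignment coordinates) and
#'   \code{poolSize}.
#' @export
simulatePopulationAlignment <- function(reference, demography, seed = NULL,
                                        ssrStepLambda = 0.8) {
  stopifnot(inherits(reference, "PlastomeReference"),
            is(demography, "DemographySpec"))
  validObject(demography)
  withSeed(seed, {
    refChars <- strsplit(reference$sequence, "")[[1]]
    L0 <- length(refChars)
    w <- mutationWeights(reference)
    seeds <- reference$ssrSeeds
    nSeeds <- nrow(seeds)
    pops <- demography@populations
    nPops <- nrow(pops)
    poolSize <- demography@haplotypePoolSize
    perDeme <- rep(poolSize %/% nPops, nPops)
    extra <- poolSize - sum(perDeme)
    if (extra > 0L) perDeme[seq_len(extra)] <- perDeme[seq_len(extra)] + 1L

    emptyEvents <- list(snpPos = integer(), snpBase = character(),
                        dels = data.frame(start = integer(), end = integer()),
                        ssrUnits = if (nSeeds) seeds$units else integer())
    stepSSR <- function(units, lambda) {
      if (!nSeeds) return(units)
      delta <- rpois(nSeeds, lambda) - rpois(nSeeds, lambda)
      pmax(2L, pmin(seeds$units + 4L, units + delta))
    }
    pool <- list(); demeOf <- integer()
    for (d in seq_len(nPops)) {
      founder <- mutateBranch(emptyEvents, demography@divergenceSteps, w,
                              refChars, seeds)
      founder$ssrUnits <- stepSSR(founder$ssrUnits, ssrStepLambda)
      pool[[length(pool) + 1L]] <- founder; demeOf <- c(demeOf, d)
      if (perDeme[d] > 1L) for (s in seq_len(perDeme[d] - 1L)) {
        sat <- mutateBranch(founder, demography@localSteps, w, refChars, seeds)
        if (nSeeds && runif(1) < 0.5) {
          j <- sample.int(nSeeds, 1L)
          sat$ssrUnits[j] <- max(2L, min(seeds$units[j] + 4L,
                                         sat$ssrUnits[j] + sample(c(-1L, 1L), 1L)))
        }
        pool[[length(pool) + 1L]] <- sat; demeOf <- c(demeOf, d)
      }
    }

    # realized haplotype sequences in a shared alignment frame
    insLen <- matrix(0L, nrow = length(pool), ncol = max(1L, nSeeds))
    if (nSeeds)
      for (hIdx in seq_along(pool))
        insLen[hIdx, ] <- pmax(0L, pool[[hIdx]]$ssrUnits - seeds$units) *
          nchar(seeds$motif)
    extraCols <- if (nSeeds) apply(insLen, 2, max) else integer()
    buildHap <- function(ev, hIdx) {
      chars <- refChars
      if (length(ev$snpPos)) chars[ev$snpPos] <- ev$snpBase
      if (nrow(ev$dels))
        for (i in seq_len(nrow(ev$dels)))
          chars[ev$dels$start[i]:ev$dels$end[i]] <- "-"
      if (!nSeeds) return(paste(chars, collapse = ""))
      for (j in seq_len(nSeeds)) {
        du <- ev$ssrUnits[j] - seeds$units[j]
        p <- nchar(seeds$motif[j])
        if (du < 0L)
          chars[(seeds$end[j] + du * p + 1L):seeds$end[j]] <- "-"
      }
      segs <- character(0); prev <- 1L
      ord <- order(seeds$end)
      for (j in ord) {
        segs <- c(segs, paste(chars[prev:seeds$end[j]], collapse = ""))
        du <- max(0L, ev$ssrUnits[j] - seeds$units[j])
        p <- nchar(seeds$motif[j])
        ins <- strrep(seeds$motif[j], du)
        pad <- strrep("-", extraCols[j] - du * p)
        segs <- c(segs, paste0(ins, pad))
        prev <- seeds$end[j] + 1L
      }
      segs <- c(segs, paste(chars[prev:L0], collapse = ""))
      paste(segs, collapse = "")
    }
    hapSeqs <- vapply(seq_along(pool), function(i) buildHap(pool[[i]], i), "")

    # column map: original position -> alignment column
    shift <- integer(L0)
    if (nSeeds) {
      ord <- order(seeds$end)
      cum <- 0L
      prev <- 1L
      for (j in ord) {
        shift[prev:seeds$end[j]] <- cum
        cum <- cum + extraCols[j]
        prev <- seeds$end[j] + 1L
      }
      if (prev <= L0) shift[prev:L0] <- cum
    }
    colOf <- seq_len(L0) + shift
    hs <- reference$hotspots
    hotspotColumns <- if (nrow(hs))
      data.frame(start = colOf[hs$start], end = colOf[hs$end]) else
      data.frame(start = integer(), end = integer())

    # sample assignment
    demeHaps <- split(seq_along(pool), demeOf)
    sampleNames <- character(); samplePop <- character()
    sampleHap <- integer(); sampleSrc <- integer()
    for (d in seq_len(nPops)) {
      for (i in seq_len(pops$n_samples[d])) {
        src <- d
        if (nPops > 1L && runif(1) < demography@admixture)
          src <- sample(setdiff(seq_len(nPops), d), 1L)
        hIdx <- demeHaps[[as.character(src)]]
        hIdx <- if (length(hIdx) > 1L) sample(hIdx, 1L) else hIdx
        sampleNames <- c(sampleNames, sprintf("%s_%02d", pops$name[d], i))
        samplePop <- c(samplePop, pops$name[d])
        sampleHap <- c(sampleHap, hIdx); sampleSrc <- c(sampleSrc, src)
      }
    }
    aln <- PlastomeAlignment(setNames(hapSeqs[sampleHap], sampleNames),
                             population = setNames(samplePop, sampleNames),
                             group = setNames(pops$group, pops$name))
    popmap <- data.frame(sample_id = sampleNames, population = samplePop,
                         group = pops$group[match(samplePop, pops$name)],
                         stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = sampleNames, population = samplePop,
                        haplotype = paste0("hap", sampleHap),
                        source_deme = pops$name[sampleSrc],
                        stringsAsFactors = FALSE)
    ssrTruth <- NULL; ssrSeedColumns <- NULL
    if (nSeeds) {
      um <- vapply(pool[sampleHap], function(e) e$ssrUnits, integer(nSeeds))
      ssrTruth <- if (nSeeds == 1L) matrix(um, ncol = 1L) else t(um)
      rownames(ssrTruth) <- sampleNames
      ssrSeedColumns <- data.frame(motif = seeds$motif,
                                   start = colOf[seeds$start],
                                   end = colOf[seeds$end] + extraCols)
    }
    structure(list(alignment = aln, popmap = popmap, truth = truth,
                   hotspotColumns = hotspotColumns, poolSize = length(pool),
                   ssrTruth = ssrTruth, ssrSeedColumns = ssrSeedColumns),
              class = "PopulationSim")
  })
}

#' @export
print.PopulationSim <- function(x, ...) {
  cat(sprintf("PopulationSim: %d samples x %d columns, %d haplotype lineages\n",
              length(sampleIDs(x$alignment)), alignmentWidth(x$alignment),
              x$poolSize))
  invisible(x)
}

#' Simulate haploid multilocus cpSSR genotypes with cluster structure
#'
#' Draws per-cluster, per-locus allele frequencies from a Dirichlet with
#' concentration \code{divergence} (small values give strongly diverged,
#' near-fixed clusters), draws each sample's admixture proportions (pure
#' membership when \code{admixtureAlpha = 0}), and samples one allele per
#' locus from the sample's latent origin cluster.
#'
#' @param kTrue number of clusters.
#' @param nLoci number of cpSSR loci.
#' @param samplesPerCluster haploid samples per cluster.
#' @param divergence Dirichlet concentration (> 0) of cluster allele
#'   frequencies.
#' @param admixtureAlpha Dirichlet weight of foreign-cluster membership; 0
#'   gives pure membership.
#' @param seed integer seed.
#' @param nAlleles alleles per locus.
#' @param fixAlleles when TRUE, cluster k is fixed for allele
#'   \code{((k-1) mod nAlleles) + 1} at every locus (clusters share no
#'   alleles when \code{kTrue <= nAlleles}).
#' @return a list of class \code{CpssrSim}: \code{genotypes} (samples x loci
#'   integer matrix), \code{Q} (true admixture proportions), \code{P} (true
#'   allele-frequency array K x loci x alleles), \code{cluster} (origin
#'   labels).
#' @export
simulateCpssrGenotypes <- function(kTrue, nLoci, samplesPerCluster,
                                   divergence = 0.2, admixtureAlpha = 0,
                                   seed = NULL, nAlleles = 4L,
                                   fixAlleles = FALSE) {
  if (divergence <= 0) stopf("divergence (Dirichlet concentration) must be > 0")
  if (kTrue < 1L || nLoci < 1L || samplesPerCluster < 1L)
    stopf("kTrue, nLoci and samplesPerCluster must be >= 1")
  if (admixtureAlpha < 0) stopf("admixtureAlpha must be >= 0")
  withSeed(seed, {
    n <- kTrue * samplesPerCluster
    P <- array(0, dim = c(kTrue, nLoci, nAlleles))
    for (k in seq_len(kTrue)) for (l in seq_len(nLoci)) {
      if (fixAlleles) {
        P[k, l, ((k - 1L) %% nAlleles) + 1L] <- 1
      } else {
        P[k, l, ] <- rdirichlet1(rep(divergence, nAlleles))
      }
    }
    origin <- rep(seq_len(kTrue), each = samplesPerCluster)
    Q <- matrix(0, n, kTrue)
    if (admixtureAlpha == 0) {
      Q[cbind(seq_len(n), origin)] <- 1
    } else {
      for (i in seq_len(n)) {
        a <- rep(admixtureAlpha, kTrue); a[origin[i]] <- admixtureAlpha + 1
        Q[i, ] <- rdirichlet1(a)
      }
    }
    g <- matrix(NA_integer_, n, nLoci)
    for (i in seq_len(n)) for (l in seq_len(nLoci)) {
      z <- sample.int(kTrue, 1L, prob = Q[i, ])
      g[i, l] <- sample.int(nAlleles, 1L, prob = P[z, l, ])
    }
    rownames(g) <- sprintf("s%03d", seq_len(n))
    colnames(g) <- sprintf("locus%d", seq_len(nLoci))
    rownames(Q) <- rownames(g)
    structure(list(genotypes = g, Q = Q, P = P, cluster = origin),
              class = "CpssrSim")
  })
}

#' @export
print.CpssrSim <- function(x, ...) {
  cat(sprintf("CpssrSim: %d haploid samples x %d loci, %d true clusters\n",
              nrow(x$genotypes), ncol(x$genotypes), ncol(x$Q)))
  invisible(x)
}
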