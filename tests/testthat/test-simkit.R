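test_that("reference plastome has quadripartite structure at published scale", {
  spec <- plastomeSpec()     # 84,719 + 12,099 + 2 x 25,984
  ref <- simulateReferencePlastome(spec, seed = 1)
  expect_equal(nchar(ref$sequence), 148786)
  expect_equal(nrow(ref$regions), 4)
  # second IR is the reverse complement of the first
  chars <- strsplit(ref$sequence, "")[[1]]
  ira <- chars[(84719 + 1):(84719 + 25984)]
  irb <- chars[(84719 + 25984 + 12099 + 1):148786]
  expect_identical(irb, rev(unname(c(A = "T", C = "G", G = "C", T = "A")[ira])))
  # declared SSR seeds are present verbatim
  for (i in seq_len(nrow(ref$ssrSeeds))) {
    s <- ref$ssrSeeds[i, ]
    expect_identical(substr(ref$sequence, s$start, s$end),
                     strrep(s$motif, s$units))
  }
})

test_that("reference simulation is deterministic and honors degenerate IR = 0", {
  spec <- plastomeSpec(lscLength = 5000, sscLength = 1000, irLength = 500,
                       nHotspots = 4)
  expect_identical(simulateReferencePlastome(spec, seed = 9)$sequence,
                   simulateReferencePlastome(spec, seed = 9)$sequence)
  noIr <- plastomeSpec(lscLength = 5000, sscLength = 1000, irLength = 0,
                       nHotspots = 4)
  ref <- simulateReferencePlastome(noIr, seed = 3)
  expect_equal(nchar(ref$sequence), 6000)
  expect_false("IRA" %in% ref$regions$region)
})

test_that("non-hotspot GC tracks the background within 2 percentage points", {
  spec <- plastomeSpec(lscLength = 30000, sscLength = 2000, irLength = 1000,
                       nHotspots = 3, hotspotLength = 300)
  ref <- simulateReferencePlastome(spec, seed = 5)
  chars <- strsplit(ref$sequence, "")[[1]]
  bg <- setdiff(seq_len(30000), unlist(mapply(seq, ref$hotspots$start,
                                              ref$hotspots$end)))
  gc <- mean(chars[bg] %in% c("G", "C"))
  expect_lt(abs(gc - 0.375), 0.02)
})

test_that("overlapping hotspot intervals are a specification error", {
  h <- data.frame(start = c(100, 300), end = c(400, 600), gc_local = 0.25,
                  snp_rate = 0.01, indel_rate = 0.01)
  expect_error(plastomeSpec(lscLength = 5000, sscLength = 0, irLength = 0,
                            hotspots = h, ssrSeeds = data.frame()),
               "overlap")
})

test_that("zero mutation rates collapse the population to one haplotype", {
  h <- data.frame(start = 1000, end = 1400, gc_local = 0.25,
                  snp_rate = 0, indel_rate = 0)
  spec <- plastomeSpec(lscLength = 5000, sscLength = 0, irLength = 0,
                       hotspots = h,
                       ssrSeeds = data.frame(hotspot = integer(),
                                             motif = character(),
                                             units = integer()))
  ref <- simulateReferencePlastome(spec, seed = 2)
  demo <- demographySpec(populations = data.frame(name = c("a", "b"),
                                                  n_samples = c(3L, 3L),
                                                  group = "g"),
                         haplotypePoolSize = 4, divergenceSteps = 5,
                         admixture = 0)
  sim <- simulatePopulationAlignment(ref, demo, seed = 4)
  seqs <- as.character(sim$alignment@seqs)
  expect_true(all(seqs == seqs[1]))
  ht <- suppressWarnings(collapseHaplotypes(sim$alignment))
  expect_equal(nrow(haplotypeCounts(ht)), 1)
})

test_that("hotspot bins accumulate more SNPs than background bins", {
  # Monte-Carlo across replicate simulations of the small fixture; the
  # hotspot SNP rate is 10x the background rate by construction.
  reps <- 20
  wins <- 0
  for (r in seq_len(reps)) {
    fx <- smallSimFixture(seedRef = 1000 + r, seedPop = 2000 + r)
    bins <- profileBins(fx$sim$alignment, binLength = 400)
    hot <- rep(FALSE, nrow(bins))
    for (i in seq_len(nrow(fx$sim$hotspotColumns)))
      hot <- hot | (bins$start <= fx$sim$hotspotColumns$end[i] &
                    bins$end >= fx$sim$hotspotColumns$start[i])
    if (mean(bins$snp_count[hot]) > mean(bins$snp_count[!hot])) wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("doubling the hotspot SNP rate does not decrease hotspot SNP counts", {
  countHotspotSnps <- function(rate, seedOffset) {
    h <- data.frame(start = c(500, 2000, 3500), end = c(900, 2400, 3900),
                    gc_local = 0.25, snp_rate = rate, indel_rate = 0.002)
    spec <- plastomeSpec(lscLength = 5000, sscLength = 0, irLength = 0,
                         hotspots = h,
                         ssrSeeds = data.frame(hotspot = integer(),
                                               motif = character(),
                                               units = integer()))
    ref <- simulateReferencePlastome(spec, seed = 11 + seedOffset)
    demo <- demographySpec(populations = data.frame(name = c("a", "b"),
                                                    n_samples = c(4L, 4L),
                                                    group = "g"),
                           haplotypePoolSize = 4, divergenceSteps = 6,
                           admixture = 0)
    sim <- simulatePopulationAlignment(ref, demo, seed = 21 + seedOffset)
    bins <- profileBins(sim$alignment, binLength = 400)
    hot <- rep(FALSE, nrow(bins))
    for (i in seq_len(nrow(sim$hotspotColumns)))
      hot <- hot | (bins$start <= sim$hotspotColumns$end[i] &
                    bins$end >= sim$hotspotColumns$start[i])
    mean(bins$snp_count[hot])
  }
  lo <- vapply(1:20, function(r) countHotspotSnps(0.01, 100 * r), 0)
  hi <- vapply(1:20, function(r) countHotspotSnps(0.02, 100 * r + 50), 0)
  se <- sqrt(var(lo) / 20 + var(hi) / 20)
  expect_gte(mean(hi) - mean(lo), -2 * se)
})

test_that("cpSSR genotype simulation obeys its contracts", {
  sim <- simulateCpssrGenotypes(5, 6, 6, divergence = 0.2, seed = 31)
  # a 28-sample x 6-locus shaped design (5 clusters here sum to 30)
  expect_equal(dim(sim$genotypes), c(30, 6))
  expect_true(all(rowSums(sim$Q) == 1))

  fixed <- simulateCpssrGenotypes(2, 8, 10, fixAlleles = TRUE, seed = 32)
  a1 <- unique(as.vector(fixed$genotypes[fixed$cluster == 1, ]))
  a2 <- unique(as.vector(fixed$genotypes[fixed$cluster == 2, ]))
  expect_length(intersect(a1, a2), 0)
  expect_true(all(fixed$Q %in% c(0, 1)))   # admixtureAlpha = 0: pure membership

  expect_error(simulateCpssrGenotypes(2, 6, 5, divergence = 0), "> 0")
  expect_identical(simulateCpssrGenotypes(3, 6, 5, seed = 7)$genotypes,
                   simulateCpssrGenotypes(3, 6, 5, seed = 7)$genotypes)
})

test_that("simulated SSR truth matches the polymorphic cpSSR screen", {
  fx <- smallSimFixture()
  sim <- fx$sim
  scr <- screenPolymorphicSsrs(trimAlignment(sim$alignment)$alignment)
  seedSpans <- sim$ssrSeedColumns
  # which seed loci truly vary among the sampled haplotypes
  trulyPoly <- apply(sim$ssrTruth, 2, function(u) length(unique(u)) > 1)
  hitSeed <- function(r) {
    which(seedSpans$start <= scr$clusters$aln_end[r] &
          seedSpans$end >= scr$clusters$aln_start[r])[1]
  }
  seedOfCluster <- vapply(seq_len(nrow(scr$clusters)), hitSeed, 0L)
  polyClusters <- which(scr$clusters$polymorphic)
  # every truly polymorphic seed is recovered as a polymorphic cluster
  expect_setequal(na.omit(seedOfCluster[polyClusters]), which(trulyPoly))
  # and no polymorphic cluster lies outside the seeded loci
  expect_false(anyNA(seedOfCluster[polyClusters]))
  # detected allele (unit) differences reproduce the truth differences
  for (r in polyClusters) {
    sd <- seedOfCluster[r]
    det <- scr$alleles[r, rownames(sim$ssrTruth)]
    expect_equal(det - min(det), sim$ssrTruth[, sd] - min(sim$ssrTruth[, sd]),
                 ignore_attr = TRUE)
  }
})
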