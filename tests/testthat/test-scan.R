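test_that("ambiguous columns are trimmed and mapped back to original coordinates", {
  aln <- PlastomeAlignment(c(a = "ACGTNACGT-", b = "ACGTAACRT-", c = "ACGTAACGT-"))
  tr <- trimAlignment(aln)
  # columns 5 (N in a) and 8 (R in b) removed
  expect_equal(alignmentWidth(tr$alignment), 8)
  expect_equal(tr$report$original_col, c(1:4, 6, 7, 9, 10))
  # re-applying the report to the original reconstructs the trimmed set
  m <- alignmentMatrix(aln)
  rebuilt <- apply(m[, tr$report$original_col], 1, paste, collapse = "")
  expect_identical(unname(rebuilt),
                   unname(as.character(tr$alignment@seqs)))

  clean <- PlastomeAlignment(c(a = "ACGT", b = "AC-T"))
  expect_identical(as.character(trimAlignment(clean)$alignment@seqs),
                   as.character(clean@seqs))
  allBad <- PlastomeAlignment(c(a = "NNN", b = "NNN"))
  expect_error(trimAlignment(allBad), "ambiguous")
})

test_that("bin tiling matches the published 372 x 400 bp design", {
  L <- 148800
  aln <- PlastomeAlignment(c(a = strrep("ACGT", L / 4), b = strrep("ACGT", L / 4)))
  bins <- profileBins(aln, binLength = 400)
  expect_equal(nrow(bins), 372)
  expect_equal(bins$start, seq(1, L, by = 400))
  expect_true(all(bins$end - bins$start + 1 == 400))
  expect_true(all(bins$snp_count == 0))
  expect_true(all(bins$indel_count == 0))
})

test_that("a hand-built alignment yields the enumerated bin profile", {
  #            12345678901234567890
  a <- PlastomeAlignment(c(s1 = "AAAATTTTCCCCGGGGACGT",
                           s2 = "AAGATTTTCC---GGGACGT",
                           s3 = "AATATTTTCCCCGGGGACGA"))
  bins <- profileBins(a, binLength = 20)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$snp_count, 2)    # columns 3 and 20 segregate; col 11-13 gap
  expect_equal(bins$indel_count, 1)  # one 3-column gap run
  # short final bin is retained, and events land in the bin of their left end
  bins2 <- profileBins(a, binLength = 12)
  expect_equal(nrow(bins2), 2)
  expect_equal(bins2$end, c(12, 20))
  expect_equal(bins2$indel_count, c(1, 0))
  expect_equal(sum(bins2$snp_count), 2)
})

test_that("per-bin SNP counts sum to total segregating sites and indel events are conserved", {
  set.seed(404)
  for (rep in 1:5) {
    n <- 4; L <- 130
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(0.35, 0.15, 0.15, 0.35)), n, L)
    base <- sample(4, 1)
    m <- matrix(m[base, ], n, L, byrow = TRUE)   # clone, then mutate
    for (k in 1:10) m[sample(n, 1), sample(L, 1)] <- sample(c("A", "C", "G", "T"), 1)
    for (k in 1:3) {
      i <- sample(n, 1); s <- sample(L - 6, 1)
      m[i, s:(s + sample(3, 1))] <- "-"
    }
    rownames(m) <- paste0("s", 1:n)
    aln <- PlastomeAlignment(apply(m, 1, paste, collapse = ""))
    segSites <- sum(vapply(seq_len(L), function(j) {
      b <- unique(m[, j]); length(setdiff(b, "-")) >= 2
    }, TRUE))
    for (bl in c(13, 50, 200)) {
      bins <- profileBins(aln, binLength = bl)
      expect_equal(sum(bins$snp_count), segSites)
      runs <- unique(do.call(rbind, lapply(1:n, function(i) {
        r <- rle(m[i, ] == "-")
        if (!any(r$values)) return(NULL)
        e <- cumsum(r$lengths); s <- e - r$lengths + 1
        cbind(s[r$values], e[r$values])
      })))
      expect_equal(sum(bins$indel_count), nrow(runs))
    }
  }
})

test_that("SSR detection honors the 8-unit mono / 5-unit multi thresholds", {
  expect_equal(nrow(detectSsrs(strrep("A", 8))), 1)
  expect_equal(detectSsrs(strrep("A", 8))$units, 8)
  expect_equal(nrow(detectSsrs(strrep("A", 7))), 0)
  at5 <- detectSsrs("GATATATATATC")
  expect_equal(nrow(at5), 1)
  expect_equal(at5$units, 5)
  expect_equal(at5$length, 10)
  expect_true(at5$motif %in% c("AT", "TA"))
  expect_equal(nrow(detectSsrs("GATATATATC")), 0)   # (AT)4: below threshold
  expect_error(detectSsrs("ACGTN"), "outside")
})

test_that("SSR detection equals the brute-force oracle on random sequences", {
  set.seed(77)
  for (rep in 1:12) {
    # repeat-enriched random sequences
    parts <- c(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               strrep(sample(c("A", "T", "AT", "TA", "AAG", "ACGT"), 1),
                      sample(4:12, 1)),
               sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               strrep(sample(c("C", "G", "CT", "TTA"), 1), sample(5:11, 1)),
               sample(c("A", "C", "G", "T"), 30, replace = TRUE))
    s <- paste(parts, collapse = "")
    expect_equal(detectSsrs(s), oracleDetectSsrs(s), ignore_attr = TRUE)
  }
})

test_that("SSR loci are invariant under sequence reversal up to coordinates", {
  set.seed(12)
  s <- paste0(paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
              strrep("AG", 7),
              paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
              strrep("T", 9))
  fwd <- detectSsrs(s)
  rev <- detectSsrs(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  L <- nchar(s)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(L - fwd$end + 1, rev$start)
  expect_setequal(fwd$units, rev$units)
})

test_that("Spearman rho matches hand computation and flags constant input", {
  expect_equal(spearmanRho(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearmanRho(1:3, c(3, 2, 1))$rho, -1)
  # tie-corrected hand oracle: Pearson on average ranks
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  handRho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearmanRho(x, y)
  expect_equal(got$rho, handRho)
  # agrees with the t-approximation route of the standard implementation
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate))
  expect_warning(out <- spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out$rho))
  expect_equal(spearmanRho(x, y)$rho, spearmanRho(y, x)$rho)
})

test_that("hotspot ranking applies scoring, tie-breaks and adjacency merging", {
  prof <- data.frame(bin_index = 1:6, start = seq(1, 2001, 400),
                     end = seq(400, 2400, 400),
                     gc = 0.3, snp_count = c(0, 5, 0, 0, 0, 0),
                     indel_count = c(0, 1, 0, 0, 0, 0), ssr_count = 0)
  expect_warning(one <- rankHotspots(prof, k = 27), "only 1")
  expect_equal(nrow(one), 1)
  expect_equal(one$snp_total, 5)

  # equal-score bins at positions 1, 3, 5: coordinate tie-break picks 1 and 3
  tie <- data.frame(bin_index = 1:5, start = seq(1, 1601, 400),
                    end = seq(400, 2000, 400), gc = 0.3,
                    snp_count = c(3, 0, 3, 0, 3), indel_count = 0, ssr_count = 0)
  two <- rankHotspots(tie, k = 2)
  expect_equal(sort(two$start), c(1, 801))

  # adjacent selected bins fuse, totals summed, rank 1 = most variable
  adj <- data.frame(bin_index = 1:5, start = seq(1, 1601, 400),
                    end = seq(400, 2000, 400), gc = 0.3,
                    snp_count = c(4, 3, 0, 2, 0), indel_count = c(1, 0, 0, 0, 0),
                    ssr_count = 0)
  merged <- rankHotspots(adj, k = 2)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start[merged$rank == 1], 1)
  expect_equal(merged$end[merged$rank == 1], 800)
  expect_equal(merged$snp_total[merged$rank == 1], 7)
  expect_equal(merged$indel_total[merged$rank == 1], 1)
})

test_that("screened hotspot regions recover true simulated hotspots", {
  reps <- 20
  frac <- numeric(reps)
  for (r in seq_len(reps)) {
    fx <- smallSimFixture(seedRef = 5000 + r, seedPop = 6000 + r)
    bins <- profileBins(fx$sim$alignment, binLength = 400)
    regs <- suppressWarnings(rankHotspots(bins, k = 8))
    hits <- vapply(seq_len(nrow(regs)), function(i)
      any(regs$start[i] <= fx$sim$hotspotColumns$end &
          regs$end[i] >= fx$sim$hotspotColumns$start), TRUE)
    frac[r] <- mean(hits)
  }
  expect_gte(mean(frac >= 0.8), 0.8)
})

test_that("polymorphic cpSSR screening separates shared and divergent loci", {
  # (A)9 vs (A)11 at a homologous position: one polymorphic cluster
  aln <- PlastomeAlignment(c(
    s1 = paste0("GCGC", strrep("A", 9), "--CGCGCGGT"),
    s2 = paste0("GCGC", strrep("A", 11), "CGCGCGGT")))
  scr <- screenPolymorphicSsrs(aln)
  expect_equal(nrow(scr$clusters), 1)
  expect_true(scr$clusters$polymorphic)
  expect_setequal(scr$alleles[1, ], c(9, 11))

  # identical sequences: zero polymorphic clusters
  same <- PlastomeAlignment(c(s1 = paste0("GC", strrep("TA", 6), "GGTT"),
                              s2 = paste0("GC", strrep("TA", 6), "GGTT")))
  scr2 <- screenPolymorphicSsrs(same)
  expect_false(any(scr2$clusters$polymorphic))
})
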