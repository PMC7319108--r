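eqDist <- function(n) {
  d <- matrix(1, n, n); diag(d) <- 0
  dimnames(d) <- list(paste0("H", 1:n), paste0("H", 1:n))
  d
}

test_that("Pons-Petit estimators behave at the differentiation extremes", {
  # two populations fixed for different haplotypes
  cnt <- matrix(c(4L, 0L, 0L, 4L), 2, 2,
                dimnames = list(c("H1", "H2"), c("p1", "p2")))
  pd <- permutDiversity(cnt, eqDist(2))
  expect_equal(pd$Hs, 0)
  expect_equal(pd$Gst, 1)
  expect_equal(pd$Nst, 1)

  # one population duplicated as two: no differentiation (the unbiased
  # corrections leave an O(1/n) remainder, so use a well-sampled table)
  cnt2 <- matrix(c(30L, 20L, 10L, 30L, 20L, 10L), 3, 2,
                 dimnames = list(paste0("H", 1:3), c("p1", "p2")))
  pd2 <- permutDiversity(cnt2, eqDist(3))
  expect_lt(abs(pd2$Gst), 0.02)

  # populations below n = 2 are excluded with a warning
  cnt3 <- cbind(cnt2, p3 = c(1L, 0L, 0L))
  expect_warning(pd3 <- permutDiversity(cnt3, eqDist(3)), "excluding")
  expect_equal(pd3$nPopulations, 2)
})

test_that("Nst equals Gst exactly when all inter-haplotype distances are equal", {
  set.seed(99)
  for (r in 1:20) {
    nh <- sample(3:6, 1); P <- 3
    cnt <- matrix(rpois(nh * P, 2), nh, P,
                  dimnames = list(paste0("H", 1:nh), paste0("p", 1:P)))
    cnt[1, ] <- cnt[1, ] + 2L   # keep all populations at n >= 2
    pd <- suppressWarnings(permutDiversity(cnt, eqDist(nh)))
    expect_equal(pd$Nst, pd$Gst, tolerance = 1e-12)
    expect_equal(pd$vS, pd$Hs, tolerance = 1e-12)
    expect_equal(pd$vT, pd$Ht, tolerance = 1e-12)
  }
})

test_that("within-population diversity reproduces the published Hs = 0.663", {
  cnt <- fivePopHaplotypeCounts()
  nh <- nrow(cnt)
  d <- matrix(1, nh, nh); diag(d) <- 0
  pd <- permutDiversity(cnt, d)
  expect_equal(round(pd$Hs, 3), 0.663)
})

test_that("the Nst > Gst permutation test is deterministic and calibrated", {
  cnt <- matrix(c(4L, 1L, 0L, 1L, 4L, 0L, 0L, 1L, 3L), 3, 3,
                dimnames = list(paste0("H", 1:3), paste0("p", 1:3)))
  d <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3)
  t1 <- testNstGtGst(cnt, d, nPerm = 200, seed = 10)
  t2 <- testNstGtGst(cnt, d, nPerm = 200, seed = 10)
  expect_identical(t1, t2)
  expect_gt(t1$p, 0); expect_lte(t1$p, 1)

  # equal distances: observed statistic 0, p high
  tEq <- testNstGtGst(cnt, eqDist(3), nPerm = 200, seed = 11)
  expect_equal(tEq$observed, 0)
  expect_gt(tEq$p, 0.5)
})

test_that("the Nst > Gst test has power on structured simulations", {
  # isolated demes (admixture 0) at 5 expected founder steps; a richer
  # haplotype pool gives the permutation null enough distinct arrangements
  reps <- 20; sig <- 0
  spec <- plastomeSpec(lscLength = 6000, sscLength = 1500, irLength = 600,
                       nHotspots = 8, hotspotLength = 300)
  demo <- demographySpec(
    populations = data.frame(name = paste0("p", 1:3),
                             n_samples = c(8L, 7L, 6L), group = "g"),
    haplotypePoolSize = 12, divergenceSteps = 5, localSteps = 1,
    admixture = 0)
  for (r in seq_len(reps)) {
    ref <- simulateReferencePlastome(spec, seed = 8000 + r)
    sim <- simulatePopulationAlignment(ref, demo, seed = 9000 + r)
    ht <- suppressWarnings(
      collapseHaplotypes(trimAlignment(sim$alignment)$alignment))
    if (nrow(haplotypeCounts(ht)) < 2) next
    res <- tryCatch(
      testNstGtGst(haplotypeCounts(ht), stepDistances(ht), nPerm = 199,
                   seed = r),
      error = function(e) NULL)
    if (!is.null(res) && res$p < 0.05) sig <- sig + 1
  }
  expect_gte(sig, 16)
})

test_that("one-level AMOVA on two fixed populations gives Phi_ST = 1", {
  d <- matrix(c(0, 0, 1, 1,
                0, 0, 1, 1,
                1, 1, 0, 0,
                1, 1, 0, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  pops <- setNames(c("X", "X", "Y", "Y"), paste0("s", 1:4))
  res <- amova(d, pops, nPerm = 0)
  tab <- res$table
  expect_equal(tab$SS[tab$source == "Among populations"], 1)
  expect_equal(tab$SS[tab$source == "Within populations"], 0)
  expect_equal(tab$sigma2[tab$source == "Among populations"], 0.5)
  expect_equal(unname(res$phi["PhiST"]), 1)
})

test_that("AMOVA on identical samples reports zero components and undefined Phi", {
  d <- matrix(0, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  pops <- setNames(c("a", "a", "b", "b", "b"), paste0("s", 1:5))
  res <- amova(d, pops, nPerm = 0)
  expect_true(all(res$table$sigma2 == 0))
  expect_true(is.na(res$phi["PhiST"]))
})

test_that("AMOVA components equal the expected-mean-squares oracle", {
  set.seed(2024)
  for (r in 1:10) {
    P <- 3; G <- 2
    nk <- sample(2:5, P, replace = TRUE)
    while (sum(nk) > 15) nk <- sample(2:5, P, replace = TRUE)
    N <- sum(nk)
    pop <- rep(paste0("p", 1:P), nk)
    grpOfPop <- setNames(c("g1", "g1", "g2"), paste0("p", 1:P))
    grp <- as.character(grpOfPop[pop])
    Y <- matrix(rnorm(N * 3), N, 3) +
      rep(rnorm(P, sd = 1.2), nk) + ifelse(grp == "g1", 0.8, -0.8)
    ids <- paste0("s", seq_len(N))
    rownames(Y) <- ids
    d <- as.matrix(dist(Y))

    # one level
    got <- amova(d, setNames(pop, ids), nPerm = 0)
    want <- oracleAmovaEuclid(Y, pop)
    tab <- got$table
    expect_equal(tab$SS[1], unname(want$SS["AP"]), tolerance = 1e-8)
    expect_equal(tab$SS[2], unname(want$SS["WP"]), tolerance = 1e-8)
    expect_equal(tab$sigma2[1:2], unname(want$sigma2[c("a", "c")]),
                 tolerance = 1e-8)
    expect_equal(unname(got$phi["PhiST"]), want$phiST, tolerance = 1e-8)

    # two levels
    got2 <- amova(d, setNames(pop, ids), groups = grpOfPop, nPerm = 0)
    want2 <- oracleAmovaEuclid(Y, pop, grp)
    tab2 <- got2$table
    expect_equal(tab2$SS[1:3], unname(want2$SS), tolerance = 1e-8)
    expect_equal(tab2$sigma2[1:3], unname(want2$sigma2), tolerance = 1e-8)
    expect_equal(unname(got2$phi), c(want2$phiCT, want2$phiSC, want2$phiST),
                 tolerance = 1e-8)

    # using d (not d^2) as delta^2 is a different, consistent decomposition
    gotRaw <- amova(d^2, setNames(pop, ids), nPerm = 0, squared = FALSE)
    expect_equal(gotRaw$table$SS, got$table$SS, tolerance = 1e-10)
  }
})

test_that("a single-group grouped design reduces to the one-level AMOVA", {
  set.seed(5)
  Y <- matrix(rnorm(12), 6, 2)
  rownames(Y) <- paste0("s", 1:6)
  d <- as.matrix(dist(Y))
  pops <- setNames(rep(c("a", "b", "c"), each = 2), rownames(Y))
  one <- amova(d, pops, nPerm = 0)
  grouped <- amova(d, pops, groups = c(a = "g", b = "g", c = "g"), nPerm = 0)
  expect_equal(unname(grouped$phi["PhiST"]), unname(one$phi["PhiST"]),
               tolerance = 1e-12)
})

test_that("one-level AMOVA reproduces the published five-population table", {
  # per-sample haplotype assignment from the printed per-population counts;
  # haplotype-frequency distances (0 same, 1 different)
  cnt <- fivePopHaplotypeCounts()
  hap <- character(); pop <- character()
  for (p in colnames(cnt)) for (h in rownames(cnt)) {
    hap <- c(hap, rep(h, cnt[h, p])); pop <- c(pop, rep(p, cnt[h, p]))
  }
  ids <- sprintf("ind%02d", seq_along(hap))
  d <- outer(hap, hap, function(a, b) as.numeric(a != b))
  dimnames(d) <- list(ids, ids)
  res <- amova(d, setNames(pop, ids), nPerm = 0)   # 0/1 distances: d^2 = d
  tab <- res$table
  expect_equal(tab$df[1:2], c(4, 23))
  expect_equal(round(tab$SS, 3), c(2.683, 9.067, 11.750))
  expect_equal(round(tab$sigma2[1], 5), 0.05177)
  expect_equal(round(tab$sigma2[2], 5), 0.39424)
  expect_equal(round(tab$pct[1], 2), 11.61)
  expect_equal(round(tab$pct[2], 2), 88.39)
  expect_equal(round(unname(res$phi["PhiST"]), 4), 0.1161)
})

test_that("permutation p-values are valid and uniform under exchangeability", {
  set.seed(31)
  # determinism
  Y <- matrix(rnorm(20), 10, 2); rownames(Y) <- paste0("s", 1:10)
  d <- as.matrix(dist(Y))
  pops <- setNames(rep(c("a", "b"), 5), rownames(Y))
  r1 <- amova(d, pops, nPerm = 99, seed = 42)
  r2 <- amova(d, pops, nPerm = 99, seed = 42)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p[["PhiST"]], 0); expect_lte(r1$p[["PhiST"]], 1)

  # label-exchangeable data: p approximately uniform (KS at alpha = 0.01)
  ps <- vapply(1:200, function(r) {
    Y <- matrix(rnorm(24), 12, 2)
    rownames(Y) <- paste0("s", 1:12)
    pops <- setNames(sample(rep(c("a", "b", "c"), 4)), rownames(Y))
    amova(as.matrix(dist(Y)), pops, nPerm = 99, seed = r)$p[["PhiST"]]
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sample-level distances expand haplotype steps consistently", {
  aln <- PlastomeAlignment(c(a = "AATA", b = "ACTA", c = "AATA"),
                           population = c(a = "p1", b = "p1", c = "p2"))
  ht <- collapseHaplotypes(aln)
  d <- sampleStepDistances(ht)
  expect_equal(dim(d), c(3, 3))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 1)
})
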