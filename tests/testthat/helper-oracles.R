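# Independent oracles used to freeze expected values. Each reimplements the
# target quantity by a different route (brute force, enumeration, linear
# algebra) and must stay independent of the package code paths it checks.

# ---- brute-force perfect-tandem-repeat scanner -----------------------------
# Enumerates every (start, period) pair, counts whole units directly, keeps
# left-maximal primitive-motif candidates, then applies the leftmost-longest
# overlap rule.
oracleDetectSsrs <- function(seq, minMono = 8, minMulti = 5, maxMotif = 6) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  cand <- list()
  for (st in seq_len(L)) for (p in seq_len(maxMotif)) {
    if (st + 2 * p - 1 > L) next
    motif <- paste(s[st:(st + p - 1)], collapse = "")
    u <- 1
    while (st + (u + 1) * p - 1 <= L &&
           paste(s[(st + u * p):(st + (u + 1) * p - 1)], collapse = "") == motif)
      u <- u + 1
    thr <- if (p == 1) minMono else minMulti
    if (u < thr) next
    if (st > 1 && s[st - 1] == s[st + p - 1]) next   # extendable left
    prim <- TRUE
    if (p > 1) for (d in seq_len(p - 1)) {
      if (p %% d == 0 && strrep(substr(motif, 1, d), p / d) == motif) prim <- FALSE
    }
    if (!prim) next
    cand[[length(cand) + 1]] <- data.frame(
      start = st, end = st + u * p - 1, motif = motif, units = u,
      length = u * p, period = p, stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      units = integer(), length = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -cand$length, cand$period), , drop = FALSE]
  keep <- logical(nrow(cand)); keepEnd <- -1
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > keepEnd) { keep[i] <- TRUE; keepEnd <- cand$end[i] }
  }
  out <- cand[keep, c("start", "end", "motif", "units", "length")]
  rownames(out) <- NULL
  out
}

# ---- AMOVA via coordinates + numerically derived EMS coefficients ----------
# Samples are points in R^m; squared Euclidean distances are the AMOVA input.
# Sums of squares come from projection quadratic forms and the variance
# components from solving the expected-mean-square linear system whose
# coefficients are matrix traces (never the closed-form n' formulas).
oracleAmovaEuclid <- function(Y, pop, grp = NULL) {
  n <- nrow(Y)
  I <- diag(n); J <- matrix(1 / n, n, n)
  proj <- function(f) {
    H <- matrix(0, n, n)
    for (lev in unique(f)) {
      idx <- which(f == lev)
      H[idx, idx] <- 1 / length(idx)
    }
    H
  }
  Hp <- proj(pop)
  Zb <- outer(pop, unique(pop), "==") * 1
  Vb <- Zb %*% t(Zb)
  ssOf <- function(A) sum((A %*% Y) * Y)
  trOf <- function(A, V = I) sum(diag(A %*% V))
  if (is.null(grp)) {
    A_AP <- Hp - J; A_WP <- I - Hp
    SS <- c(ssOf(A_AP), ssOf(A_WP))
    # rows: SS_AP, SS_WP; cols: sigma2_a (pops), sigma2_c (error)
    M <- rbind(c(trOf(A_AP, Vb), trOf(A_AP)),
               c(trOf(A_WP, Vb), trOf(A_WP)))
    comp <- solve(M, SS)
    list(SS = c(AP = SS[1], WP = SS[2]),
         sigma2 = c(a = comp[1], c = comp[2]),
         phiST = comp[1] / sum(comp))
  } else {
    Hg <- proj(grp)
    Za <- outer(grp, unique(grp), "==") * 1
    Va <- Za %*% t(Za)
    A_AG <- Hg - J; A_AP <- Hp - Hg; A_WP <- I - Hp
    SS <- c(ssOf(A_AG), ssOf(A_AP), ssOf(A_WP))
    M <- rbind(c(trOf(A_AG, Va), trOf(A_AG, Vb), trOf(A_AG)),
               c(trOf(A_AP, Va), trOf(A_AP, Vb), trOf(A_AP)),
               c(trOf(A_WP, Va), trOf(A_WP, Vb), trOf(A_WP)))
    comp <- solve(M, SS)
    tot <- sum(comp)
    list(SS = c(AG = SS[1], APWG = SS[2], WP = SS[3]),
         sigma2 = c(a = comp[1], b = comp[2], c = comp[3]),
         phiCT = comp[1] / tot,
         phiSC = comp[2] / (comp[2] + comp[3]),
         phiST = (comp[1] + comp[2]) / tot)
  }
}

# ---- exhaustive union-of-MSTs via Pruefer enumeration ----------------------
oracleMstUnion <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 7)
  decodePruefer <- function(pr) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 1L
    for (v in pr) {
      leaf <- which(degree == 1L)[1]
      edges[ptr, ] <- c(leaf, v); ptr <- ptr + 1L
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    edges[ptr, ] <- last
    edges
  }
  prs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf; union <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(prs))) {
    e <- decodePruefer(prs[r, ])
    wsum <- sum(d[e])
    if (wsum < best - 1e-9) { best <- wsum; union <- e }
    else if (wsum <= best + 1e-9) union <- rbind(union, e)
  }
  u <- unique(t(apply(union, 1, sort)))
  u[order(u[, 1], u[, 2]), , drop = FALSE]
}

# ---- direct mean pairwise difference nucleotide diversity -------------------
oraclePi <- function(seqMat, L) {
  n <- nrow(seqMat)
  acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    acc <- acc + sum(seqMat[i, ] != seqMat[j, ])
  (n / (n - 1)) * (2 / n^2) * acc / L
}

# ---- construct a HaplotypeTable directly from a state matrix ---------------
makeHapTable <- function(states, counts = NULL, charType = NULL) {
  n <- nrow(states)
  if (is.null(counts))
    counts <- matrix(1L, n, 1, dimnames = list(paste0("H", seq_len(n)), "p1"))
  if (is.null(charType)) charType <- rep("substitution", ncol(states))
  nTot <- sum(counts)
  hapOfSample <- rep(rownames(counts), rowSums(counts))
  names(hapOfSample) <- sprintf("s%03d", seq_len(nTot))
  rownames(states) <- rownames(counts)
  new("HaplotypeTable", signatures = states, charType = charType,
      charColumn = seq_len(ncol(states)), counts = counts,
      sampleHaplotype = hapOfSample, nTotal = as.integer(nTot),
      lEffective = as.integer(ncol(states)))
}

# ---- printed per-population haplotype counts (five-population design) ------
fivePopHaplotypeCounts <- function() {
  haps <- paste0("H", 1:11)
  pops <- c("DabieshanHuoshan", "DabieshanLuan", "Huangshan", "Longhushan",
            "Funiushan")
  m <- matrix(0L, length(haps), length(pops), dimnames = list(haps, pops))
  m[c("H1", "H2", "H3", "H4", "H5"), "DabieshanHuoshan"] <- c(2L, 4L, 1L, 1L, 1L)
  m[c("H2", "H4", "H5", "H6"), "DabieshanLuan"] <- c(3L, 1L, 1L, 2L)
  m["H6", "Huangshan"] <- 2L
  m[c("H1", "H2", "H7", "H8"), "Longhushan"] <- c(1L, 2L, 2L, 1L)
  m[c("H9", "H10", "H11"), "Funiushan"] <- c(2L, 1L, 1L)
  m
}

# small shared simulation fixture (seeds fixed for reproducibility)
smallSimFixture <- function(seedRef = 42, seedPop = 7, admixture = 0,
                            divergenceSteps = 5) {
  spec <- plastomeSpec(lscLength = 6000, sscLength = 1500, irLength = 600,
                       nHotspots = 8, hotspotLength = 300)
  ref <- simulateReferencePlastome(spec, seed = seedRef)
  demo <- demographySpec(
    populations = data.frame(name = paste0("p", 1:3),
                             n_samples = c(6L, 5L, 4L),
                             group = c("g1", "g1", "g2")),
    haplotypePoolSize = 6, divergenceSteps = divergenceSteps,
    localSteps = 1, admixture = admixture)
  sim <- simulatePopulationAlignment(ref, demo, seed = seedPop)
  list(spec = spec, ref = ref, demo = demo, sim = sim)
}
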