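#' Fit a haploid admixture model by Gibbs sampling
#'
#' Model-based clustering of haploid multilocus genotypes (the cpSSR use
#' case): each sample i draws the latent origin z of its allele at locus l
#' from its admixture proportions Q[i, ], and the allele from the origin
#' cluster's locus frequencies P. The Gibbs sweep updates
#' P | z ~ Dirichlet(lambda + counts), Q | z ~ Dirichlet(alpha0 + counts) and
#' z | P, Q categorical with probability proportional to
#' \eqn{q_{ik} p_{kl a}}. Allele frequencies use the independent Dirichlet
#' prior (lambda per allele), not the correlated-frequency model. The model
#' log-probability is estimated as \eqn{\overline{\ln L} -
#' \mathrm{var}(\ln L)/2} over post-burn-in sweeps, with
#' \eqn{\ln L = \sum_{il} \ln \sum_k q_{ik} p_{kl a_{il}}}. For K = 1 the
#' result is analytic: Q is a column of ones and lnpd is the exact
#' Dirichlet-multinomial marginal likelihood.
#'
#' @param g samples x loci integer matrix of allele codes; \code{NA} or
#'   \code{-9} mark missing calls. Codes are locus-local.
#' @param K number of clusters (1 to number of samples).
#' @param burnin,iters burn-in and retained sweeps (defaults 5000 / 20000;
#'   scale up for production runs).
#' @param alpha0 Dirichlet admixture prior (> 0, default 1).
#' @param lambda allele-frequency prior (> 0, default 1).
#' @param seed integer seed; fixed seed gives identical results.
#' @return a \linkS4class{ClusterResult}.
#' @export
fitAdmixture <- function(g, K, burnin = 5000L, iters = 20000L,
                         alpha0 = 1, lambda = 1, seed = NULL) {
  g <- as.matrix(g)
  g[g == -9] <- NA
  n <- nrow(g); L <- ncol(g)
  if (K < 1L) stopf("K must be >= 1")
  if (K > n) stopf("K may not exceed the number of samples")
  if (iters < 1L || L < 1L) stopf("iters and loci must be >= 1")
  if (alpha0 <= 0 || lambda <= 0) stopf("alpha0 and lambda must be > 0")
  empty <- colSums(!is.na(g)) == 0L
  if (any(empty)) {
    warnf("dropping %d locus/loci with no observed alleles", sum(empty))
    g <- g[, !empty, drop = FALSE]
    L <- ncol(g)
    if (L < 1L) stopf("no loci left after dropping empty ones")
  }
  # recode alleles locus-locally to 1..A_l
  lev <- lapply(seq_len(L), function(l) sort(unique(g[!is.na(g[, l]), l])))
  A <- vapply(lev, length, 0L)
  Amax <- max(A)
  for (l in seq_len(L)) g[, l] <- match(g[, l], lev[[l]])

  sampleNames <- rownames(g)
  if (is.null(sampleNames)) sampleNames <- sprintf("s%03d", seq_len(n))

  if (K == 1L) {
    # single-population Dirichlet-multinomial fit: Q is analytically a column
    # of ones and every allele shares one origin, so the posterior of P is a
    # fixed Dirichlet; lnpd uses the same mean - var/2 sweep estimator as
    # K > 1 so model log-probabilities are comparable across K.
    cnts <- lapply(seq_len(L), function(l) tabulate(g[, l], nbins = A[l]))
    P <- lapply(cnts, function(cnt)
      matrix((lambda + cnt) / sum(lambda + cnt), nrow = 1))
    lnls <- withSeed(seed, {
      vapply(seq_len(iters), function(sw) {
        sum(vapply(seq_len(L), function(l) {
          p <- rdirichlet1(lambda + cnts[[l]])
          pos <- cnts[[l]] > 0
          sum(cnts[[l]][pos] * log(p[pos]))
        }, 0))
      }, 0)
    })
    Q <- matrix(1, n, 1, dimnames = list(sampleNames, NULL))
    return(new("ClusterResult", K = 1L, Q = Q, P = P,
               lnpd = mean(lnls) - var(lnls) / 2, trace = lnls,
               burnin = as.integer(burnin),
               iters = as.integer(iters), alpha0 = alpha0, lambda = lambda,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               model = "haploid admixture, independent allele frequencies (K=1: single-population fit)"))
  }

  obs <- which(!is.na(g), arr.ind = TRUE)
  iIdx <- obs[, 1]; lIdx <- obs[, 2]
  aIdx <- g[obs]
  M <- length(aIdx)
  pLin <- function(z) z + K * (lIdx - 1L) + K * L * (aIdx - 1L)

  withSeed(seed, {
    z <- sample.int(K, M, replace = TRUE)
    sweeps <- burnin + iters
    sumQ <- matrix(0, n, K)
    sumP <- array(0, dim = c(K, L, Amax))
    lnls <- numeric(iters)
    alleleMask <- array(0, dim = c(K, L, Amax))
    for (l in seq_len(L)) alleleMask[, l, seq_len(A[l])] <- 1
    for (sw in seq_len(sweeps)) {
      # P | z
      cntP <- array(tabulate(pLin(z), nbins = K * L * Amax), dim = c(K, L, Amax))
      gP <- array(rgamma(K * L * Amax, shape = (lambda + cntP)), dim = c(K, L, Amax))
      gP <- gP * alleleMask
      sP <- rowSums(gP, dims = 2)
      P <- gP / as.vector(sP)[rep(seq_len(K * L), Amax)]  # broadcast over alleles
      # Q | z
      cntQ <- matrix(tabulate(iIdx + n * (z - 1L), nbins = n * K), n, K)
      Q <- rdirichletRows(alpha0 + cntQ)
      # z | P, Q
      probs <- matrix(0, M, K)
      for (k in seq_len(K))
        probs[, k] <- Q[iIdx, k] * P[k + K * (lIdx - 1L) + K * L * (aIdx - 1L)]
      tot <- rowSums(probs)
      tot[tot <= 0] <- .Machine$double.xmin
      r <- runif(M) * tot
      z <- rep(1L, M)
      cum <- probs[, 1]
      if (K > 1L) for (k in seq_len(K - 1L)) {
        z <- z + (r > cum)
        cum <- cum + probs[, k + 1L]
      }
      if (sw > burnin) {
        it <- sw - burnin
        lnls[it] <- sum(log(tot))
        sumQ <- sumQ + Q
        sumP <- sumP + P
      }
    }
    Qbar <- sumQ / iters
    Qbar <- Qbar / rowSums(Qbar)
    Pbar <- sumP / iters
    Plist <- lapply(seq_len(L), function(l) {
      pm <- matrix(Pbar[, l, seq_len(A[l])], nrow = K)
      pm / rowSums(pm)
    })
    rownames(Qbar) <- sampleNames
    lnpd <- mean(lnls) - var(lnls) / 2
    new("ClusterResult", K = as.integer(K), Q = Qbar, P = Plist, lnpd = lnpd,
        trace = lnls, burnin = as.integer(burnin), iters = as.integer(iters),
        alpha0 = alpha0, lambda = lambda,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        model = "haploid admixture, independent allele frequencies")
  })
}

#' @rdname admixtureQ
#' @export
setMethod("admixtureQ", "ClusterResult", function(x) x@Q)

#' @rdname alleleFreqP
#' @export
setMethod("alleleFreqP", "ClusterResult", function(x) x@P)

#' @rdname logProbData
#' @export
setMethod("logProbData", "ClusterResult", function(x) x@lnpd)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: K = %d, %d samples, %d loci\n",
              object@K, nrow(object@Q), length(object@P)))
  cat(sprintf("  ln P(D) = %.2f (%s)\n", object@lnpd, object@model))
})

#' Evanno delta-K model choice
#'
#' Given replicate model log-probabilities per K, computes
#' \eqn{L(K)} = mean over runs, its standard deviation, and
#' \eqn{\Delta K = |L(K+1) - 2 L(K) + L(K-1)| / \mathrm{sd}(L(K))} for
#' interior K. \eqn{\Delta K} is undefined (NA, flagged) where the
#' across-run sd is 0.
#'
#' @param lnpdRuns named list mapping K (as names, consecutive integers) to
#'   numeric vectors of per-run lnpd values (>= 2 runs per K).
#' @return data.frame of class \code{deltaKTable} with columns \code{K},
#'   \code{meanL}, \code{sdL}, \code{deltaK}; attribute \code{bestK} holds
#'   the argmax of deltaK.
#' @examples
#' evannoDeltaK(list(`1` = c(-100.2, -99.8), `2` = c(-50.4, -49.6),
#'                   `3` = c(-40.3, -39.7), `4` = c(-39.2, -38.8)))
#' @export
evannoDeltaK <- function(lnpdRuns) {
  ks <- as.integer(names(lnpdRuns))
  if (any(is.na(ks))) stopf("lnpdRuns must be named by integer K")
  o <- order(ks)
  ks <- ks[o]; lnpdRuns <- lnpdRuns[o]
  if (length(ks) < 3L || any(diff(ks) != 1L))
    stopf("need at least 3 consecutive K values")
  if (any(lengths(lnpdRuns) < 2L))
    stopf("need at least 2 runs per K for the standard deviation")
  meanL <- vapply(lnpdRuns, mean, 0)
  sdL <- vapply(lnpdRuns, sd, 0)
  deltaK <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    if (i == 1L || i == length(ks)) next
    second <- meanL[i + 1L] - 2 * meanL[i] + meanL[i - 1L]
    deltaK[i] <- if (sdL[i] > 0) abs(second) / sdL[i] else NA_real_
  }
  out <- data.frame(K = ks, meanL = unname(meanL), sdL = unname(sdL),
                    deltaK = deltaK)
  attr(out, "bestK") <- if (all(is.na(deltaK))) NA_integer_ else
    ks[which.max(deltaK)]
  class(out) <- c("deltaKTable", "data.frame")
  out
}

#' @export
print.deltaKTable <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("best K (max deltaK): %s\n", attr(x, "bestK")))
  invisible(x)
}

#' Align cluster labels across replicate runs
#'
#' Resolves label switching: clusters of each run are greedily matched to the
#' first run's Q columns, repeatedly pairing the columns with the smallest
#' summed absolute difference; the permutation is applied to both Q and P.
#'
#' @param results list of \linkS4class{ClusterResult} objects sharing K.
#' @return list of relabelled \linkS4class{ClusterResult} objects (the first
#'   is returned unchanged).
#' @export
alignClusterLabels <- function(results) {
  if (length(results) < 2L) return(results)
  K <- results[[1]]@K
  if (any(vapply(results, function(r) r@K, 0L) != K))
    stopf("all results must share K")
  ref <- results[[1]]@Q
  out <- results
  for (r in seq_along(results)[-1]) {
    Q <- results[[r]]@Q
    cost <- matrix(0, K, K)
    for (a in seq_len(K)) for (b in seq_len(K))
      cost[a, b] <- sum(abs(ref[, a] - Q[, b]))
    perm <- integer(K)       # perm[a] = column of Q matched to ref column a
    usedA <- logical(K); usedB <- logical(K)
    for (step in seq_len(K)) {
      masked <- cost
      masked[usedA, ] <- Inf; masked[, usedB] <- Inf
      idx <- arrayInd(which.min(masked), dim(masked))
      perm[idx[1]] <- idx[2]
      usedA[idx[1]] <- TRUE; usedB[idx[2]] <- TRUE
    }
    res <- results[[r]]
    res@Q <- res@Q[, perm, drop = FALSE]
    res@P <- lapply(res@P, function(pl) pl[perm, , drop = FALSE])
    out[[r]] <- res
  }
  out
}

#' Run replicate admixture fits over a K range
#'
#' Convenience driver for Evanno model choice: fits \code{runs} independent
#' chains for each K in \code{kMin:kMax} with seeds derived from
#' \code{seed}, and collects lnpd values.
#'
#' @param g genotype matrix as in \code{\link{fitAdmixture}}.
#' @param kMin,kMax K range (default 1 to 7).
#' @param runs independent runs per K (default 10).
#' @param burnin,iters,alpha0,lambda passed to \code{\link{fitAdmixture}}.
#' @param seed master seed; run r at K uses \code{seed + 1000*K + r}.
#' @return list with \code{lnpd} (named list K -> numeric vector),
#'   \code{deltaK} (from \code{\link{evannoDeltaK}}, when computable) and
#'   \code{fits} (list of lists of \linkS4class{ClusterResult}).
#' @export
admixtureKScan <- function(g, kMin = 1L, kMax = 7L, runs = 10L,
                           burnin = 5000L, iters = 20000L, alpha0 = 1,
                           lambda = 1, seed = NULL) {
  ks <- kMin:kMax
  lnpd <- setNames(vector("list", length(ks)), ks)
  fits <- setNames(vector("list", length(ks)), ks)
  for (K in ks) {
    lnpd[[as.character(K)]] <- numeric(runs)
    fits[[as.character(K)]] <- vector("list", runs)
    for (r in seq_len(runs)) {
      s <- if (is.null(seed)) NULL else seed + 1000L * K + r
      fit <- fitAdmixture(g, K, burnin = burnin, iters = iters,
                          alpha0 = alpha0, lambda = lambda, seed = s)
      lnpd[[as.character(K)]][r] <- fit@lnpd
      fits[[as.character(K)]][[r]] <- fit
    }
  }
  dk <- if (length(ks) >= 3L && runs >= 2L) evannoDeltaK(lnpd) else NULL
  list(lnpd = lnpd, deltaK = dk, fits = fits)
}

#' Read a haploid genotype table
#'
#' TSV with columns \code{sample_id}, \code{population}, then one integer
#' column per locus; missing alleles coded -9.
#'
#' @param path TSV path.
#' @return list with \code{genotypes} (integer matrix, -9 -> NA) and
#'   \code{population} (named character vector).
#' @export
readGenotypeMatrix <- function(path) {
  df <- readTsv(path)
  if (!all(c("sample_id", "population") %in% names(df)))
    stopf("genotype table needs sample_id and population columns")
  loci <- setdiff(names(df), c("sample_id", "population"))
  if (!length(loci)) stopf("genotype table has no locus columns")
  g <- as.matrix(df[, loci, drop = FALSE])
  storage.mode(g) <- "integer"
  g[g == -9L] <- NA_integer_
  rownames(g) <- df$sample_id
  list(genotypes = g, population = setNames(df$population, df$sample_id))
}

#' Write a haploid genotype table
#' @param g samples x loci integer matrix (NA written as -9).
#' @param population named character vector sample -> population.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGenotypeMatrix <- function(g, population, path) {
  gg <- g
  gg[is.na(gg)] <- -9L
  df <- data.frame(sample_id = rownames(g),
                   population = unname(population[rownames(g)]),
                   gg, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
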