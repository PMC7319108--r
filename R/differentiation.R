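#' Pons-Petit diversity and differentiation estimators
#'
#' Unordered and ordered (distance-weighted) gene-diversity estimators for
#' haploid data. With \eqn{P} populations of sizes \eqn{n_k}, harmonic mean
#' \eqn{\tilde n}, within-population frequencies \eqn{p_{ki}} and unweighted
#' mean frequencies \eqn{\bar p_i}:
#' \deqn{h_k = \frac{n_k}{n_k - 1}\left(1 - \sum_i p_{ki}^2\right),\quad
#'       H_S = \frac{1}{P}\sum_k h_k,\quad
#'       H_T = 1 - \sum_i \bar p_i^2 + \frac{H_S}{\tilde n P},\quad
#'       G_{ST} = 1 - H_S/H_T.}
#' The ordered analogues replace \eqn{1 - \sum p^2} by
#' \eqn{\sum_{i \ne j} p_i p_j d_{ij}} with the same unbiased and total
#' corrections, giving \eqn{v_S}, \eqn{v_T} and
#' \eqn{N_{ST} = 1 - v_S/v_T}. When all inter-haplotype distances are equal,
#' \eqn{N_{ST} = G_{ST}} exactly; \eqn{N_{ST} > G_{ST}} indicates
#' phylogeographic structure.
#'
#' @param counts haplotype x population count matrix.
#' @param dists symmetric haplotype step-distance matrix (rows/cols follow
#'   \code{counts} rows).
#' @return list of class \code{permutDiversity} with \code{Hs}, \code{Ht},
#'   \code{Gst}, \code{vS}, \code{vT}, \code{Nst}, \code{perPopulation}
#'   (vector of \eqn{h_k}) and bookkeeping fields.
#' @export
permutDiversity <- function(counts, dists) {
  counts <- as.matrix(counts)
  nk <- colSums(counts)
  drop <- nk < 2
  if (any(drop)) {
    warnf("excluding population(s) with n < 2: %s",
          paste(colnames(counts)[drop], collapse = ", "))
    counts <- counts[, !drop, drop = FALSE]
    nk <- nk[!drop]
  }
  P <- ncol(counts)
  if (P < 2L) stopf("need at least 2 populations with n >= 2")
  if (nrow(dists) != nrow(counts))
    stopf("dists must have one row per haplotype")
  freq <- sweep(counts, 2, nk, "/")
  hk <- (nk / (nk - 1)) * (1 - colSums(freq^2))
  Hs <- mean(hk)
  pbar <- rowMeans(freq)
  ntilde <- 1 / mean(1 / nk)
  Ht <- 1 - sum(pbar^2) + Hs / (ntilde * P)

  quad <- function(p) as.numeric(t(p) %*% dists %*% p)  # sum_{i!=j} pi pj dij
  vk <- (nk / (nk - 1)) * apply(freq, 2, quad)
  vS <- mean(vk)
  vT <- quad(pbar) + vS / (ntilde * P)

  Gst <- if (abs(Ht) < 1e-12) { warnf("Ht is 0 (monomorphic): Gst undefined"); NA_real_ } else 1 - Hs / Ht
  Nst <- if (abs(vT) < 1e-12) NA_real_ else 1 - vS / vT
  structure(list(Hs = Hs, Ht = Ht, Gst = Gst, vS = vS, vT = vT, Nst = Nst,
                 perPopulation = setNames(hk, colnames(counts)),
                 nPopulations = P, nTilde = ntilde),
            class = "permutDiversity")
}

#' @export
print.permutDiversity <- function(x, ...) {
  cat(sprintf("Pons-Petit estimators over %d populations\n", x$nPopulations))
  cat(sprintf("  Hs = %.3f  Ht = %.3f  Gst = %.3f\n", x$Hs, x$Ht, x$Gst))
  cat(sprintf("  vS = %.3f  vT = %.3f  Nst = %.3f\n", x$vS, x$vT, x$Nst))
  invisible(x)
}

#' Permutation test for phylogeographic structure (Nst > Gst)
#'
#' Builds the null distribution of \eqn{N_{ST} - G_{ST}} by shuffling
#' haplotype identities on the distance matrix (permuting rows/columns
#' jointly), which preserves the frequency structure while destroying any
#' association between genealogical distance and geography. The p-value uses
#' the add-one convention \eqn{(1 + x)/(1 + n_{perm})}.
#'
#' @param counts haplotype x population count matrix.
#' @param dists haplotype step-distance matrix.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{observed} (Nst - Gst), \code{p}, \code{nPerm}.
#' @export
testNstGtGst <- function(counts, dists, nPerm = 1000L, seed = NULL) {
  if (nrow(as.matrix(counts)) < 2L) stopf("test undefined for fewer than 2 haplotypes")
  obs <- permutDiversity(counts, dists)
  if (is.na(obs$Nst) || is.na(obs$Gst)) stopf("Nst or Gst undefined on these data")
  stat <- obs$Nst - obs$Gst
  nh <- nrow(dists)
  withSeed(seed, {
    hits <- 0L
    for (b in seq_len(nPerm)) {
      idx <- sample.int(nh)
      perm <- suppressWarnings(permutDiversity(counts, dists[idx, idx]))
      if (!is.na(perm$Nst) && (perm$Nst - perm$Gst) >= stat - 1e-12)
        hits <- hits + 1L
    }
    list(observed = stat, p = (1 + hits) / (nPerm + 1), nPerm = nPerm)
  })
}

# SSD of a set of index groups: sum over groups of (1/n_g) sum_{i<j in g} d2.
ssdWithin <- function(d2, groups) {
  sum(vapply(groups, function(idx) {
    if (length(idx) < 2L) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
}

amovaComponents <- function(d2, pop, grp = NULL) {
  N <- nrow(d2)
  pops <- split(seq_len(N), pop)
  P <- length(pops)
  nk <- lengths(pops)
  SSD_T <- sum(d2[upper.tri(d2)]) / N
  SSD_WP <- ssdWithin(d2, pops)
  if (is.null(grp)) {
    SSD_AP <- SSD_T - SSD_WP
    dfAP <- P - 1L; dfWP <- N - P
    MS_AP <- SSD_AP / dfAP; MS_WP <- SSD_WP / dfWP
    nprime <- (N - sum(nk^2) / N) / (P - 1)
    s2c <- MS_WP
    s2a <- (MS_AP - MS_WP) / nprime
    tot <- s2a + s2c
    list(table = data.frame(
           source = c("Among populations", "Within populations", "Total"),
           df = c(dfAP, dfWP, dfAP + dfWP),
           SS = c(SSD_AP, SSD_WP, SSD_T),
           sigma2 = c(s2a, s2c, tot),
           pct = 100 * c(s2a, s2c, tot) / tot),
         phi = c(PhiST = if (abs(tot) < 1e-15) NA_real_ else s2a / tot))
  } else {
    groups <- split(seq_len(N), grp)
    G <- length(groups)
    Ng <- lengths(groups)
    SSD_WG <- ssdWithin(d2, groups)
    SSD_AG <- SSD_T - SSD_WG
    SSD_APWG <- SSD_WG - SSD_WP
    dfAG <- G - 1L; dfAP <- P - G; dfWP <- N - P
    MS_AG <- SSD_AG / dfAG; MS_AP <- SSD_APWG / dfAP; MS_WP <- SSD_WP / dfWP
    grpOfPop <- vapply(names(pops), function(p) as.character(grp[pops[[p]][1]]), "")
    Sg <- vapply(names(groups), function(g) {
      k <- nk[grpOfPop == g]
      sum(k^2) / sum(k)
    }, 0)
    nprime <- (N - sum(Sg)) / (P - G)
    n2prime <- (sum(Sg) - sum(nk^2) / N) / (G - 1)
    n3prime <- (N - sum(Ng^2) / N) / (G - 1)
    s2c <- MS_WP
    s2b <- (MS_AP - s2c) / nprime
    s2a <- (MS_AG - s2c - n2prime * s2b) / n3prime
    tot <- s2a + s2b + s2c
    und <- abs(tot) < 1e-15
    list(table = data.frame(
           source = c("Among groups", "Among populations within groups",
                      "Within populations", "Total"),
           df = c(dfAG, dfAP, dfWP, dfAG + dfAP + dfWP),
           SS = c(SSD_AG, SSD_APWG, SSD_WP, SSD_T),
           sigma2 = c(s2a, s2b, s2c, tot),
           pct = 100 * c(s2a, s2b, s2c, tot) / tot),
         phi = c(PhiCT = if (und) NA_real_ else s2a / tot,
                 PhiSC = if (und || abs(s2b + s2c) < 1e-15) NA_real_ else s2b / (s2b + s2c),
                 PhiST = if (und) NA_real_ else (s2a + s2b) / tot))
  }
}

#' Analysis of molecular variance (AMOVA) with Phi-statistics
#'
#' Partitions squared inter-sample distances among hierarchical strata in
#' the Excoffier-Weir-Cockerham framework. One level (populations):
#' \eqn{SSD_T = \frac{1}{N}\sum_{i<j}\delta^2_{ij}},
#' \eqn{SSD_{WP} = \sum_k \frac{1}{n_k}\sum_{i<j \in k}\delta^2_{ij}},
#' variance components from the mean squares with
#' \eqn{n' = (N - \sum n_k^2/N)/(P-1)}, and
#' \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_c)}. With groups, the
#' two-level decomposition with the standard unbalanced-design coefficients
#' yields \eqn{\Phi_{CT}}, \eqn{\Phi_{SC}} and \eqn{\Phi_{ST}}. Significance
#' is assessed by permutation: samples among populations for
#' \eqn{\Phi_{ST}}, samples among populations within groups for
#' \eqn{\Phi_{SC}}, and whole populations among groups for \eqn{\Phi_{CT}}.
#' Negative variance components are reported as computed.
#'
#' @param d sample x sample step-distance matrix (row/col names are sample
#'   ids).
#' @param populations named character vector sample id -> population.
#' @param groups optional named character vector population -> group.
#' @param nPerm permutations for p-values (default 1000); 0 skips testing.
#' @param seed integer seed (one master seed; the Phi_ST, Phi_SC and
#'   Phi_CT tests use derived streams).
#' @param squared when TRUE (default) the input distances are squared to
#'   Excoffier's \eqn{\delta^2}; set FALSE to use them as-is.
#' @return list of class \code{amovaResult} with \code{table} (source, df,
#'   SS, variance component, percent of total), \code{phi} (named fixation
#'   indices) and \code{p} (named permutation p-values).
#' @export
amova <- function(d, populations, groups = NULL, nPerm = 1000L, seed = NULL,
                  squared = TRUE) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stopf("distance matrix needs sample ids as dimnames")
  if (!all(ids %in% names(populations)))
    stopf("every sample needs a population assignment")
  pop <- as.character(populations[ids])
  N <- length(ids)
  if (N < 3L) stopf("AMOVA needs at least 3 samples")
  if (any(table(pop) == 0L)) stopf("empty population")
  grp <- NULL
  if (!is.null(groups)) {
    if (!all(pop %in% names(groups)))
      stopf("every population needs a group assignment")
    grp <- as.character(groups[pop])
    if (length(unique(grp)) < 2L)
      grp <- NULL                      # G = 1 reduces to the one-level design
  }
  d2 <- if (squared) d^2 else d
  obs <- amovaComponents(d2, pop, grp)

  pvals <- setNames(rep(NA_real_, length(obs$phi)), names(obs$phi))
  if (nPerm > 0L && !all(is.na(obs$phi))) {
    statST <- obs$phi[["PhiST"]]
    grpOfPopMap <- if (is.null(grp)) NULL else
      setNames(vapply(unique(pop), function(p) grp[match(p, pop)], ""), unique(pop))
    withSeed(if (is.null(seed)) NULL else seed + 1L, {
      hits <- 0L
      for (b in seq_len(nPerm)) {
        popPerm <- sample(pop)
        grpPerm <- if (is.null(grp)) NULL else
          as.character(grpOfPopMap[popPerm])
        perm <- amovaComponents(d2, popPerm, grpPerm)
        if (!is.na(perm$phi[["PhiST"]]) && perm$phi[["PhiST"]] >= statST - 1e-12)
          hits <- hits + 1L
      }
      pvals["PhiST"] <- (1 + hits) / (nPerm + 1)
    })
    if (!is.null(grp)) {
      statSC <- obs$phi[["PhiSC"]]
      withSeed(if (is.null(seed)) NULL else seed + 2L, {
        hits <- 0L
        for (b in seq_len(nPerm)) {
          popPerm <- pop
          for (g in unique(grp)) {
            idx <- which(grp == g)
            popPerm[idx] <- sample(pop[idx])
          }
          perm <- amovaComponents(d2, popPerm, grp)
          if (!is.na(perm$phi[["PhiSC"]]) && perm$phi[["PhiSC"]] >= statSC - 1e-12)
            hits <- hits + 1L
        }
        pvals["PhiSC"] <- (1 + hits) / (nPerm + 1)
      })
      statCT <- obs$phi[["PhiCT"]]
      popNames <- unique(pop)
      grpOfPop <- vapply(popNames, function(p) grp[match(p, pop)], "")
      withSeed(if (is.null(seed)) NULL else seed + 3L, {
        hits <- 0L
        for (b in seq_len(nPerm)) {
          permAssign <- setNames(sample(grpOfPop), popNames)
          perm <- amovaComponents(d2, pop, as.character(permAssign[pop]))
          if (!is.na(perm$phi[["PhiCT"]]) && perm$phi[["PhiCT"]] >= statCT - 1e-12)
            hits <- hits + 1L
        }
        pvals["PhiCT"] <- (1 + hits) / (nPerm + 1)
      })
    }
  }
  structure(list(table = obs$table, phi = obs$phi, p = pvals,
                 nPerm = nPerm, squared = squared),
            class = "amovaResult")
}

#' @export
print.amovaResult <- function(x, ...) {
  cat("AMOVA\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$sigma2 <- round(tab$sigma2, 5)
  tab$pct <- round(tab$pct, 2)
  print(tab, row.names = FALSE)
  for (nm in names(x$phi))
    cat(sprintf("  %s = %.4f%s\n", nm, x$phi[[nm]],
                if (!is.na(x$p[[nm]])) sprintf(" (p = %.4g)", x$p[[nm]]) else ""))
  invisible(x)
}

#' Sample-level step distances from a haplotype table
#'
#' Expands inter-haplotype mutational step distances to a sample x sample
#' matrix, the natural AMOVA input for haplotype sequence data.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @return symmetric matrix with sample ids as dimnames.
#' @export
sampleStepDistances <- function(table) {
  stopifnot(is(table, "HaplotypeTable"))
  hd <- stepDistances(table)
  hap <- haplotypeOf(table)
  idx <- match(hap, rownames(hd))
  out <- hd[idx, idx]
  dimnames(out) <- list(names(hap), names(hap))
  out
}
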