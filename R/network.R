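#' @importFrom igraph graph_from_data_frame is_connected distances degree
NULL

#' Minimum spanning network over a haplotype distance matrix
#'
#' The union of all minimum spanning trees, optionally relaxed: an edge
#' (i, j) belongs to the network when its distance does not exceed the
#' single-linkage merge threshold of i and j plus \code{epsilon}. With
#' \code{epsilon = 0} and a unique MST the network is exactly that MST; tied
#' alternatives are all retained.
#'
#' @param dists symmetric distance matrix with node names as dimnames.
#' @param epsilon relaxation in mutational steps (default 0).
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
minimumSpanningNetwork <- function(dists, epsilon = 0) {
  d <- as.matrix(dists)
  n <- nrow(d)
  if (n < 2L) stopf("need at least 2 haplotypes")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("H", seq_len(n))
  if (n == 2L)
    return(data.frame(from = rownames(d)[1], to = rownames(d)[2],
                      weight = d[1, 2], stringsAsFactors = FALSE))
  hc <- hclust(as.dist(d), method = "single")
  merge <- as.matrix(cophenetic(hc))
  merge <- merge[rownames(d), rownames(d)]
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] <= merge[i, j] + epsilon + 1e-12)
      out[[length(out) + 1L]] <- data.frame(
        from = rownames(d)[i], to = rownames(d)[j], weight = d[i, j],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# total weight of one minimum spanning tree = sum of single-linkage heights
mstCost <- function(d) {
  if (nrow(d) < 2L) return(0)
  sum(hclust(as.dist(d), method = "single")$height)
}

# hamming distances over a character state matrix (NA-tolerant)
stateDistances <- function(states) {
  n <- nrow(states)
  d <- matrix(0, n, n, dimnames = list(rownames(states), rownames(states)))
  if (n >= 2L && ncol(states))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(states[i, ]) & !is.na(states[j, ])
      d[i, j] <- d[j, i] <- sum(states[i, ok] != states[j, ok])
    }
  d
}

# per-character majority state of a connected triplet; when all three states
# differ the state of the lowest-ordered node (u) is kept.
tripletMedian <- function(u, v, w) {
  vapply(seq_along(u), function(c) {
    s <- c(u[c], v[c], w[c])
    if (all(is.na(s))) return(NA_character_)
    s2 <- s[!is.na(s)]
    tab <- table(s2)
    if (max(tab) >= 2L) return(names(tab)[which.max(tab)])
    if (!is.na(s[1])) s[1] else s2[1]
  }, "")
}

#' Median-joining haplotype network
#'
#' Builds a maximum-parsimony haplotype network in the median-joining
#' framework: iteratively construct the (epsilon-relaxed) minimum spanning
#' network over the current node set, generate the per-character majority
#' median of every connected triplet, add the median that most reduces the
#' spanning cost of the node set, and repeat to a fixpoint; finally remove
#' median vectors that lie on no shortest path between observed haplotypes.
#' All characters (substitution columns and binary indel-event characters)
#' carry equal weight, matching the one-indel-one-step convention.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param epsilon MSN relaxation in steps (default 0).
#' @param maxMedians cap on added median vectors (default 10000).
#' @return a \linkS4class{HaplotypeNetwork}; observed-node frequencies carry
#'   the haplotype sample counts.
#' @export
medianJoiningNetwork <- function(table, epsilon = 0, maxMedians = 10000L) {
  stopifnot(is(table, "HaplotypeTable"))
  states <- table@signatures
  nObs <- nrow(states)
  if (nObs < 2L) stopf("need at least 2 haplotypes")
  rownames(states) <- rownames(table@counts)
  medCount <- 0L
  repeat {
    d <- stateDistances(states)
    cost <- mstCost(d)
    msn <- minimumSpanningNetwork(d, epsilon)
    adj <- lapply(rownames(states), function(v)
      unique(c(msn$to[msn$from == v], msn$from[msn$to == v])))
    names(adj) <- rownames(states)
    cand <- list()
    for (v in rownames(states)) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
        trip <- sort(match(c(nb[a], v, nb[b]), rownames(states)))
        m <- tripletMedian(states[trip[1], ], states[trip[2], ], states[trip[3], ])
        cand[[paste(ifelse(is.na(m), "?", m), collapse = "\r")]] <- m
      }
    }
    if (length(cand)) {
      existing <- apply(states, 1, function(s)
        paste(ifelse(is.na(s), "?", s), collapse = "\r"))
      cand <- cand[setdiff(names(cand), existing)]
    }
    if (!length(cand) || medCount >= maxMedians) break
    best <- NULL; bestCost <- cost - 1e-9
    for (key in sort(names(cand))) {
      trial <- rbind(states, cand[[key]])
      tc <- mstCost(stateDistances(trial))
      if (tc < bestCost) { bestCost <- tc; best <- cand[[key]] }
    }
    if (is.null(best)) break
    medCount <- medCount + 1L
    states <- rbind(states, best)
    rownames(states)[nrow(states)] <- paste0("M", medCount)
  }

  # obsolete-median removal: keep medians on a shortest observed-observed path
  obsIds <- rownames(table@counts)
  repeat {
    d <- stateDistances(states)
    msn <- minimumSpanningNetwork(d, epsilon)
    g <- igraph::graph_from_data_frame(msn, directed = FALSE,
                                       vertices = rownames(states))
    D <- igraph::distances(g, weights = igraph::E(g)$weight)
    medIds <- setdiff(rownames(states), obsIds)
    dropIds <- character()
    for (m in medIds) {
      onPath <- FALSE
      for (a in obsIds) {
        for (b in obsIds) {
          if (a >= b) next
          if (abs(D[a, m] + D[m, b] - D[a, b]) < 1e-9 &&
              D[a, m] > 1e-9 && D[m, b] > 1e-9) { onPath <- TRUE; break }
        }
        if (onPath) break
      }
      if (!onPath) dropIds <- c(dropIds, m)
    }
    if (!length(dropIds)) break
    states <- states[setdiff(rownames(states), dropIds), , drop = FALSE]
  }

  d <- stateDistances(states)
  msn <- minimumSpanningNetwork(d, epsilon)
  freq <- rowSums(table@counts)
  nodes <- data.frame(id = rownames(states),
                      kind = ifelse(rownames(states) %in% obsIds,
                                    "observed", "median"),
                      frequency = ifelse(rownames(states) %in% obsIds,
                                         freq[rownames(states)], NA_real_),
                      stringsAsFactors = FALSE)
  new("HaplotypeNetwork", nodes = nodes, edges = msn, states = states,
      epsilon = epsilon)
}

setMethod("show", "HaplotypeNetwork", function(object) {
  cat(sprintf("HaplotypeNetwork: %d observed + %d median nodes, %d edges (epsilon = %g)\n",
              sum(object@nodes$kind == "observed"),
              sum(object@nodes$kind == "median"),
              nrow(object@edges), object@epsilon))
  cat(sprintf("  total edge length %g steps\n", sum(object@edges$weight)))
})

#' Total spanning cost of a network's node set
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @return minimum spanning tree weight over the node states.
#' @export
networkCost <- function(net) mstCost(stateDistances(net@states))

#' Write a haplotype network to JSON
#'
#' Nodes carry id, kind (observed/median) and observed frequency; edges carry
#' endpoint ids and mutational-step weights.
#'
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeNetworkJson <- function(net, path) {
  jsonlite::write_json(
    list(epsilon = net@epsilon, nodes = net@nodes, edges = net@edges),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
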