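#' @importFrom stats cor cophenetic hclust as.dist pt rgamma runif rpois var sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed so library calls never perturb a
# surrounding simulation stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}

# One draw from Dirichlet(alpha); guards against all-zero gamma underflow.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) {
    out <- numeric(length(alpha))
    out[which.max(alpha)] <- 1
    return(out)
  }
  g / s
}

# Row-wise Dirichlet draws for a matrix of concentration parameters.
rdirichletRows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  s <- rowSums(g)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    for (i in which(bad)) {
      g[i, ] <- 0
      g[i, which.max(alpha[i, ])] <- 1
    }
    s <- rowSums(g)
  }
  g / s
}

DNA_BASES4 <- c("A", "C", "G", "T")

reverseComplementChars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  rev(unname(comp[chars]))
}

#' Write a TSV result table with a provenance header
#'
#' All tabular artifacts share one dialect: tab-separated values preceded by
#' `#`-prefixed comment lines carrying the tool version, the coordinate
#' convention (1-based, closed intervals over alignment columns) and the
#' parameters and seed of the run.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param params named list of parameters echoed into the header.
#' @param seed integer seed echoed into the header, or NULL.
#' @return `path`, invisibly.
#' @export
writeTsvWithHeader <- function(df, path, params = list(), seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# plastomark %s", as.character(packageVersion("plastomark"))), con)
  writeLines("# coordinates: 1-based, closed intervals over alignment columns", con)
  if (!is.null(seed)) params$seed <- seed
  for (nm in names(params))
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV artifact written by this package
#'
#' @param path file path.
#' @return data.frame (comment lines skipped).
#' @export
readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, check.names = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
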