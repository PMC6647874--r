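# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package: naive enumeration and
# textbook dynamic programming only.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# exhaustive enumeration of every (start, spacer) assignment of a
# fixed-spacer-fixed motif against a region, symbol by symbol
oracle_scan <- function(region, elements, min_dist, max_dist,
                        max_mismatch = 0L) {
  # elements: list of list(seq=) for fixed or list(min=,max=) for spacer
  rchars <- strsplit(toupper(region), "")[[1]]
  n <- length(rchars)
  spacer_idx <- which(vapply(elements, function(e) is.null(e$seq), TRUE))
  stopifnot(length(spacer_idx) == 1L)
  sp <- elements[[spacer_idx]]
  hits <- NULL
  for (spacer_len in sp$min:sp$max) {
    symbols <- character(); is_spacer <- logical(); elem <- integer()
    for (i in seq_along(elements)) {
      el <- elements[[i]]
      s <- if (is.null(el$seq)) rep("N", spacer_len) else
        strsplit(toupper(el$seq), "")[[1]]
      symbols <- c(symbols, s)
      is_spacer <- c(is_spacer, rep(is.null(el$seq), length(s)))
      elem <- c(elem, rep(i, length(s)))
    }
    span <- length(symbols)
    if (span > n) next
    for (start in 1:(n - span + 1L)) {
      ok <- TRUE
      mm <- integer(length(elements))
      for (t in seq_len(span)) {
        b <- rchars[start + t - 1L]
        match_t <- b %in% c("A", "C", "G", "T") &&
          b %in% ORACLE_IUPAC[[symbols[t]]]
        if (!match_t) {
          if (is_spacer[t]) { ok <- FALSE; break }
          mm[elem[t]] <- mm[elem[t]] + 1L
          if (mm[elem[t]] > max_mismatch) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      gd <- n - (start + span - 1L)
      if (gd < min_dist || gd > max_dist) next
      hits <- rbind(hits, data.frame(match_start = start,
                                     match_end = start + span - 1L,
                                     spacer_len = spacer_len,
                                     gene_distance = gd))
    }
  }
  if (is.null(hits)) {
    return(data.frame(match_start = integer(), match_end = integer(),
                      spacer_len = integer(), gene_distance = integer()))
  }
  hits <- hits[order(hits$match_start, hits$spacer_len), ]
  rownames(hits) <- NULL
  hits
}

hrp_elements <- list(list(seq = "NGGAACN"), list(min = 15L, max = 16L),
                     list(seq = "CCACNNAG"))

# Gotoh affine-gap local alignment, scores only. A gap of length L costs
# open + (L - 1) * extend.
oracle_sw <- function(a, b, submat, open, extend) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in y (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)   # gap in x (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[x[i - 1], y[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - open, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open, Iy[i, j - 1] - extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

random_aa <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

random_dna_string <- function(n, with_n = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# random additive tree and its exact path-length distance matrix
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  tr$tip.label <- sort(tr$tip.label)
  tr
}

blosum <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}
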