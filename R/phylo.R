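# phylo: distance-based phylogenetics. K80 distances for nucleotide
# alignments, Jukes-Cantor-corrected distances for protein alignments,
# neighbor joining with deterministic tie-breaking, nonparametric bootstrap,
# Newick output. Trees are ape "phylo" objects throughout.

#' Construct a multiple sequence alignment object
#'
#' @param seqs named character vector of equal-length aligned sequences with
#'   `-` as the gap symbol; names are taxon labels and must be unique
#' @param type `"dna"`, `"protein"`, or `"auto"` (guessed from the alphabet)
#' @return an object of class `msa` with fields `taxa`, `seqs`, `type`,
#'   `length`
#' @export
msa <- function(seqs, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 2)
  if (anyDuplicated(names(seqs))) stopf("duplicated taxon labels")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stopf("aligned rows have unequal lengths")
  seqs <- toupper(seqs)
  if (type == "auto") {
    symbols <- unique(chars(paste(seqs, collapse = "")))
    type <- if (all(symbols %in% c(DNA_BASES, "N", "-"))) "dna" else "protein"
  }
  structure(list(taxa = names(seqs), seqs = seqs, type = type,
                 length = lens[1]), class = "msa")
}

#' Read an aligned multi-FASTA file
#' @param path FASTA file of pre-aligned sequences
#' @inheritParams msa
#' @return an [msa()]
#' @export
read_alignment <- function(path, type = c("auto", "dna", "protein")) {
  ss <- Biostrings::readBStringSet(path)
  msa(setNames(as.character(ss), sub("\\s.*$", "", names(ss))),
      type = match.arg(type))
}

# columns usable for a pair: concrete symbols on both rows
comparable_dna <- function(x, y) x %in% DNA_BASES & y %in% DNA_BASES
comparable_aa <- function(x, y) x %in% AA_STANDARD & y %in% AA_STANDARD

#' Kimura-80 (two-parameter) nucleotide distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion fraction over comparable columns. Gap and ambiguous
#' (`N`) columns are pairwise-deleted. When the log argument is not
#' positive the pair is saturated: the distance is flagged `Inf` with a
#' warning.
#'
#' @param a,b aligned nucleotide strings of equal length
#' @return distance in substitutions/site (`Inf` when saturated)
#' @export
k80_distance <- function(a, b) {
  x <- chars(toupper(a)); y <- chars(toupper(b))
  if (length(x) != length(y)) stopf("aligned rows have unequal lengths")
  keep <- comparable_dna(x, y)
  n <- sum(keep)
  if (n == 0L) stopf("no comparable (non-gap, non-N) columns")
  x <- x[keep]; y <- y[keep]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K80 distance saturated (log argument <= 0); returning Inf",
            call. = FALSE)
    return(Inf)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Jukes-Cantor-corrected protein distance
#'
#' `d = -(19/20) log(1 - 20 p / 19)` with `p` the mismatch fraction over
#' comparable columns (pairwise deletion of gaps and non-standard symbols).
#' Saturated pairs (`p >= 19/20`) are flagged `Inf` with a warning.
#'
#' @param a,b aligned amino-acid strings of equal length
#' @return distance in substitutions/site (`Inf` when saturated)
#' @export
jc_protein_distance <- function(a, b) {
  x <- chars(toupper(a)); y <- chars(toupper(b))
  if (length(x) != length(y)) stopf("aligned rows have unequal lengths")
  keep <- comparable_aa(x, y)
  n <- sum(keep)
  if (n == 0L) stopf("no comparable (non-gap) columns")
  p <- sum(x[keep] != y[keep]) / n
  if (p >= 19 / 20) {
    warning("JC protein distance saturated (p >= 19/20); returning Inf",
            call. = FALSE)
    return(Inf)
  }
  -(19 / 20) * log(1 - 20 * p / 19)
}

#' Pairwise distance matrix of an alignment
#'
#' @param x an [msa()]
#' @param model `"k80"` (nucleotide) or `"jc_protein"`
#' @param deletion `"pairwise"` (default: drop gap/ambiguous columns per
#'   pair) or `"complete"` (drop every column containing any gap or
#'   ambiguous symbol once, for the whole alignment)
#' @return symmetric matrix with zero diagonal; saturated entries are `Inf`
#'   and flagged in `attr(, "saturated")`
#' @export
distance_matrix <- function(x, model = c("k80", "jc_protein"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  seqs <- x$seqs
  if (deletion == "complete") {
    m <- do.call(rbind, strsplit(seqs, ""))
    okfun <- if (model == "k80") function(col) all(col %in% DNA_BASES)
             else function(col) all(col %in% AA_STANDARD)
    keep <- apply(m, 2, okfun)
    if (!any(keep)) stopf("complete deletion removed every column")
    seqs <- setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                     names(seqs))
  }
  dfun <- if (model == "k80") k80_distance else jc_protein_distance
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(x$taxa, x$taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- suppressWarnings(dfun(seqs[[i]], seqs[[j]]))
  }
  attr(d, "saturated") <- !is.finite(d) & row(d) != col(d)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest pair of
#' cluster representatives (the smallest original taxon label in each
#' cluster). Negative branch lengths are clamped to zero
#' (Kuhner-Felsenstein convention); the clamped deficits are recorded in
#' `attr(, "clamped")`.
#'
#' @param D symmetric distance matrix with taxon dimnames (e.g. from
#'   [distance_matrix()]), at least 3 taxa, all entries finite
#' @return an unrooted `ape::phylo` tree with branch lengths in
#'   substitutions/site
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stopf("D must be a square matrix")
  taxa <- rownames(D)
  if (is.null(taxa) || anyDuplicated(taxa)) stopf("D needs unique taxon dimnames")
  if (nrow(D) < 3L) stopf("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(D))) stopf("non-finite distances (saturated pairs?) in D")
  if (max(abs(D - t(D))) > 1e-8) stopf("D is not symmetric")
  if (any(diag(D) != 0)) stopf("D has a nonzero diagonal")

  clamped <- list()
  clamp <- function(len, desc) {
    if (len < 0) {
      clamped[[length(clamped) + 1L]] <<- data.frame(branch = desc,
                                                     deficit = -len)
      0
    } else len
  }
  # cluster state: newick fragment and representative label per active node
  frag <- setNames(quote_newick_labels(taxa), taxa)
  rep_label <- setNames(taxa, taxa)
  active <- taxa
  d <- D

  while (length(active) > 3L) {
    n <- length(active)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_label[active[ij[1]]], rep_label[active[ij[2]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    fi <- active[i]; fj <- active[j]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- clamp(li, rep_label[fi]); lj <- clamp(lj, rep_label[fj])
    new_id <- paste0("(", fi, ",", fj, ")")
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[fi], fmt_len(li),
                        frag[fj], fmt_len(lj))
    new_rep <- min(rep_label[fi], rep_label[fj])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dk[-c(i, j)]), c(dk[-c(i, j)], 0))
    active <- c(active[-c(i, j)], new_id)
    rownames(d) <- colnames(d) <- active
    frag[new_id] <- new_frag
    rep_label[new_id] <- new_rep
  }
  # final three clusters joined at the central node (three-point formulas)
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- clamp(la, rep_label[a]); lb <- clamp(lb, rep_label[b])
  lc <- clamp(lc, rep_label[c3])
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt_len(la),
                 frag[b], fmt_len(lb), frag[c3], fmt_len(lc))
  tree <- read_newick(text = nwk)
  attr(tree, "clamped") <- if (length(clamped)) do.call(rbind, clamped) else
    data.frame(branch = character(), deficit = numeric())
  tree
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Nonparametric bootstrap supports for a neighbor-joining tree
#'
#' Builds the NJ tree of the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilds an NJ tree per
#' replicate, and reports for each internal bipartition of the original
#' tree the percentage of successful replicates containing it. Replicates
#' in which any pairwise distance saturates are skipped and counted;
#' supports are percentages of the non-skipped replicates.
#'
#' @param x an [msa()]
#' @param n_replicates number of bootstrap replicates (>= 1)
#' @param model `"k80"` or `"jc_protein"` (see [distance_matrix()])
#' @param seed integer seed; the run is fully determined by it
#' @param deletion passed to [distance_matrix()]
#' @return list with `tree` (the original-data NJ tree, `node.label` set to
#'   integer percent supports, `""` on trivial nodes), `support` (table of
#'   bipartitions with raw counts and fractions), `n_replicates`,
#'   `n_skipped`
#' @export
bootstrap_support <- function(x, n_replicates = 1000L,
                              model = c("k80", "jc_protein"), seed,
                              deletion = c("pairwise", "complete")) {
  stopifnot(n_replicates >= 1L)
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (missing(seed)) stopf("a seed is mandatory for bootstrap runs")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  tree <- neighbor_joining(distance_matrix(x, model, deletion))
  bip <- tree_bipartitions(tree)      # node id -> canonical key (non-trivial)
  counts <- setNames(integer(length(bip)), unlist(bip))
  rows <- do.call(rbind, strsplit(x$seqs, ""))
  n_skipped <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(rows), ncol(rows), replace = TRUE)
    rep_seqs <- setNames(apply(rows[, cols, drop = FALSE], 1, paste,
                               collapse = ""), x$taxa)
    rep_msa <- structure(list(taxa = x$taxa, seqs = rep_seqs, type = x$type,
                              length = length(cols)), class = "msa")
    d <- tryCatch(distance_matrix(rep_msa, model, deletion),
                  error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) { n_skipped <- n_skipped + 1L; next }
    rep_tree <- neighbor_joining(d)
    seen <- unique(unlist(tree_bipartitions(rep_tree)))
    hit <- names(counts) %in% seen
    counts[hit] <- counts[hit] + 1L
  }
  n_ok <- n_replicates - n_skipped
  frac <- if (n_ok > 0) counts / n_ok else counts * NA_real_
  # write supports onto the original tree's internal nodes
  n_tip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  for (node in as.integer(names(bip))) {
    labels[node - n_tip] <- as.character(round(100 * frac[[bip[[as.character(node)]]]]))
  }
  tree$node.label <- labels
  support <- data.frame(bipartition = gsub("\r", "|", names(counts)),
                        count = as.integer(counts), fraction = as.numeric(frac),
                        support = round(100 * as.numeric(frac)),
                        stringsAsFactors = FALSE)
  list(tree = tree, support = support, n_replicates = n_replicates,
       n_skipped = n_skipped)
}

# canonical keys for the non-trivial bipartitions of an (unrooted) tree:
# named list, node id -> key. The side not containing the overall smallest
# taxon label is sorted and joined; invariant to taxon order.
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  clade <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade))
  }
  anchor <- min(tree$tip.label)
  out <- list()
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    if (node == root) next
    side <- clade(node)
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    out[[as.character(node)]] <- paste(sort(side), collapse = "\r")
  }
  out
}

# ---- Newick serialization ---------------------------------------------------

quote_newick_labels <- function(labels) {
  needs <- grepl("[],[(): ;'\t\n]", labels)
  labels[needs] <- paste0("'", gsub("'", "''", labels[needs]), "'")
  labels
}

unquote_newick_label <- function(label) {
  quoted <- grepl("^'.*'$", label)
  label[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", label[quoted]))
  label
}

#' Write a tree as Newick
#'
#' Standard Newick with branch lengths and (when present) internal node
#' labels such as integer bootstrap supports. Labels containing Newick
#' metacharacters (commas, colons, parentheses, spaces) are single-quoted.
#'
#' @param tree an `ape::phylo` object
#' @param path output file, or `NULL` to return the string
#' @return the Newick string, invisibly when written to a file
#' @export
write_newick <- function(tree, path = NULL) {
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lens <- tree$edge.length
  node_lab <- tree$node.label %||% rep("", tree$Nnode)
  ser <- function(node, edge_idx) {
    lab <- if (node <= n_tip) quote_newick_labels(tree$tip.label[node]) else {
      inner <- vapply(kids[[as.character(node)]],
                      function(e) ser(tree$edge[e, 2], e), character(1))
      lab0 <- node_lab[node - n_tip]
      paste0("(", paste(inner, collapse = ","), ")",
             if (nzchar(lab0)) quote_newick_labels(lab0) else "")
    }
    if (!is.null(edge_idx) && !is.null(lens)) {
      paste0(lab, ":", fmt_len(lens[edge_idx]))
    } else lab
  }
  nwk <- paste0(ser(n_tip + 1L, NULL), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Read a Newick tree
#'
#' @param path file to read, or use `text =` for an in-memory string
#' @param text Newick string
#' @return an `ape::phylo` tree; quoted labels are unescaped
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  tree$tip.label <- unquote_newick_label(tree$tip.label)
  if (!is.null(tree$node.label)) {
    tree$node.label <- unquote_newick_label(tree$node.label)
  }
  tree
}

#' JSON tree report with raw bootstrap counts
#'
#' @param bs result of [bootstrap_support()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tree_json <- function(bs, path) {
  jsonlite::write_json(list(newick = write_newick(bs$tree),
                            support = bs$support,
                            n_replicates = bs$n_replicates,
                            n_skipped = bs$n_skipped),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
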