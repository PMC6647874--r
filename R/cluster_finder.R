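# cluster_finder: T3SS component homolog search by local protein alignment
# against a reference panel, and chaining of proximate hits into clusters.
#
# Component naming follows the rsp/rsc/rop nomenclature used for
# rhizosphere-expressed secretion systems: rsp = rhizosphere-expressed
# secretion protein, rsc = rsp conserved, rop = rhizosphere-expressed outer
# (effector) protein.

# Conserved core inventory every T3SS cluster report is checked against:
# nine structural genes plus the two regulators.
T3SS_CORE_COMPONENTS <- c("rscV", "rscN", "rscQ", "rscR", "rscS", "rscT",
                          "rscU", "rscC", "rscJ", "rspL", "rspR")

PANEL_ROLES <- c("regulatory", "structural-conserved",
                 "structural-nonconserved", "effector")

#' Read a T3SS component reference panel
#'
#' The panel is a protein FASTA whose headers are `name|role`, with roles
#' drawn from `regulatory`, `structural-conserved`,
#' `structural-nonconserved`, `effector`. The packaged default panel
#' (`t3ss_panel_synthetic.faa`) carries synthetic stand-in sequences under
#' the real component names and roles and is meant to be swapped for real
#' component sequences when available.
#'
#' @param path FASTA file; default: the packaged synthetic panel
#' @return data.frame of class `reference_panel` with columns
#'   `component_name`, `role`, `sequence`
#' @export
read_panel <- function(path = system.file("extdata",
                                          "t3ss_panel_synthetic.faa",
                                          package = "t3ssmine")) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stopf("panel header without 'name|role': %s",
                      names(aa)[bad][1])
  panel <- data.frame(component_name = vapply(parts, `[[`, "", 1L),
                      role = sub("\\s.*$", "", vapply(parts, `[[`, "", 2L)),
                      sequence = as.character(aa), stringsAsFactors = FALSE)
  if (anyDuplicated(panel$component_name)) stopf("duplicated component names in panel")
  unknown <- setdiff(panel$role, PANEL_ROLES)
  if (length(unknown)) stopf("unknown panel role(s): %s",
                             paste(unknown, collapse = ", "))
  class(panel) <- c("reference_panel", class(panel))
  panel
}

#' Optimal local (Smith-Waterman) alignment of two proteins
#'
#' Affine gap costs: a gap of length L costs `gap_open + (L - 1) *
#' gap_extend`. Percent identity is computed over aligned columns (the
#' BLAST convention), coverage as the fraction of the reference (`b`)
#' covered by the aligned range.
#'
#' @param a,b protein sequences (`b` is the reference for coverage)
#' @param matrix substitution matrix name (`"BLOSUM62"`, `"BLOSUM50"`, ...)
#' @param gap_open,gap_extend gap penalties (positive numbers)
#' @return list with `score`, `percent_identity`, `coverage`, `aligned_a`,
#'   `aligned_b`
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  for (s in list(a, b)) {
    bad <- setdiff(chars(toupper(s)), AA_STANDARD)
    if (length(bad)) stopf("unknown residue symbol '%s' in sequence", bad[1])
  }
  if (nchar(a) == 0L || nchar(b) == 0L) stopf("empty sequence")
  mat <- get_substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, type = "local",
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       percent_identity = 100 * Biostrings::nmatch(aln) / ncol_aln,
       coverage = (Biostrings::end(Biostrings::subject(aln)) -
                     Biostrings::start(Biostrings::subject(aln)) + 1) /
         nchar(b),
       aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)))
}

.matrix_cache <- new.env(parent = emptyenv())

get_substitution_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  if (!exists(name, envir = .matrix_cache)) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = e)) {
      stopf("unknown substitution matrix '%s'", name)
    }
    assign(name, get(name, envir = e), envir = .matrix_cache)
  }
  get(name, envir = .matrix_cache)
}

#' Find T3SS component homologs in a genome's proteome
#'
#' Every protein is aligned locally against every panel entry; each gene is
#' assigned its best-scoring component, and hits below the identity or
#' coverage threshold are dropped. One gene maps to at most one component;
#' a component may hit several genes, in which case all are reported and
#' flagged (`multi_hit`).
#'
#' @param genome an [annotated_genome()]
#' @param panel a [read_panel()] table
#' @param min_identity minimum percent identity over aligned columns
#' @param min_coverage minimum fraction of the panel sequence aligned
#' @param matrix,gap_open,gap_extend alignment scoring (see [local_align()])
#' @return data.frame with one row per retained gene: `gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `component_name`, `role`,
#'   `score`, `percent_identity`, `coverage`, `multi_hit`
#' @export
find_components <- function(genome, panel = read_panel(), min_identity = 30,
                            min_coverage = 0.5, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1)
  mat <- get_substitution_matrix(matrix)
  keep <- !is.na(genome$cds$protein) & nchar(genome$cds$protein) > 0L
  prots <- Biostrings::AAStringSet(setNames(genome$cds$protein[keep],
                                            genome$cds$gene_id[keep]))
  n_gene <- length(prots)
  rows <- list()
  if (n_gene) {
    # one vectorized alignment call per panel entry; keep each gene's best
    score <- identity <- coverage <- matrix(NA_real_, n_gene, nrow(panel))
    for (j in seq_len(nrow(panel))) {
      aln <- Biostrings::pairwiseAlignment(
        prots, Biostrings::AAString(panel$sequence[j]),
        substitutionMatrix = mat, type = "local",
        gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
      ncol_aln <- Biostrings::nchar(aln)
      score[, j] <- Biostrings::score(aln)
      identity[, j] <- 100 * Biostrings::nmatch(aln) / ncol_aln
      subj <- Biostrings::subject(aln)
      coverage[, j] <- (Biostrings::end(subj) - Biostrings::start(subj) + 1) /
        nchar(panel$sequence[j])
    }
    for (i in seq_len(n_gene)) {
      j <- which.max(score[i, ])
      if (identity[i, j] < min_identity || coverage[i, j] < min_coverage) next
      f <- genome$cds[genome$cds$gene_id == names(prots)[i], ]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = f$gene_id, contig_id = f$contig_id, start = f$start,
        end = f$end, strand = f$strand,
        component_name = panel$component_name[j], role = panel$role[j],
        score = score[i, j], percent_identity = identity[i, j],
        coverage = coverage[i, j], stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               component_name = character(), role = character(),
               score = numeric(), percent_identity = numeric(),
               coverage = numeric(), stringsAsFactors = FALSE)
  hits$multi_hit <- hits$component_name %in%
    hits$component_name[duplicated(hits$component_name)]
  rownames(hits) <- NULL
  hits
}

#' Chain component hits into T3SS gene clusters
#'
#' Single-linkage chaining per contig: successive hits (by genomic start)
#' whose gap (`next start - previous end - 1`) is at most `max_gap` belong
#' to the same cluster. Intervening non-panel genes are allowed; the span is
#' first-to-last member. Each cluster reports its role inventory and which
#' conserved core components (`rscV,N,Q,R,S,T,U,C,J` plus `rspL,R`) it
#' lacks.
#'
#' @param hits result of [find_components()]
#' @param max_gap maximum genomic gap in bp between successive members
#' @return list of `t3ss_cluster` objects, each with `contig_id`,
#'   `members` (hit rows ordered by start), `span_bp`, `present_roles`,
#'   `missing_components`
#' @export
assemble_clusters <- function(hits, max_gap = 5000L) {
  clusters <- list()
  if (nrow(hits) == 0L) return(clusters)
  for (ctg in unique(sort(hits$contig_id))) {
    h <- hits[hits$contig_id == ctg, , drop = FALSE]
    h <- h[order(h$start, h$gene_id), , drop = FALSE]
    brk <- c(FALSE, h$start[-1L] - h$end[-nrow(h)] - 1L > max_gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      m <- h[grp == g, , drop = FALSE]
      rownames(m) <- NULL
      clusters[[length(clusters) + 1L]] <- structure(list(
        contig_id = ctg, members = m,
        span_bp = max(m$end) - min(m$start) + 1L,
        present_roles = sort(unique(m$role)),
        missing_components = setdiff(T3SS_CORE_COMPONENTS, m$component_name)),
        class = "t3ss_cluster")
    }
  }
  clusters
}

#' @export
print.t3ss_cluster <- function(x, ...) {
  cat(sprintf("t3ss_cluster on %s: %d members, span %.1f kb\n", x$contig_id,
              nrow(x$members), x$span_bp / 1000))
  cat("  components:", paste(x$members$component_name, collapse = " "), "\n")
  if (length(x$missing_components))
    cat("  missing core:", paste(x$missing_components, collapse = " "), "\n")
  invisible(x)
}

#' Summarize clusters as a table
#' @param clusters result of [assemble_clusters()]
#' @return data.frame with one row per cluster
#' @export
cluster_summary <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(contig_id = character(), n_members = integer(),
                      span_bp = integer(), components = character(),
                      missing_core = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    contig_id = cl$contig_id, n_members = nrow(cl$members),
    span_bp = cl$span_bp,
    components = paste(cl$members$component_name, collapse = ","),
    missing_core = paste(cl$missing_components, collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Write cluster reports
#'
#' TSV/JSON reports plus a GFF3 track of cluster members for genome-browser
#' visualization.
#'
#' @param clusters result of [assemble_clusters()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_clusters_tsv <- function(clusters, path) {
  write.table(cluster_summary(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
write_clusters_json <- function(clusters, path) {
  payload <- lapply(clusters, function(cl) list(
    contig_id = cl$contig_id, span_bp = cl$span_bp,
    present_roles = cl$present_roles,
    missing_components = cl$missing_components, members = cl$members))
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
write_clusters_gff3 <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    for (i in seq_len(nrow(cl$members))) {
      m <- cl$members[i, ]
      writeLines(paste(m$contig_id, "t3ssmine", "CDS", m$start, m$end,
                       sprintf("%.1f", m$score), m$strand, ".",
                       sprintf("ID=%s;component=%s;role=%s;cluster=cluster%d",
                               m$gene_id, m$component_name, m$role, k),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
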