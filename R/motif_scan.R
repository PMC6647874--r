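# motif_scan: degenerate hrp-box motif search in upstream regions.
#
# The hrp box is the promoter element bound by the HrpL/RspL sigma factor.
# Two renderings of the consensus circulate; both are shipped (see
# hrp_box_pattern) and the screening form is the default.

#' Build a motif pattern with fixed IUPAC elements and variable spacers
#'
#' @param name pattern name
#' @param elements list of elements, each either a fixed IUPAC string
#'   (`motif_fixed("NGGAACN")`) or a variable spacer
#'   (`motif_spacer(15, 16)`)
#' @return an object of class `motif_pattern`
#' @export
motif_pattern <- function(name, elements) {
  kinds <- vapply(elements, `[[`, "", "kind")
  if (!any(kinds == "fixed")) stopf("pattern '%s' has no fixed element", name)
  for (el in elements) {
    if (el$kind == "fixed") {
      bad <- setdiff(chars(el$seq), names(IUPAC_SETS))
      if (length(bad)) stopf("non-IUPAC symbol(s) in pattern: %s",
                             paste(bad, collapse = ", "))
    } else if (el$min > el$max || el$min < 0) {
      stopf("invalid spacer range [%d, %d]", el$min, el$max)
    }
  }
  structure(list(name = name, elements = elements), class = "motif_pattern")
}

#' @rdname motif_pattern
#' @param seq fixed element as an IUPAC nucleotide string
#' @export
motif_fixed <- function(seq) list(kind = "fixed", seq = toupper(seq))

#' @rdname motif_pattern
#' @param min,max spacer length bounds in nt
#' @export
motif_spacer <- function(min, max) list(kind = "spacer", min = as.integer(min),
                                        max = as.integer(max))

#' The hrp-box promoter motif
#'
#' Two consensus renderings are shipped. `"screening"` (the default used
#' throughout the pipeline) reads the published screening motif
#' `xGGAACx[N15-16]CCACxxAG` with `x` as any nucleotide. `"consensus"` is
#' the alternative rendering `GGAACC-N15/16-CCACNNA`. The two disagree and
#' are not reconciled in the literature; the choice is a config key.
#'
#' @param variant `"screening"` or `"consensus"`
#' @return a [motif_pattern()]
#' @export
hrp_box_pattern <- function(variant = c("screening", "consensus")) {
  variant <- match.arg(variant)
  if (variant == "screening") {
    motif_pattern("hrp_box_screening",
                  list(motif_fixed("NGGAACN"), motif_spacer(15, 16),
                       motif_fixed("CCACNNAG")))
  } else {
    motif_pattern("hrp_box_consensus",
                  list(motif_fixed("GGAACC"), motif_spacer(15, 16),
                       motif_fixed("CCACNNA")))
  }
}

# min/max total span of a pattern in nt
pattern_span <- function(pattern) {
  mn <- 0L; mx <- 0L
  for (el in pattern$elements) {
    if (el$kind == "fixed") { mn <- mn + nchar(el$seq); mx <- mx + nchar(el$seq) }
    else { mn <- mn + el$min; mx <- mx + el$max }
  }
  c(min = mn, max = mx)
}

#' Default upstream window for a motif screen
#'
#' 300 nt (the maximum motif-to-gene distance) plus the maximum span of the
#' pattern, so a motif whose 3' end sits exactly at the distance bound is
#' still inside the window.
#'
#' @param pattern a [motif_pattern()]; default hrp-box screening pattern
#' @param max_dist maximum motif-to-gene distance in nt
#' @return window length in nt
#' @export
default_upstream_window <- function(pattern = hrp_box_pattern(),
                                    max_dist = 300L) {
  as.integer(max_dist + pattern_span(pattern)[["max"]])
}

# all concrete per-position layouts of the pattern, one per combination of
# spacer lengths: list of (symbols, element index per position, spacer_len)
pattern_layouts <- function(pattern) {
  spacers <- which(vapply(pattern$elements, `[[`, "", "kind") == "spacer")
  grids <- lapply(spacers, function(i) {
    el <- pattern$elements[[i]]
    seq.int(el$min, el$max)
  })
  combos <- if (length(grids)) expand.grid(grids) else data.frame(row.names = 1)
  lapply(seq_len(nrow(combos)), function(ci) {
    syms <- character(); elem <- integer()
    si <- 0L
    for (i in seq_along(pattern$elements)) {
      el <- pattern$elements[[i]]
      if (el$kind == "fixed") {
        s <- chars(el$seq)
      } else {
        si <- si + 1L
        s <- rep("N", combos[ci, si])
      }
      syms <- c(syms, s)
      elem <- c(elem, rep(i, length(s)))
    }
    list(symbols = syms, element = elem,
         spacer_len = if (length(spacers) == 1L) combos[ci, 1L] else
           sum(unlist(combos[ci, , drop = TRUE])))
  })
}

#' Scan one upstream region for a motif
#'
#' Reports every distinct `(start, spacer length)` assignment that matches
#' the pattern and whose distance to the start codon lies in
#' `[min_dist, max_dist]`. Overlapping matches are all reported; scanning is
#' on the coding strand only. A subject base that is not a concrete
#' A/C/G/T (e.g. `N`) never matches any motif symbol, wildcard and spacer
#' positions included.
#'
#' @param region an `upstream_region` from [extract_upstream()], or a plain
#'   nucleotide string (then `gene_id` is `NA`)
#' @param pattern a [motif_pattern()]
#' @param min_dist,max_dist bounds (nt) on the gap between the last base of
#'   the match and the base before the start codon
#' @param max_mismatch mismatches tolerated per fixed element (default 0;
#'   spacer positions are never allowed to mismatch)
#' @return data.frame with columns `gene_id`, `match_start`, `match_end`
#'   (1-based inclusive positions within the region), `matched_sequence`,
#'   `spacer_len`, `gene_distance`, ordered by `match_start` then
#'   `spacer_len`
#' @export
scan_region <- function(region, pattern = hrp_box_pattern(),
                        min_dist = 30L, max_dist = 300L, max_mismatch = 0L) {
  stopifnot(min_dist >= 0L, min_dist <= max_dist)
  if (is.character(region)) {
    region <- structure(list(gene_id = NA_character_, sequence = region,
                             length = nchar(region)), class = "upstream_region")
  }
  seq <- toupper(region$sequence)
  n <- nchar(seq)
  base_idx <- match(chars(seq), DNA_BASES)  # NA for N / ambiguity codes
  hits <- list()
  for (lay in pattern_layouts(pattern)) {
    span <- length(lay$symbols)
    if (span > n) next
    # allowed[t, b]: does base b satisfy pattern position t?
    allowed <- t(vapply(lay$symbols,
                        function(s) DNA_BASES %in% IUPAC_SETS[[s]],
                        logical(4)))
    starts <- seq_len(n - span + 1L)
    idx <- outer(starts, 0:(span - 1L), "+")
    bi <- matrix(base_idx[idx], nrow = length(starts))
    ok <- matrix(FALSE, nrow = length(starts), ncol = span)
    for (t in seq_len(span)) {
      b <- bi[, t]
      ok[, t] <- !is.na(b) & allowed[t, ][b]
    }
    mism <- !ok
    good <- rep(TRUE, length(starts))
    for (e in unique(lay$element)) {
      cols <- which(lay$element == e)
      nm <- rowSums(mism[, cols, drop = FALSE])
      budget <- if (pattern$elements[[e]]$kind == "fixed") max_mismatch else 0L
      good <- good & nm <= budget
    }
    for (s in starts[good]) {
      e <- s + span - 1L
      gd <- n - e
      if (gd < min_dist || gd > max_dist) next
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = region$gene_id, match_start = s, match_end = e,
        matched_sequence = substr(seq, s, e), spacer_len = lay$spacer_len,
        gene_distance = gd, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(), match_start = integer(),
               match_end = integer(), matched_sequence = character(),
               spacer_len = integer(), gene_distance = integer(),
               stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("match_start", "spacer_len")]), , drop = FALSE]
  out <- out[order(out$match_start, out$spacer_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a whole genome for hrp-box-positive genes
#'
#' Extracts the upstream region of every CDS and scans it for the motif.
#' One row is returned per gene with at least one surviving hit, whatever
#' the hit multiplicity; the best hit is the one with the smallest distance
#' to the gene, ties broken by smallest match start.
#'
#' @inheritParams scan_region
#' @param genome an [annotated_genome()]
#' @param window upstream window in nt; defaults to
#'   [default_upstream_window()] for the pattern and `max_dist`
#' @param both_strands also scan the reverse complement of each upstream
#'   region? Off by default: the hrp box is a sigma-factor element read on
#'   the coding strand.
#' @param truncate_at_cds passed to [extract_upstream()]
#' @return data.frame with one row per positive gene: `gene_id`,
#'   `contig_id`, `n_hits`, `best_match_start`, `best_spacer_len`,
#'   `best_gene_distance`, `best_matched_sequence`. The full per-hit table
#'   (with genomic coordinates) is attached as `attr(, "hits")`.
#' @export
screen_genome <- function(genome, pattern = hrp_box_pattern(),
                          min_dist = 30L, max_dist = 300L, window = NULL,
                          max_mismatch = 0L, both_strands = FALSE,
                          truncate_at_cds = FALSE) {
  if (is.null(window)) window <- default_upstream_window(pattern, max_dist)
  all_hits <- list()
  for (g in genome$cds$gene_id) {
    reg <- extract_upstream(genome, g, window = window,
                            truncate_at_cds = truncate_at_cds)
    h <- scan_region(reg, pattern, min_dist, max_dist, max_mismatch)
    h$scanned_strand <- rep("coding", nrow(h))
    if (both_strands && reg$length > 0L) {
      rc <- reg
      rc$sequence <- revcomp(reg$sequence)
      h2 <- scan_region(rc, pattern, min_dist, max_dist, max_mismatch)
      h2$scanned_strand <- rep("template", nrow(h2))
      h <- rbind(h, h2)
    }
    if (nrow(h)) {
      h <- cbind(h, hit_genomic_coords(reg, h))
      h$contig_id <- reg$contig_id
      h$strand <- reg$strand
      all_hits[[g]] <- h
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(gene_id = character(), match_start = integer(),
               match_end = integer(), matched_sequence = character(),
               spacer_len = integer(), gene_distance = integer(),
               scanned_strand = character(), genomic_start = integer(),
               genomic_end = integer(), contig_id = character(),
               strand = character(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  rows <- lapply(split(hits, factor(hits$gene_id, levels = unique(hits$gene_id))),
                 function(h) {
    b <- h[order(h$gene_distance, h$match_start), ][1, ]
    data.frame(gene_id = b$gene_id, contig_id = b$contig_id, n_hits = nrow(h),
               best_match_start = b$match_start, best_spacer_len = b$spacer_len,
               best_gene_distance = b$gene_distance,
               best_matched_sequence = b$matched_sequence,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), contig_id = character(),
               n_hits = integer(), best_match_start = integer(),
               best_spacer_len = integer(), best_gene_distance = integer(),
               best_matched_sequence = character(), stringsAsFactors = FALSE)
  tab <- tab[order(match(tab$gene_id, genome$cds$gene_id)), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "hits") <- hits
  tab
}

# map region-local match coordinates onto the genome (coding-strand scans)
hit_genomic_coords <- function(region, h) {
  if (is.null(region$genomic_start)) {
    return(data.frame(genomic_start = rep(NA_integer_, nrow(h)),
                      genomic_end = rep(NA_integer_, nrow(h))))
  }
  if (identical(region$strand, "-")) {
    data.frame(genomic_start = region$genomic_end - h$match_end + 1L,
               genomic_end = region$genomic_end - h$match_start + 1L)
  } else {
    data.frame(genomic_start = region$genomic_start + h$match_start - 1L,
               genomic_end = region$genomic_start + h$match_end - 1L)
  }
}

#' Write motif hits as TSV or BED
#'
#' The BED track uses 0-based half-open genomic intervals for genome-browser
#' use; the TSV keeps the package's 1-based inclusive coordinates.
#'
#' @param screen result of [screen_genome()] (the attached hit table is
#'   used), or the hit table itself
#' @param path output file
#' @return `path`, invisibly
#' @export
write_hits_tsv <- function(screen, path) {
  hits <- attr(screen, "hits") %||% screen
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(screen, path) {
  hits <- attr(screen, "hits") %||% screen
  bed <- data.frame(chrom = hits$contig_id,
                    chromStart = hits$genomic_start - 1L,
                    chromEnd = hits$genomic_end,
                    name = paste0(hits$gene_id, "_hrp_box"),
                    score = 0L, strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
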