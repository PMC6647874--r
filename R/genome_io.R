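# genome_io: annotated-genome container, GenBank / FASTA+GFF3 readers and
# writers, strand-correct upstream (promoter) extraction.

#' Construct an annotated genome
#'
#' The substrate of all scans: contig sequences plus strand-aware CDS
#' features with protein translations.
#'
#' @param genome_id identifier for the genome
#' @param contigs named character vector of contig sequences over
#'   `A/C/G/T/N`; names are contig ids and must be unique
#' @param cds data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (1-based inclusive, `start <= end` always, also on the minus
#'   strand), `strand` (`"+"` or `"-"`) and optionally `protein`
#'   (amino-acid translation; missing translations are computed with the
#'   bacterial genetic code, table 11)
#' @return an object of class `annotated_genome`
#' @export
annotated_genome <- function(genome_id, contigs, cds) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  if (anyDuplicated(names(contigs))) {
    stopf("duplicated contig ids: %s",
          paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  }
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  missing_cols <- setdiff(need, names(cds))
  if (length(missing_cols)) {
    stopf("cds table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  if (!"protein" %in% names(cds)) cds$protein <- NA_character_
  if (anyDuplicated(cds$gene_id)) {
    stopf("duplicated gene ids: %s",
          paste(unique(cds$gene_id[duplicated(cds$gene_id)]), collapse = ", "))
  }
  if (!all(cds$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(cds$start > cds$end)) stopf("CDS with start > end")
  bad <- !cds$contig_id %in% names(contigs)
  if (any(bad)) stopf("CDS on unknown contig: %s", paste(cds$gene_id[bad], collapse = ", "))
  clen <- nchar(contigs)[cds$contig_id]
  out_of_bounds <- cds$start < 1L | cds$end > clen
  if (any(out_of_bounds)) {
    stopf("CDS outside contig bounds: %s",
          paste(cds$gene_id[out_of_bounds], collapse = ", "))
  }
  # fill in translations the annotation did not provide
  no_prot <- which(is.na(cds$protein) | cds$protein == "")
  for (i in no_prot) {
    cds$protein[i] <- translate_cds(cds_nucleotide(contigs, cds[i, ]))
  }
  structure(list(genome_id = genome_id, contigs = contigs, cds = cds),
            class = "annotated_genome")
}

# nucleotide sequence of one CDS row, on its coding strand
cds_nucleotide <- function(contigs, feat) {
  s <- substr(contigs[[feat$contig_id]], feat$start, feat$end)
  if (feat$strand == "-") s <- revcomp(s)
  s
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d contig(s), %d bp, %d CDS\n",
              x$genome_id, length(x$contigs), sum(nchar(x$contigs)),
              nrow(x$cds)))
  invisible(x)
}

#' Read an annotated genome
#'
#' @param path path to a GenBank flat file, or to the FASTA file of a
#'   FASTA+GFF3 pair
#' @param format `"genbank"` or `"fasta+gff3"`
#' @param gff3 path to the GFF3 file (required for `format = "fasta+gff3"`)
#' @param genome_id optional genome id; defaults to the file base name
#' @return an [annotated_genome()]
#' @details For GenBank input, `/translation` qualifiers are used verbatim
#'   when present; otherwise (and always for GFF3 input, which carries no
#'   translations) proteins are computed with the bacterial genetic code.
#'   GFF3 gene ids are taken from the `locus_tag` attribute, falling back
#'   to `ID`.
#' @export
read_genome <- function(path, format = c("genbank", "fasta+gff3"),
                        gff3 = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "genbank") {
    read_genbank(path, genome_id)
  } else {
    if (is.null(gff3)) stopf("format 'fasta+gff3' needs the gff3= path")
    if (!file.exists(gff3)) stopf("file not found: %s", gff3)
    read_fasta_gff3(path, gff3, genome_id)
  }
}

read_fasta_gff3 <- function(fasta_path, gff3_path, genome_id) {
  contig_set <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(as.character(contig_set),
                      sub("\\s.*$", "", names(contig_set)))
  gr <- rtracklayer::import(gff3_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) {
    cds <- data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    return(annotated_genome(genome_id, contigs, cds))
  }
  md <- as.data.frame(gr)
  ids <- if ("locus_tag" %in% names(md) && !all(is.na(md$locus_tag))) {
    ifelse(is.na(md$locus_tag), md$ID, md$locus_tag)
  } else md$ID
  if (any(is.na(ids))) stopf("GFF3 CDS without ID or locus_tag attribute")
  cds <- data.frame(gene_id = as.character(ids),
                    contig_id = as.character(md$seqnames),
                    start = md$start, end = md$end,
                    strand = as.character(md$strand),
                    stringsAsFactors = FALSE)
  annotated_genome(genome_id, contigs, cds)
}

# ---- minimal GenBank flat-file support -------------------------------------
# Covers the subset this package writes: LOCUS per contig, CDS features with
# simple or complement() spans, /locus_tag and /translation qualifiers, and
# an ORIGIN block. Fuzzy locations and joins are out of scope.

read_genbank <- function(path, genome_id) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  if (!length(rec_starts)) stopf("%s: no LOCUS record found", path)
  rec_ends <- grep("^//\\s*$", lines)
  if (length(rec_ends) < length(rec_starts)) {
    stopf("%s: unterminated GenBank record (missing '//')", path)
  }
  contigs <- character()
  cds_list <- list()
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
    contig_id <- locus[2]
    ori <- grep("^ORIGIN", block)
    if (!length(ori)) stopf("%s: record '%s' has no ORIGIN block", path, contig_id)
    seq_lines <- block[(ori + 1):(length(block) - 1)]
    seq <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
    contigs[contig_id] <- seq
    fstart <- grep("^FEATURES", block)
    if (length(fstart)) {
      feat_lines <- block[(fstart + 1):(ori - 1)]
      cds_list[[r]] <- parse_genbank_features(feat_lines, contig_id, path)
    }
  }
  cds <- do.call(rbind, cds_list)
  if (is.null(cds)) {
    cds <- data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      protein = character(), stringsAsFactors = FALSE)
  }
  annotated_genome(genome_id, contigs, cds)
}

parse_genbank_features <- function(feat_lines, contig_id, path) {
  # feature keys start at column 6, qualifiers/continuations at column 22
  key_idx <- grep("^ {5}\\S", feat_lines)
  rows <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    j <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(feat_lines)
    fields <- strsplit(trimws(feat_lines[i]), "\\s+")[[1]]
    if (fields[1] != "CDS") next
    loc <- fields[2]
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order|<|>", loc)) {
      stopf("%s: unsupported CDS location '%s' (joins/fuzzy out of scope)",
            path, fields[2])
    }
    m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
    if (length(m) != 3L) stopf("%s: cannot parse CDS location '%s'", path, fields[2])
    quals <- parse_genbank_qualifiers(feat_lines[(i + 1):j])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = quals[["locus_tag"]] %||% quals[["gene"]] %||%
        sprintf("%s_cds%d", contig_id, k),
      contig_id = contig_id,
      start = as.integer(m[2]), end = as.integer(m[3]), strand = strand,
      protein = quals[["translation"]] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

parse_genbank_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- grep("^/", lines)
  quals <- list()
  for (s in seq_along(starts)) {
    i <- starts[s]
    j <- if (s < length(starts)) starts[s + 1] - 1L else length(lines)
    txt <- paste(lines[i:j], collapse = "")
    m <- regmatches(txt, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', txt))[[1]]
    if (length(m) == 3L) quals[[m[2]]] <- m[3]
  }
  quals
}

#' Write an annotated genome as a GenBank flat file
#'
#' @param genome an [annotated_genome()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (contig_id in names(genome$contigs)) {
    seq <- genome$contigs[[contig_id]]
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000",
                       contig_id, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s.", genome$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    feats <- genome$cds[genome$cds$contig_id == contig_id, , drop = FALSE]
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      loc <- sprintf("%d..%d", f$start, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', f$gene_id), con)
      writeLines(wrap_qualifier("translation", f$protein), con)
    }
    writeLines("ORIGIN", con)
    writeLines(format_origin(seq), con)
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(name, value) {
  txt <- sprintf('/%s="%s"', name, value)
  pieces <- substring(txt, seq(1, nchar(txt), by = 58),
                      pmin(seq(1, nchar(txt), by = 58) + 57, nchar(txt)))
  paste0(strrep(" ", 21), pieces)
}

format_origin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1, n, by = 60)
  vapply(starts, function(s) {
    line <- substr(seq, s, min(s + 59, n))
    blocks <- substring(line, seq(1, nchar(line), by = 10),
                        pmin(seq(1, nchar(line), by = 10) + 9, nchar(line)))
    sprintf("%9d %s", s, paste(tolower(blocks), collapse = " "))
  }, character(1))
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome an [annotated_genome()]
#' @param fasta,gff3 output paths
#' @return invisibly, the two paths
#' @export
write_fasta_gff3 <- function(genome, fasta, gff3) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fasta)
  con <- file(gff3, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (contig_id in names(genome$contigs)) {
    writeLines(sprintf("##sequence-region %s 1 %d", contig_id,
                       nchar(genome$contigs[[contig_id]])), con)
  }
  for (i in seq_len(nrow(genome$cds))) {
    f <- genome$cds[i, ]
    writeLines(paste(f$contig_id, "t3ssmine", "CDS", f$start, f$end, ".",
                     f$strand, "0",
                     sprintf("ID=%s;locus_tag=%s", f$gene_id, f$gene_id),
                     sep = "\t"), con)
  }
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Extract the upstream (promoter) region of a gene
#'
#' Returns the sequence on the coding strand of the gene, written 5'->3',
#' ending immediately before the start codon. For minus-strand genes this is
#' the reverse complement of the genomic region after the annotated end.
#' Truncated at the contig boundary; by default the window is *not*
#' truncated at neighboring CDS (set `truncate_at_cds = TRUE` to clip at the
#' nearest overlapping CDS).
#'
#' @param genome an [annotated_genome()]
#' @param gene_id gene to extract for
#' @param window maximum length in nt; defaults to 300 + the span of the
#'   default hrp-box pattern, so a motif ending exactly 300 bp from the
#'   start codon is still findable
#' @param truncate_at_cds clip the window where it overlaps another CDS?
#' @return an object of class `upstream_region` with fields `gene_id`,
#'   `sequence`, `length`, `contig_id`, `strand`, `genomic_start`,
#'   `genomic_end` (the genomic interval covered; zero-length regions have
#'   `genomic_start > genomic_end`)
#' @export
extract_upstream <- function(genome, gene_id, window = NULL,
                             truncate_at_cds = FALSE) {
  if (is.null(window)) window <- default_upstream_window()
  stopifnot(window >= 1)
  i <- match(gene_id, genome$cds$gene_id)
  if (is.na(i)) stopf("unknown gene_id: %s", gene_id)
  f <- genome$cds[i, ]
  clen <- nchar(genome$contigs[[f$contig_id]])
  if (f$strand == "+") {
    gstart <- max(1L, f$start - window)
    gend <- f$start - 1L
  } else {
    gstart <- f$end + 1L
    gend <- min(clen, f$end + window)
  }
  if (truncate_at_cds && gend >= gstart) {
    others <- genome$cds[genome$cds$contig_id == f$contig_id &
                           genome$cds$gene_id != gene_id, , drop = FALSE]
    ov <- others[others$end >= gstart & others$start <= gend, , drop = FALSE]
    if (nrow(ov)) {
      if (f$strand == "+") gstart <- max(gstart, max(ov$end) + 1L)
      else gend <- min(gend, min(ov$start) - 1L)
    }
  }
  seq <- if (gend >= gstart) {
    s <- substr(genome$contigs[[f$contig_id]], gstart, gend)
    if (f$strand == "-") revcomp(s) else s
  } else ""
  structure(list(gene_id = gene_id, sequence = seq, length = nchar(seq),
                 contig_id = f$contig_id, strand = f$strand,
                 genomic_start = gstart, genomic_end = gend),
            class = "upstream_region")
}

#' Write upstream regions or the proteome as FASTA
#'
#' @param genome an [annotated_genome()]
#' @param path output FASTA file
#' @param window upstream window in nt (see [extract_upstream()])
#' @return `path`, invisibly
#' @export
write_upstream_fasta <- function(genome, path, window = NULL) {
  regs <- lapply(genome$cds$gene_id, function(g)
    extract_upstream(genome, g, window = window))
  seqs <- setNames(vapply(regs, `[[`, "", "sequence"),
                   vapply(regs, `[[`, "", "gene_id"))
  seqs <- seqs[nchar(seqs) > 0]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_upstream_fasta
#' @export
write_proteome_fasta <- function(genome, path) {
  seqs <- setNames(genome$cds$protein, genome$cds$gene_id)
  seqs <- seqs[!is.na(seqs) & nchar(seqs) > 0]
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
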