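# synthetic_data: annotated synthetic genomes and alignments with planted,
# manifest-recorded ground truth, so every pipeline stage can be verified
# offline. Background composition is i.i.d. with configurable GC content
# (no codon model); intergenic/background stretches that will be scanned
# are rejection-sampled to be free of accidental motif matches, so the
# manifest is the complete truth.

HRP_DECOY_TYPES <- c("wrong_spacer", "distance_too_near", "distance_too_far",
                     "mutated_core")
EFFECTOR_VIOLATIONS <- c("low_ser", "low_polar", "too_acidic",
                         "no_aliphatic_34")

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe the standard test genome: a 2-Mb single contig at 60%
#' GC (Pseudomonas-like) carrying 5 conformant hrp boxes upstream of
#' distinct genes, 10 near-miss box decoys (wrong spacer, distance out of
#' bounds on either side, mutated core, cycled), 10 true-effector ORFs and
#' 10 decoy ORFs each violating exactly one N-terminal criterion (all 20
#' with conformant boxes so the N-terminal filter is what separates them),
#' a contiguous cluster of diverged homologs of the full reference panel,
#' and 10 background genes with motif-free promoters.
#'
#' @param genome_length total contig length in bp
#' @param gc background GC content
#' @param n_conformant_boxes conformant hrp boxes upstream of plain genes
#' @param n_decoy_boxes near-miss decoy boxes (types cycled)
#' @param n_effectors true-effector ORFs (conformant box + conformant
#'   N-terminus)
#' @param n_effector_decoys ORFs with a conformant box whose N-terminus
#'   violates exactly one criterion (violations cycled)
#' @param n_background_genes genes with no planted box
#' @param cluster_components panel component names to plant as a contiguous
#'   cluster (`NULL` or `character(0)` for none)
#' @param cluster_mutation_rate per-residue substitution probability applied
#'   to each planted cluster protein
#' @param cluster_intergap intergenic gap inside the cluster in bp
#' @param contig_id name of the single contig
#' @return a list of class `synthetic_genome_config`
#' @export
synthetic_genome_config <- function(genome_length = 2e6, gc = 0.60,
                                    n_conformant_boxes = 5L,
                                    n_decoy_boxes = 10L,
                                    n_effectors = 10L,
                                    n_effector_decoys = 10L,
                                    n_background_genes = 10L,
                                    cluster_components = read_panel()$component_name,
                                    cluster_mutation_rate = 0.2,
                                    cluster_intergap = 400L,
                                    contig_id = "contig1") {
  stopifnot(genome_length >= 1, gc > 0, gc < 1, cluster_mutation_rate >= 0,
            cluster_mutation_rate <= 1, cluster_intergap >= 1)
  structure(as.list(environment()), class = "synthetic_genome_config")
}

#' Generate a synthetic annotated genome with planted ground truth
#'
#' The genome is reproducible bit-for-bit from `(config, seed)`. Every
#' planted element is recorded in the manifest; every decoy violates
#' exactly the one property the manifest names. Scanned background
#' (promoter windows of non-box genes, cluster intergaps) is
#' rejection-sampled to contain no accidental motif match, so pipeline
#' positives can be scored for precision and recall exactly against the
#' manifest.
#'
#' @param config a [synthetic_genome_config()]
#' @param seed integer seed
#' @param out_dir if non-`NULL`, write `genome.gbk`, `genome.fna`,
#'   `genome.gff3` and `manifest.json` there
#' @param pattern motif pattern being planted (default hrp-box screening
#'   form)
#' @return list with `genome` (an [annotated_genome()]), `manifest`, and
#'   `paths` (when written)
#' @export
generate_genome <- function(config = synthetic_genome_config(), seed,
                            out_dir = NULL, pattern = hrp_box_pattern()) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  if (missing(seed)) stopf("a seed is mandatory for genome generation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  win_len <- default_upstream_window(pattern)
  boxes <- list(); effectors <- list(); cassettes <- list()
  add_box <- function(gene_id, group, planted) {
    boxes[[length(boxes) + 1L]] <<- data.frame(
      gene_id = gene_id, group = group, motif_sequence = planted$motif,
      spacer_len = planted$spacer_len, gene_distance = planted$gene_distance,
      conformant = planted$conformant, defect = planted$defect,
      stringsAsFactors = FALSE)
  }

  gid <- 0L
  next_id <- function(prefix) {
    gid <<- gid + 1L
    sprintf("%s_%03d", prefix, gid)
  }

  # plain genes with motif-free promoters
  for (i in seq_len(config$n_background_genes)) {
    g <- next_id("bg")
    cassettes[[g]] <- make_cassette(g, clean_window(win_len, config$gc, pattern),
                                    random_protein(150L),
                                    strand = if (i %% 2) "+" else "-")
  }
  # conformant boxes upstream of plain genes
  for (i in seq_len(config$n_conformant_boxes)) {
    g <- next_id("box")
    pl <- plant_box(win_len, config$gc, pattern, defect = "none")
    add_box(g, "motif", pl)
    cassettes[[g]] <- make_cassette(g, pl$window, random_protein(150L),
                                    strand = if (i %% 2) "+" else "-")
  }
  # near-miss decoy boxes
  for (i in seq_len(config$n_decoy_boxes)) {
    g <- next_id("dbox")
    defect <- HRP_DECOY_TYPES[(i - 1L) %% length(HRP_DECOY_TYPES) + 1L]
    pl <- plant_box(win_len, config$gc, pattern, defect = defect)
    add_box(g, "motif", pl)
    cassettes[[g]] <- make_cassette(g, pl$window, random_protein(150L),
                                    strand = if (i %% 2) "+" else "-")
  }
  # true effectors and single-violation decoys, all hrp-box positive
  for (i in seq_len(config$n_effectors)) {
    g <- next_id("eff")
    pl <- plant_box(win_len, config$gc, pattern, defect = "none")
    add_box(g, "effector", pl)
    effectors[[g]] <- data.frame(gene_id = g, violated_criterion = "none",
                                 is_true_effector = TRUE,
                                 stringsAsFactors = FALSE)
    cassettes[[g]] <- make_cassette(g, pl$window, effector_protein("none"),
                                    strand = if (i %% 2) "+" else "-")
  }
  for (i in seq_len(config$n_effector_decoys)) {
    g <- next_id("deff")
    viol <- EFFECTOR_VIOLATIONS[(i - 1L) %% length(EFFECTOR_VIOLATIONS) + 1L]
    pl <- plant_box(win_len, config$gc, pattern, defect = "none")
    add_box(g, "effector", pl)
    effectors[[g]] <- data.frame(gene_id = g, violated_criterion = viol,
                                 is_true_effector = FALSE,
                                 stringsAsFactors = FALSE)
    cassettes[[g]] <- make_cassette(g, pl$window, effector_protein(viol),
                                    strand = if (i %% 2) "+" else "-")
  }

  # contiguous cluster of diverged panel homologs (plus strand, windows
  # carved from rejection-sampled intergaps)
  cluster_rows <- list()
  cluster_cassette <- NULL
  if (length(config$cluster_components)) {
    panel <- read_panel()
    miss <- setdiff(config$cluster_components, panel$component_name)
    if (length(miss)) stopf("unknown cluster component(s): %s",
                            paste(miss, collapse = ", "))
    seq_parts <- character(); feats <- list(); offset <- 0L
    for (comp in config$cluster_components) {
      g <- next_id("t3ss")
      gap <- clean_window(config$cluster_intergap, config$gc, pattern)
      prot <- mutate_protein(panel$sequence[panel$component_name == comp],
                             config$cluster_mutation_rate)
      cds <- reverse_translate(prot)
      seq_parts <- c(seq_parts, gap, cds)
      start <- offset + nchar(gap) + 1L
      end <- start + nchar(cds) - 1L
      offset <- end
      feats[[g]] <- data.frame(gene_id = g, start = start, end = end,
                               strand = "+", protein = prot,
                               stringsAsFactors = FALSE)
      cluster_rows[[g]] <- data.frame(gene_id = g, component_name = comp,
                                      mutation_rate = config$cluster_mutation_rate,
                                      stringsAsFactors = FALSE)
    }
    cluster_cassette <- list(sequence = paste(seq_parts, collapse = ""),
                             features = do.call(rbind, feats))
  }

  all_cassettes <- c(cassettes,
                     if (!is.null(cluster_cassette)) list(t3ss_cluster = cluster_cassette))
  total_cassette <- sum(vapply(all_cassettes, function(x) nchar(x$sequence), 0))
  n_gaps <- length(all_cassettes) + 1L
  filler_total <- config$genome_length - total_cassette
  if (filler_total < n_gaps) {
    stopf("infeasible config: %d bp of genes do not fit in a %d bp genome",
          total_cassette, config$genome_length)
  }
  filler_each <- filler_total %/% n_gaps
  filler_rem <- filler_total %% n_gaps

  seq_parts <- character(); cds_rows <- list(); offset <- 0L
  for (k in seq_along(all_cassettes)) {
    fl <- filler_each + (if (k <= filler_rem) 1L else 0L)
    seq_parts <- c(seq_parts, random_dna(fl, config$gc))
    offset <- offset + fl
    cas <- all_cassettes[[k]]
    f <- cas$features
    f$start <- f$start + offset
    f$end <- f$end + offset
    cds_rows[[k]] <- f
    seq_parts <- c(seq_parts, cas$sequence)
    offset <- offset + nchar(cas$sequence)
  }
  seq_parts <- c(seq_parts, random_dna(config$genome_length - offset, config$gc))
  contig <- paste(seq_parts, collapse = "")
  cds <- do.call(rbind, cds_rows)
  cds$contig_id <- config$contig_id
  rownames(cds) <- NULL
  genome <- annotated_genome(sprintf("synthetic_%d", seed),
                             setNames(contig, config$contig_id), cds)

  manifest <- list(
    seed = seed,
    window_len = win_len,
    pattern = pattern$name,
    planted_hrp_boxes = if (length(boxes)) do.call(rbind, boxes) else NULL,
    planted_effectors = if (length(effectors)) do.call(rbind, effectors) else NULL,
    planted_cluster = if (length(cluster_rows)) {
      pc <- do.call(rbind, cluster_rows)
      pc$start <- cds$start[match(pc$gene_id, cds$gene_id)]
      pc$end <- cds$end[match(pc$gene_id, cds$gene_id)]
      pc
    } else NULL,
    background = list(gc = config$gc, genome_length = config$genome_length,
                      n_cds = nrow(cds)))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(genbank = file.path(out_dir, "genome.gbk"),
               fasta = file.path(out_dir, "genome.fna"),
               gff3 = file.path(out_dir, "genome.gff3"),
               manifest = file.path(out_dir, "manifest.json"))
    write_genbank(genome, paths[["genbank"]])
    write_fasta_gff3(genome, paths[["fasta"]], paths[["gff3"]])
    jsonlite::write_json(manifest, paths[["manifest"]], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(genome = genome, manifest = manifest, paths = paths)
}

# one gene cassette: upstream window block followed by the CDS, optionally
# reverse-complemented as a whole to plant the gene on the minus strand
make_cassette <- function(gene_id, window_seq, protein, strand = "+") {
  cds <- reverse_translate(protein)
  w <- nchar(window_seq)
  len <- w + nchar(cds)
  if (strand == "+") {
    feat <- data.frame(gene_id = gene_id, start = w + 1L, end = len,
                       strand = "+", protein = protein, stringsAsFactors = FALSE)
    list(sequence = paste0(window_seq, cds), features = feat)
  } else {
    feat <- data.frame(gene_id = gene_id, start = 1L, end = nchar(cds),
                       strand = "-", protein = protein, stringsAsFactors = FALSE)
    list(sequence = revcomp(paste0(window_seq, cds)), features = feat)
  }
}

# random window with no motif match anywhere (rejection sampling)
clean_window <- function(len, gc, pattern, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    w <- random_dna(len, gc)
    if (nrow(scan_region(w, pattern, min_dist = 0L, max_dist = len)) == 0L)
      return(w)
  }
  stopf("could not sample a motif-free window of %d nt in %d tries",
        len, max_tries)
}

# realize one concrete motif instance (optionally defective) and splice it
# into a clean window at the required distance from the start codon
plant_box <- function(win_len, gc, pattern, defect = "none",
                      max_tries = 100L) {
  spacer_len <- switch(defect,
                       wrong_spacer = sample(c(14L, 17L), 1L),
                       distance_too_far = 15L,
                       sample(15:16, 1L))
  gene_distance <- switch(defect,
                          distance_too_near = sample(5:29, 1L),
                          distance_too_far = 301L,
                          sample(30:300, 1L))
  for (try in seq_len(max_tries)) {
    motif <- realize_motif(pattern, spacer_len)
    if (defect == "mutated_core") {
      # destroy the GGAAC core so the element can no longer match
      core <- regexpr("GGAAC", motif, fixed = TRUE)
      pos <- as.integer(core) + 2L
      substr(motif, pos, pos) <- "C"
    }
    span <- nchar(motif)
    if (gene_distance + span > win_len) {
      stopf("planted box (distance %d, span %d) exceeds the %d nt window",
            gene_distance, span, win_len)
    }
    window <- clean_window(win_len, gc, pattern)
    at <- win_len - gene_distance - span + 1L
    substr(window, at, at + span - 1L) <- motif
    # the spliced window must contain exactly the intended match set
    found <- scan_region(window, pattern, min_dist = 0L, max_dist = win_len)
    expected_clean <- switch(defect,
                             none = nrow(found) == 1L && found$match_start == at &&
                               found$spacer_len == spacer_len,
                             distance_too_near = ,
                             distance_too_far = nrow(found) == 1L &&
                               found$match_start == at,
                             nrow(found) == 0L)
    if (expected_clean) {
      return(list(window = window, motif = motif, spacer_len = spacer_len,
                  gene_distance = gene_distance,
                  conformant = defect == "none", defect = defect))
    }
  }
  stopf("could not plant a '%s' box cleanly in %d tries", defect, max_tries)
}

# concrete instance of the pattern with one spacer length
realize_motif <- function(pattern, spacer_len) {
  parts <- vapply(pattern$elements, function(el) {
    if (el$kind == "fixed") {
      paste(vapply(chars(el$seq),
                   function(s) {
                     set <- IUPAC_SETS[[s]]
                     if (length(set) == 1L) set else sample(set, 1L)
                   }, character(1)), collapse = "")
    } else {
      paste(sample(DNA_BASES, spacer_len, replace = TRUE), collapse = "")
    }
  }, character(1))
  paste(parts, collapse = "")
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA_STANDARD, len - 1L, replace = TRUE),
                    collapse = ""))
}

# N-terminus engineered to pass every default criterion with margin >= 0.05
# in each fraction, or to violate exactly the named criterion
effector_protein <- function(violated = "none", tail_len = 100L) {
  aa <- rep("K", 50L)                     # neutral, non-polar, non-acidic
  aa[1] <- "M"
  aa[2] <- "K"
  aa[3] <- if (violated == "no_aliphatic_34") "R" else "I"
  aa[4] <- if (violated == "no_aliphatic_34") "K" else "W"
  n_ser <- if (violated == "low_ser") 2L else 9L           # 0.04 vs 0.18
  n_other_polar <- if (violated == "low_polar") 4L else 15L
  if (violated == "low_ser") n_other_polar <- 22L          # keep polar >= 0.45
  if (violated == "low_polar") n_ser <- 9L                 # polar = 0.26 total
  free <- setdiff(13:50, integer(0))
  ser_pos <- free[seq_len(n_ser)]
  polar_pos <- free[n_ser + seq_len(n_other_polar)]
  aa[ser_pos] <- "S"
  aa[polar_pos] <- sample(c("T", "N", "Q", "G", "H"), n_other_polar,
                          replace = TRUE)
  if (violated == "too_acidic") {
    aa[7] <- "D"; aa[9] <- "E"
  } else {
    aa[7] <- "E"                          # exactly one acidic in first 12
  }
  paste0(paste(aa, collapse = ""),
         paste(sample(AA_STANDARD, tail_len, replace = TRUE), collapse = ""))
}

# back-translate a protein with random synonymous codons (table 11) + stop
reverse_translate <- function(protein) {
  code <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(code), code)
  codons <- vapply(chars(protein), function(a) {
    cs <- by_aa[[a]]
    if (is.null(cs)) stopf("cannot reverse-translate residue '%s'", a)
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(c("TAA", "TGA", "TAG"), 1L))
}

mutate_protein <- function(protein, rate) {
  aa <- chars(protein)
  hit <- runif(length(aa)) < rate
  aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA_STANDARD, a), 1L),
                    character(1))
  paste(aa, collapse = "")
}

#' Simulate sequence evolution along a tree
#'
#' Evolves i.i.d. sites along a tree by the standard Markov substitution
#' process, using closed-form transition probabilities: Kimura-80 with
#' transition/transversion ratio `kappa` for nucleotides, or the 20-state
#' Jukes-Cantor (equal-rates) model for proteins. Branch lengths are in
#' expected substitutions per site.
#'
#' @param tree an `ape::phylo` tree with branch lengths, or a Newick string
#' @param model `"k80"` or `"jc_protein"`
#' @param length number of sites (>= 1)
#' @param seed integer seed
#' @param kappa transition/transversion rate ratio for `"k80"`
#' @return list with `msa` (an [msa()] over the tree's tips) and `tree`
#'   (the true tree)
#' @export
generate_alignment <- function(tree, model = c("k80", "jc_protein"),
                               length, seed, kappa = 2) {
  model <- match.arg(model)
  if (is.character(tree)) tree <- read_newick(text = tree)
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  stopifnot(length >= 1)
  if (model == "k80" && kappa <= 0) stopf("kappa must be positive")
  if (missing(seed)) stopf("a seed is mandatory for simulation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  alphabet <- if (model == "k80") DNA_BASES else AA_STANDARD
  k <- base::length(alphabet)
  trans_matrix <- function(t) {
    if (model == "k80") {
      beta <- 1 / (kappa + 2); alpha <- kappa / (kappa + 2)
      e1 <- exp(-4 * beta * t); e2 <- exp(-2 * (alpha + beta) * t)
      p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
      p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
      p_tv <- 0.25 - 0.25 * e1
      # order A C G T; transitions A<->G and C<->T
      m <- matrix(p_tv, 4, 4)
      diag(m) <- p_same
      m[1, 3] <- m[3, 1] <- p_ts
      m[2, 4] <- m[4, 2] <- p_ts
      m
    } else {
      e <- exp(-(k / (k - 1)) * t)
      m <- matrix((1 - e) / k, k, k)
      diag(m) <- 1 / k + (k - 1) / k * e
      m
    }
  }
  n_tip <- base::length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, length)
  root <- n_tip + 1L
  states[root, ] <- sample.int(k, length, replace = TRUE)
  # descend from the root so a child's parent state is always available
  remaining <- seq_len(nrow(tree$edge))
  known <- rep(FALSE, n_node); known[root] <- TRUE
  while (base::length(remaining)) {
    ready <- remaining[known[tree$edge[remaining, 1]]]
    if (!base::length(ready)) stopf("tree edges are not connected to the root")
    for (e in ready) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      P <- trans_matrix(tree$edge.length[e])
      ps <- states[parent, ]
      cs <- integer(length)
      for (b in seq_len(k)) {
        idx <- which(ps == b)
        if (base::length(idx)) cs[idx] <- sample.int(k, base::length(idx),
                                                     replace = TRUE,
                                                     prob = P[b, ])
      }
      states[child, ] <- cs
      known[child] <- TRUE
    }
    remaining <- setdiff(remaining, ready)
  }
  seqs <- setNames(vapply(seq_len(n_tip), function(i)
    paste(alphabet[states[i, ]], collapse = ""), character(1)),
    tree$tip.label)
  list(msa = msa(seqs, type = if (model == "k80") "dna" else "protein"),
       tree = tree)
}
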