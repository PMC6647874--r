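# cluster_finder: local alignment against the panel and cluster chaining

test_that("identical sequences align at 100% identity and full coverage", {
  set.seed(5)
  s <- random_aa(30)
  al <- local_align(s, s)
  expect_equal(al$percent_identity, 100)
  expect_equal(al$coverage, 1.0)
})

test_that("the textbook local alignment score is reproduced", {
  al <- local_align("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                    gap_open = 8, gap_extend = 8)
  expect_equal(al$score, 28)
  expect_equal(oracle_sw("HEAGAWGHEE", "PAWHEAE", blosum("BLOSUM50"), 8, 8), 28)
})

test_that("local alignment scores are symmetric", {
  set.seed(6)
  for (i in 1:10) {
    a <- random_aa(sample(10:40, 1)); b <- random_aa(sample(10:40, 1))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("unknown residue symbols are named in the error", {
  expect_error(local_align("MKBZ", "MKLV"), "B")
})

test_that("local alignment equals exhaustive dynamic programming", {
  set.seed(77)
  mat62 <- blosum("BLOSUM62")
  for (i in 1:60) {
    a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
    open <- sample(5:12, 1); ext <- sample(1:4, 1)
    got <- local_align(a, b, gap_open = open, gap_extend = ext)$score
    expect_equal(got, oracle_sw(a, b, mat62, open, ext))
  }
})

test_that("a verbatim panel sequence is found at 100% identity", {
  panel <- read_panel()
  prot <- panel$sequence[panel$component_name == "rscC"]
  cdsseq <- paste0("ATG", strrep("AAA", 50), "TAA")
  g <- annotated_genome("t", c(c1 = strrep("ACGT", 1000)),
                        data.frame(gene_id = "g1", contig_id = "c1",
                                   start = 1L, end = 1803L, strand = "+",
                                   protein = prot, stringsAsFactors = FALSE))
  hits <- find_components(g)
  expect_equal(hits$component_name, "rscC")
  expect_equal(hits$percent_identity, 100)
  expect_false(hits$multi_hit)
})

test_that("a panel sequence mutated at half its positions is still detected", {
  set.seed(90)
  panel <- read_panel()
  prot <- panel$sequence[panel$component_name == "rscN"]
  aa <- strsplit(prot, "")[[1]]
  idx <- sample(seq_along(aa), length(aa) %/% 2)
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  aa[idx] <- vapply(aa[idx], function(x) sample(setdiff(aa20, x), 1), "")
  mut <- paste(aa, collapse = "")
  # ungapped identity by direct count stays at or above the 30% threshold
  expect_gte(100 * mean(strsplit(mut, "")[[1]] == strsplit(prot, "")[[1]]), 30)
  g <- annotated_genome("t", c(c1 = strrep("ACGT", 1000)),
                        data.frame(gene_id = "g1", contig_id = "c1",
                                   start = 1L, end = 33L, strand = "+",
                                   protein = mut, stringsAsFactors = FALSE))
  hits <- find_components(g, panel, min_identity = 30, min_coverage = 0.5)
  expect_equal(hits$component_name, "rscN")
})

test_that("an unrelated random proteome produces no hits at default thresholds", {
  set.seed(91)
  cds <- data.frame(gene_id = sprintf("r%02d", 1:10), contig_id = "c1",
                    start = seq(1L, by = 40L, length.out = 10),
                    end = seq(1L, by = 40L, length.out = 10) + 29L,
                    strand = "+",
                    protein = replicate(10, random_aa(300)),
                    stringsAsFactors = FALSE)
  g <- annotated_genome("t", c(c1 = strrep("ACGT", 200)), cds)
  expect_equal(nrow(find_components(g)), 0L)
})

make_hits <- function(starts, ends, comps = NULL) {
  n <- length(starts)
  if (is.null(comps)) comps <- sprintf("rsc%s", LETTERS[seq_len(n)])
  data.frame(gene_id = sprintf("g%d", seq_len(n)), contig_id = rep("c1", n),
             start = as.integer(starts), end = as.integer(ends),
             strand = rep("+", n), component_name = comps,
             role = rep("structural-conserved", n), score = rep(100, n),
             percent_identity = rep(50, n), coverage = rep(0.9, n),
             multi_hit = rep(FALSE, n), stringsAsFactors = FALSE)
}

test_that("hits split by a large gap form two clusters; chaining respects max_gap", {
  h <- make_hits(c(1000, 3000, 60000), c(2000, 4000, 61000))
  cl <- assemble_clusters(h, max_gap = 5000)
  expect_length(cl, 2L)
  expect_equal(nrow(cl[[1]]$members), 2L)
  expect_equal(cl[[1]]$span_bp, 4000L - 1000L + 1L)
  # raising max_gap merges, never splits
  expect_length(assemble_clusters(h, max_gap = 60000), 1L)
  for (gap in c(1000, 10000, 100000)) {
    expect_lte(length(assemble_clusters(h, max_gap = gap * 2)),
               length(assemble_clusters(h, max_gap = gap)))
  }
})

test_that("cluster assembly is invariant to hit order and reports missing core", {
  h <- make_hits(c(1000, 3000, 5000), c(2000, 4000, 6000),
                 comps = c("rscV", "rscN", "rspL"))
  cl1 <- assemble_clusters(h)
  cl2 <- assemble_clusters(h[c(3, 1, 2), ])
  expect_equal(cl1, cl2)
  expect_equal(cl1[[1]]$members$component_name, c("rscV", "rscN", "rspL"))
  expect_setequal(cl1[[1]]$missing_components,
                  c("rscQ", "rscR", "rscS", "rscT", "rscU", "rscC", "rscJ",
                    "rspR"))
})

test_that("zero hits give zero clusters", {
  expect_length(assemble_clusters(make_hits(integer(), integer())), 0L)
})

test_that("a planted synthetic cluster is recovered with its span and members", {
  set.seed(14)
  res <- generate_genome(synthetic_genome_config(
    genome_length = 80000, n_background_genes = 2, n_conformant_boxes = 0,
    n_decoy_boxes = 0, n_effectors = 0, n_effector_decoys = 0),
    seed = 17)
  hits <- find_components(res$genome)
  cl <- assemble_clusters(hits)
  expect_length(cl, 1L)
  man <- res$manifest$planted_cluster
  expect_setequal(cl[[1]]$members$gene_id, man$gene_id)
  expect_equal(cl[[1]]$span_bp, max(man$end) - min(man$start) + 1L)
  # component roles assigned correctly despite 20% divergence
  expect_equal(cl[[1]]$members$component_name[
    match(man$gene_id, cl[[1]]$members$gene_id)], man$component_name)
  expect_length(cl[[1]]$missing_components, 0L)
})
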