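# motif_scan: degenerate hrp-box matching with variable spacer

test_that("a planted conformant box is found with its spacer and distance", {
  region <- paste0(strrep("T", 40), "TGGAACT", strrep("A", 15), "CCACGTAG",
                   strrep("T", 60))
  hits <- scan_region(region)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$spacer_len, 15L)
  expect_equal(hits$gene_distance, 60L)
  expect_equal(hits$match_start, 41L)
  expect_equal(hits$matched_sequence,
               paste0("TGGAACT", strrep("A", 15), "CCACGTAG"))
})

test_that("destroying the GGAAC core abolishes the match", {
  region <- paste0(strrep("T", 40), "TGGTACT", strrep("A", 15), "CCACGTAG",
                   strrep("T", 60))
  expect_equal(nrow(scan_region(region)), 0L)
})

test_that("both consensus renderings are available and differ", {
  screening <- hrp_box_pattern("screening")
  consensus <- hrp_box_pattern("consensus")
  # GGAACC...CCACGTA satisfies the consensus form; the trailing G required
  # by the screening form is absent
  region <- paste0(strrep("T", 40), "GGAACC", strrep("A", 16), "CCACGTA",
                   strrep("T", 60))
  expect_equal(nrow(scan_region(region, consensus)), 1L)
  expect_equal(nrow(scan_region(region, screening)), 0L)
})

test_that("N in the subject never matches, wildcard and spacer positions included", {
  box <- function(wild, spacer1) paste0(strrep("T", 40), wild, "GGAACT",
                                        spacer1, strrep("A", 14), "CCACGTAG",
                                        strrep("T", 60))
  expect_equal(nrow(scan_region(box("T", "A"))), 1L)
  expect_equal(nrow(scan_region(box("N", "A"))), 0L)  # N at a wildcard slot
  expect_equal(nrow(scan_region(box("T", "N"))), 0L)  # N inside the spacer
})

test_that("two spacer lengths can complete a match at one anchor", {
  pat <- motif_pattern("toy", list(motif_fixed("GG"), motif_spacer(2, 3),
                                   motif_fixed("AAAA")))
  region <- paste0("GGTTAAAAA", strrep("C", 40))
  hits <- scan_region(region, pat, min_dist = 0, max_dist = 100)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$match_start, c(1L, 1L))
  expect_equal(sort(hits$spacer_len), c(2L, 3L))
  # brute-force enumeration agrees
  oracle <- oracle_scan(region, list(list(seq = "GG"), list(min = 2L, max = 3L),
                                     list(seq = "AAAA")), 0, 100)
  expect_equal(hits[names(oracle)], oracle)
})

test_that("scanner equals exhaustive enumeration on random regions", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:150) {
    len <- sample(40:200, 1)
    region <- random_dna_string(len, with_n = i %% 7 == 0)
    # spike half the regions with a partial or complete box to exercise hits
    if (i %% 2 == 0 && len >= 120) {
      ins <- paste0("AGGAACC", strrep("G", sample(15:16, 1)), "CCACTTAG")
      at <- sample(1:(len - nchar(ins)), 1)
      substr(region, at, at + nchar(ins) - 1L) <- ins
    }
    got <- scan_region(region, min_dist = 0, max_dist = len)
    want <- oracle_scan(region, hrp_elements, 0, len)
    expect_equal(got[c("match_start", "match_end", "spacer_len",
                       "gene_distance")], want)
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 25)   # the comparison actually exercised matches
})

test_that("mismatch allowance follows the per-element budget", {
  # one divergent base in the CCACNNAG element
  region <- paste0(strrep("T", 40), "TGGAACT", strrep("A", 15), "CCTCGTAG",
                   strrep("T", 60))
  expect_equal(nrow(scan_region(region)), 0L)
  h1 <- scan_region(region, max_mismatch = 1)
  expect_equal(nrow(h1), 1L)
  expect_equal(oracle_scan(region, hrp_elements, 30, 300, max_mismatch = 1L)$match_start,
               h1$match_start)
  # two mismatches in one element exceed the budget of one
  region2 <- paste0(strrep("T", 40), "TGGAACT", strrep("A", 15), "CGTCGTAG",
                    strrep("T", 60))
  expect_equal(nrow(scan_region(region2, max_mismatch = 1)), 0L)
})

test_that("widening the distance interval never removes hits", {
  set.seed(7)
  for (i in 1:20) {
    region <- random_dna_string(200)
    ins <- paste0("AGGAACC", strrep("A", 15), "CCACTTAG")
    at <- sample(1:(200 - nchar(ins)), 1)
    substr(region, at, at + nchar(ins) - 1L) <- ins
    narrow <- scan_region(region, min_dist = 30, max_dist = 120)
    wide <- scan_region(region, min_dist = 0, max_dist = 200)
    key <- function(h) paste(h$match_start, h$spacer_len)
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("scan output is deterministic and ordered", {
  region <- paste0("AGGAACC", strrep("A", 15), "CCACTTAG",
                   strrep("C", 10),
                   "AGGAACC", strrep("A", 16), "CCACTTAG",
                   strrep("T", 50))
  h1 <- scan_region(region, min_dist = 0, max_dist = 300)
  h2 <- scan_region(region, min_dist = 0, max_dist = 300)
  expect_identical(h1, h2)
  expect_false(is.unsorted(h1$match_start))
})

test_that("genome screen counts genes once and picks the closest best hit", {
  # build a contig with one gene whose promoter carries two boxes
  win <- strrep("T", 331)
  b1 <- paste0("TGGAACT", strrep("A", 15), "CCACGTAG")   # distance 100
  b2 <- paste0("CGGAACA", strrep("G", 16), "CCACTTAG")   # distance 40
  substr(win, 331 - 100 - nchar(b1) + 1, 331 - 100) <- b1
  substr(win, 331 - 40 - nchar(b2) + 1, 331 - 40) <- b2
  cdsseq <- paste0("ATG", strrep("AAA", 30), "TAA")
  contig <- paste0(win, cdsseq)
  g <- annotated_genome("t", c(c1 = contig),
                        data.frame(gene_id = "g1", contig_id = "c1",
                                   start = 332L, end = 331L + nchar(cdsseq),
                                   strand = "+", stringsAsFactors = FALSE))
  tab <- screen_genome(g)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_hits, 2L)
  expect_equal(tab$best_gene_distance, 40L)
  hits <- attr(tab, "hits")
  expect_equal(nrow(hits), 2L)
  # genomic coordinates map back onto the planted positions
  expect_setequal(hits$genomic_start, c(331 - 100 - nchar(b1) + 1,
                                        331 - 40 - nchar(b2) + 1))
})

test_that("a genome without boxes yields an empty table", {
  set.seed(3)
  res <- generate_genome(synthetic_genome_config(
    genome_length = 30000, n_background_genes = 3, n_conformant_boxes = 0,
    n_decoy_boxes = 0, n_effectors = 0, n_effector_decoys = 0,
    cluster_components = character(0)), seed = 5)
  tab <- screen_genome(res$genome)
  expect_equal(nrow(tab), 0L)
})

test_that("minus-strand promoters are screened on their coding strand", {
  set.seed(8)
  res <- generate_genome(synthetic_genome_config(
    genome_length = 40000, n_background_genes = 0, n_conformant_boxes = 4,
    n_decoy_boxes = 0, n_effectors = 0, n_effector_decoys = 0,
    cluster_components = character(0)), seed = 9)
  strands <- res$genome$cds$strand
  expect_setequal(unique(strands), c("+", "-"))
  tab <- screen_genome(res$genome)
  expect_setequal(tab$gene_id, res$genome$cds$gene_id)
})
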