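# phylo: distance formulas, neighbor joining, bootstrap, Newick round trips

test_that("K80 distance matches the closed form", {
  expect_equal(k80_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  # one transition among 10 sites: P = 0.1, Q = 0
  a <- "AAAAAAAAAA"; b <- "GAAAAAAAAA"
  expect_equal(k80_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)
  expect_lt(abs(k80_distance(a, b) - 0.1116), 1e-4)
})

test_that("K80 saturation is flagged infinite with a warning", {
  # P = 0.4, Q = 0.2 over 10 sites: 1 - 2P - Q = 0
  a <- "AAAAAAAAAA"
  b <- paste0(strrep("G", 4), strrep("C", 2), strrep("A", 4))
  expect_warning(d <- k80_distance(a, b), "saturat")
  expect_identical(d, Inf)
})

test_that("gap and N columns are pairwise-deleted", {
  a <- "A-GTANGTAC"
  b <- "ACGTACGTNC"
  # comparable columns exclude positions 2, 6, 9
  expect_equal(k80_distance(a, b), 0)
  expect_error(k80_distance("----", "ACGT"), "comparable")
})

test_that("JC protein distance matches the closed form", {
  expect_equal(jc_protein_distance("MKLV", "MKLV"), 0)
  # p = 19/40 = 0.475
  a <- paste(rep("A", 40), collapse = "")
  b <- paste(c(rep("R", 19), rep("A", 21)), collapse = "")
  expect_equal(jc_protein_distance(a, b), -0.95 * log(0.5), tolerance = 1e-12)
  expect_lt(abs(jc_protein_distance(a, b) - 0.6585), 1e-4)
  # p = 0.95 saturates
  b2 <- paste(c(rep("R", 19), "A"), collapse = "")
  expect_warning(d <- jc_protein_distance(strrep("A", 20), b2), "saturat")
  expect_identical(d, Inf)
})

test_that("K80 reduces to Jukes-Cantor when transitions equal transversion halves", {
  # 3 differences in 12 sites: 1 transition, 2 transversions (P = p/3)
  a <- "AAAAAAAAAAAA"
  b <- "GCTAAAAAAAAA"   # A->G transition, A->C and A->T transversions
  p <- 3 / 12
  expect_equal(k80_distance(a, b), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-12)
})

test_that("K80 agrees with an independent implementation on random pairs", {
  set.seed(55)
  for (i in 1:20) {
    a <- random_dna_string(300)
    bb <- strsplit(a, "")[[1]]
    idx <- sample(300, 40)
    bb[idx] <- vapply(bb[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    b <- paste(bb, collapse = "")
    ref <- ape::dist.dna(ape::as.DNAbin(matrix(c(strsplit(tolower(a), "")[[1]],
                                                 strsplit(tolower(b), "")[[1]]),
                                               nrow = 2, byrow = TRUE)),
                         model = "K80")[1]
    expect_equal(k80_distance(a, b), ref, tolerance = 1e-10)
  }
})

test_that("NJ inverts path distances of a 4-taxon additive tree exactly", {
  true <- read_newick(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(true)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  tr <- neighbor_joining(D)
  expect_true(same_topology(tr, true))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  # tip branch lengths recovered
  lens <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(lens[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa use the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    true <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(true)
    ord <- sample(rownames(D))          # taxon order must not matter
    tr <- neighbor_joining(D[ord, ord])
    expect_true(same_topology(tr, true))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("NJ agrees topologically with ape's implementation on noisy data", {
  set.seed(19)
  sim <- generate_alignment("((A:0.1,B:0.12):0.08,(C:0.09,D:0.11):0.07,E:0.2);",
                            model = "k80", length = 2000, seed = 99)
  D <- distance_matrix(sim$msa, "k80")
  expect_true(same_topology(neighbor_joining(D), ape::nj(as.dist(D))))
})

test_that("degenerate equal-distance matrices give deterministic output", {
  D <- matrix(1, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(neighbor_joining(D), "symmetric")
  D2 <- matrix(c(0, NaN, NaN, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(D2), "taxa|finite")
  D3 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D3[1, 2] <- D3[2, 1] <- Inf
  expect_error(neighbor_joining(D3), "finite")
})

test_that("negative branch lengths are clamped and the deficit recorded", {
  # classic NJ negative-branch case
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 2, 9, 10, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D[1, 2] <- D[2, 1] <- 0.1   # force a negative estimate
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(nrow(attr(tr, "clamped")) >= 1)
})

test_that("bootstrap is deterministic under a fixed seed and finds a clean split", {
  # two clearly distinct clades: identical within, 50% divergent between
  # (one transition + one transversion per 4 columns keeps K80 finite)
  base1 <- strrep("ACGT", 25)
  base2 <- strrep("GAGT", 25)
  seqs <- c(t1 = base1, t2 = base1, t3 = base2, t4 = base2)
  m <- msa(seqs, type = "dna")
  b1 <- bootstrap_support(m, n_replicates = 100, model = "k80", seed = 42)
  b2 <- bootstrap_support(m, n_replicates = 100, model = "k80", seed = 42)
  expect_identical(write_newick(b1$tree), write_newick(b2$tree))
  expect_identical(b1$support, b2$support)
  expect_equal(nrow(b1$support), 1L)
  # every successful replicate preserves the split by construction;
  # saturated replicates are skipped and counted, never miscounted
  expect_equal(b1$support$support, 100)
  expect_lte(b1$n_skipped, 5L)
})

test_that("bootstrap supports lie in [0,100] and survive taxon permutation", {
  set.seed(77)
  sim <- generate_alignment("((A:0.05,B:0.07):0.05,(C:0.06,D:0.05):0.04,E:0.1);",
                            model = "k80", length = 500, seed = 3)
  m <- sim$msa
  b <- bootstrap_support(m, n_replicates = 50, model = "k80", seed = 8)
  expect_true(all(b$support$support >= 0 & b$support$support <= 100))
  perm <- sample(length(m$seqs))
  m2 <- msa(m$seqs[perm], type = "dna")
  b2 <- bootstrap_support(m2, n_replicates = 50, model = "k80", seed = 8)
  s1 <- setNames(b$support$support, b$support$bipartition)
  s2 <- setNames(b2$support$support, b2$support$bipartition)
  expect_setequal(names(s1), names(s2))
  # same resampling stream, same splits counted
  expect_equal(s1[names(s2)], s2)
})

test_that("an all-identical alignment yields the tie-broken topology at full support", {
  m <- msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT", d = "ACGTACGT"))
  b <- bootstrap_support(m, n_replicates = 20, model = "k80", seed = 1)
  expect_true(all(b$support$support == 100))
})

test_that("Newick writing quotes awkward labels and round-trips", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  taxa <- c("A", "tax,1", "C (v2)")
  dimnames(D) <- list(taxa, taxa)
  tr <- neighbor_joining(D)
  nwk <- write_newick(tr)
  expect_match(nwk, "'tax,1'", fixed = TRUE)
  back <- read_newick(text = nwk)
  expect_setequal(back$tip.label, taxa)
})

test_that("Newick files round-trip topology, lengths and supports", {
  set.seed(202)
  tr <- random_additive_tree(10)
  tr$node.label <- as.character(sample(50:100, tr$Nnode, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(stats::na.omit(back$node.label), stats::na.omit(tr$node.label))
})
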