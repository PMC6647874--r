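# effector_filter: N-terminal features typical of T3SS-secreted proteins
# and classification of hrp-box-positive genes as putative effectors.
#
# The classical criteria: abundance of serine and of polar residues in the
# N-terminal window, at most one acidic residue in the first 12 positions,
# and an aliphatic residue at position 3 or 4 (Met = position 1).

#' Default residue sets and thresholds for the effector screen
#'
#' The literature the criteria come from never enumerates the residue sets
#' or quantifies "abundance"; these defaults are therefore explicit and
#' configurable, and every emitted candidate table carries the per-criterion
#' flags so alternative thresholds can be replayed from the feature table.
#'
#' The acidic-residue criterion is ambiguous in the source literature (a cap
#' of one acidic residue in the first 12 positions vs an *abundance* of
#' acidic residues); `acidic_rule` selects among `"at_most_one"` (default),
#' `"none"` and `"at_least_one"`, and the choice is recorded in every
#' report.
#'
#' @param window N-terminal window in amino acids (Met = position 1)
#' @param min_ser_frac minimum fraction of Ser in the window
#' @param min_polar_frac minimum fraction of polar residues in the window
#' @param acidic_rule `"at_most_one"`, `"none"` or `"at_least_one"` acidic
#'   residue (D/E) among positions 1-12
#' @param require_aliphatic_34 require an aliphatic residue at position 3
#'   or 4?
#' @param polar_set,aliphatic_set residue sets used by the criteria
#' @return a list of class `effector_thresholds`
#' @export
effector_thresholds <- function(window = 50L,
                                min_ser_frac = 0.10,
                                min_polar_frac = 0.40,
                                acidic_rule = c("at_most_one", "none",
                                                "at_least_one"),
                                require_aliphatic_34 = TRUE,
                                polar_set = c("S", "T", "N", "Q", "C", "Y",
                                              "G", "H"),
                                aliphatic_set = c("I", "L", "V", "A", "P")) {
  acidic_rule <- match.arg(acidic_rule)
  stopifnot(window >= 12L, min_ser_frac >= 0, min_ser_frac <= 1,
            min_polar_frac >= 0, min_polar_frac <= 1)
  structure(list(window = as.integer(window), min_ser_frac = min_ser_frac,
                 min_polar_frac = min_polar_frac, acidic_rule = acidic_rule,
                 require_aliphatic_34 = require_aliphatic_34,
                 polar_set = polar_set, aliphatic_set = aliphatic_set),
            class = "effector_thresholds")
}

#' Compute N-terminal sequence features of a protein
#'
#' Fractions are computed over the first `min(window, length)` residues,
#' counting the initiator Met as position 1.
#'
#' @param protein amino-acid string, length >= 4
#' @param window N-terminal window in aa (>= 12)
#' @param thresholds an [effector_thresholds()] supplying the residue sets
#' @param gene_id optional id carried through to the output
#' @return one-row data.frame with `gene_id`, `window_len` (residues
#'   actually used), `ser_frac`, `polar_frac`, `n_acidic_first12`,
#'   `aliphatic_pos34`
#' @export
compute_features <- function(protein, window = NULL,
                             thresholds = effector_thresholds(),
                             gene_id = NA_character_) {
  window <- window %||% thresholds$window
  stopifnot(window >= 12L)
  if (is.na(protein) || nchar(protein) < 4L) {
    stopf("protein shorter than 4 aa: position 3/4 criterion undefined")
  }
  aa <- chars(toupper(protein))
  w <- min(window, length(aa))
  win <- aa[seq_len(w)]
  first12 <- aa[seq_len(min(12L, length(aa)))]
  data.frame(
    gene_id = gene_id,
    window_len = w,
    ser_frac = sum(win == "S") / w,
    polar_frac = sum(win %in% thresholds$polar_set) / w,
    n_acidic_first12 = sum(first12 %in% c("D", "E")),
    aliphatic_pos34 = aa[3] %in% thresholds$aliphatic_set ||
      aa[4] %in% thresholds$aliphatic_set,
    stringsAsFactors = FALSE)
}

#' Classify a feature vector as putative effector or not
#'
#' Each enabled criterion is evaluated independently and recorded as a
#' pass/fail flag; the decision is the conjunction of all enabled criteria
#' and hrp-box positivity.
#'
#' @param features one-row data.frame from [compute_features()]
#' @param thresholds an [effector_thresholds()]
#' @param hrp_box_positive does the gene carry an hrp box at admissible
#'   distance?
#' @return one-row data.frame: the features, per-criterion flags
#'   (`pass_ser`, `pass_polar`, `pass_acidic`, `pass_aliphatic`) and
#'   `is_putative_effector`
#' @export
classify <- function(features, thresholds = effector_thresholds(),
                     hrp_box_positive = TRUE) {
  pass_ser <- features$ser_frac >= thresholds$min_ser_frac
  pass_polar <- features$polar_frac >= thresholds$min_polar_frac
  pass_acidic <- switch(thresholds$acidic_rule,
                        at_most_one = features$n_acidic_first12 <= 1L,
                        none = features$n_acidic_first12 == 0L,
                        at_least_one = features$n_acidic_first12 >= 1L)
  pass_aliphatic <- if (thresholds$require_aliphatic_34)
    features$aliphatic_pos34 else TRUE
  cbind(features,
        data.frame(pass_ser = pass_ser, pass_polar = pass_polar,
                   pass_acidic = pass_acidic, pass_aliphatic = pass_aliphatic,
                   hrp_box_positive = hrp_box_positive,
                   is_putative_effector = pass_ser & pass_polar &
                     pass_acidic & pass_aliphatic & hrp_box_positive))
}

#' Run the effector screen on the hrp-box-positive genes of a genome
#'
#' Candidates are evaluated only for genes present in the motif table
#' (guaranteeing that the putative-effector set is a subset of the
#' hrp-box-positive set). Genes whose protein is missing or shorter than
#' 12 aa (so the first-12-positions criterion is undefined) are recorded
#' with status `"unevaluable"`, never silently dropped.
#'
#' @param genome an [annotated_genome()]
#' @param motif_table result of [screen_genome()] on the same genome
#' @param thresholds an [effector_thresholds()]
#' @return data.frame with one row per hrp-box-positive gene: features,
#'   per-criterion flags, `status` (`"evaluated"`/`"unevaluable"`) and
#'   `is_putative_effector`
#' @export
run_effector_screen <- function(genome, motif_table,
                                thresholds = effector_thresholds()) {
  empty <- data.frame(gene_id = character(), window_len = integer(),
                      ser_frac = numeric(), polar_frac = numeric(),
                      n_acidic_first12 = integer(), aliphatic_pos34 = logical(),
                      pass_ser = logical(), pass_polar = logical(),
                      pass_acidic = logical(), pass_aliphatic = logical(),
                      hrp_box_positive = logical(),
                      is_putative_effector = logical(), status = character(),
                      stringsAsFactors = FALSE)
  if (nrow(motif_table) == 0L) return(empty)
  rows <- lapply(motif_table$gene_id, function(g) {
    i <- match(g, genome$cds$gene_id)
    prot <- if (is.na(i)) NA_character_ else genome$cds$protein[i]
    if (is.na(prot) || nchar(prot) < 12L) {
      r <- data.frame(gene_id = g, window_len = NA_integer_,
                      ser_frac = NA_real_, polar_frac = NA_real_,
                      n_acidic_first12 = NA_integer_,
                      aliphatic_pos34 = NA, pass_ser = NA, pass_polar = NA,
                      pass_acidic = NA, pass_aliphatic = NA,
                      hrp_box_positive = TRUE, is_putative_effector = FALSE,
                      status = "unevaluable", stringsAsFactors = FALSE)
      return(r)
    }
    feats <- compute_features(prot, thresholds = thresholds, gene_id = g)
    r <- classify(feats, thresholds, hrp_box_positive = TRUE)
    r$status <- "evaluated"
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an effector candidate table as TSV or JSON
#'
#' @param candidates result of [run_effector_screen()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_candidates_tsv <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
write_candidates_json <- function(candidates, path) {
  jsonlite::write_json(candidates, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
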