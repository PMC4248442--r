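AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Tuberculist-style functional category labels used by the fixtures.
FUNCTIONAL_CATEGORIES <- c(
  "intermediary metabolism and respiration",
  "cell wall and cell processes",
  "lipid metabolism",
  "information pathways",
  "regulatory proteins",
  "insertion seqs and phages",
  "conserved hypotheticals"
)

#' Simulate a reference and a query proteome with known homology structure
#'
#' Builds a desk-scale stand-in for a cross-species annotation transfer:
#' a reference proteome of `n_ref` random proteins carrying functional
#' categories and (for some) EC numbers, and a query proteome containing
#' one ortholog per reference protein (a point-mutated copy whose global
#' identity targets 60--95%), `config$n_duplicate_sets` within-proteome
#' paralog pairs (a second copy of an ortholog mutated at ~8%, placed
#' far away on the simulated chromosome), and a few unmatchable random
#' sequences. Ground truth records the intended ortholog pairing, the
#' paralog sets and the per-pair identity targets.
#'
#' @param config A [fixture_config()].
#' @param n_ref Number of reference proteins (default 48).
#' @param n_unmatched Number of query-only random sequences (default 6).
#' @param ortholog_identity Range of target percent identities for
#'   ortholog pairs (default `c(60, 95)`).
#' @param paralog_identity Target percent identity of paralog copies
#'   (default 92).
#' @return A list with `ref` and `query` ([Biostrings::AAStringSet]
#'   proteomes), `ref_annotations` and `query_annotations` (data.frames
#'   with `locus`, `category`, `ec`, `start`, `end`, `strand`), and
#'   `ground_truth` (list with `ortholog_pairs`, `paralog_sets`,
#'   `identity_targets`).
#' @export
generate_proteomes <- function(config, n_ref = 48L, n_unmatched = 6L,
                               ortholog_identity = c(60, 95),
                               paralog_identity = 92) {
  stopifnot(inherits(config, "fixture_config"))
  n_par <- config$n_duplicate_sets
  if (n_par > n_ref) stopf("n_duplicate_sets (%d) exceeds n_ref (%d)", n_par, n_ref)

  with_seed(sub_seed(config$seed, "proteomes"), {
    lens <- sample(60:120, n_ref, replace = TRUE)
    ref_seqs <- vapply(lens, function(L) paste(resample(rep(AA20, 10), L),
                                               collapse = ""), character(1))
    ref_loci <- sprintf("Rv%04d", seq_len(n_ref))

    targets <- stats::runif(n_ref, ortholog_identity[1], ortholog_identity[2])
    q_orth <- mapply(mutate_sequence, ref_seqs, 1 - targets / 100)
    q_loci <- sprintf("MSMEG_%04d", seq_len(n_ref))

    par_of <- sort(resample(seq_len(n_ref), n_par))
    q_par <- vapply(par_of, function(i) {
      mutate_sequence(q_orth[i], 1 - paralog_identity / 100)
    }, character(1))
    par_loci <- sprintf("MSMEG_%04d", n_ref + seq_len(n_par))

    un_seqs <- vapply(sample(60:120, n_unmatched, replace = TRUE), function(L) {
      paste(resample(rep(AA20, 10), L), collapse = "")
    }, character(1))
    un_loci <- sprintf("MSMEG_%04d", n_ref + n_par + seq_len(n_unmatched))

    query_seqs <- c(q_orth, q_par, un_seqs)
    query_loci <- c(q_loci, par_loci, un_loci)

    ref <- Biostrings::AAStringSet(stats::setNames(ref_seqs, ref_loci))
    query <- Biostrings::AAStringSet(stats::setNames(query_seqs, query_loci))

    cats <- resample(rep(FUNCTIONAL_CATEGORIES, ceiling(n_ref / 7)), n_ref)
    has_ec <- stats::runif(n_ref) < 0.6
    ecs <- ifelse(has_ec,
                  sprintf("%d.%d.%d.%d", sample(1:6, n_ref, replace = TRUE),
                          sample(1:9, n_ref, replace = TRUE),
                          sample(1:9, n_ref, replace = TRUE),
                          sample(1:99, n_ref, replace = TRUE)),
                  NA_character_)
    ref_ann <- data.frame(locus = ref_loci, category = cats, ec = ecs,
                          start = seq_len(n_ref) * 3000L,
                          end = seq_len(n_ref) * 3000L + lens * 3L,
                          strand = resample(rep(c("+", "-"), n_ref), n_ref),
                          stringsAsFactors = FALSE)

    # paralog copies land in a distant chromosomal region (duplicated genes
    # are typically far apart, under separate transcriptional control)
    nq <- length(query_loci)
    starts <- c(seq_len(n_ref) * 3000L,
                3500000L + seq_len(n_par) * 3000L,
                6000000L + seq_len(n_unmatched) * 3000L)
    query_ann <- data.frame(locus = query_loci, category = "unassigned",
                            ec = NA_character_, start = starts,
                            end = starts + nchar(query_seqs) * 3L,
                            strand = resample(rep(c("+", "-"), nq), nq),
                            stringsAsFactors = FALSE)

    gt_pairs <- data.frame(query = q_loci, ref = ref_loci,
                           target_identity = targets, stringsAsFactors = FALSE)
    gt_sets <- data.frame(set_id = sprintf("par%02d", seq_len(n_par)),
                          member1 = q_loci[par_of], member2 = par_loci,
                          target_identity = paralog_identity,
                          stringsAsFactors = FALSE)
    list(ref = ref, query = query,
         ref_annotations = ref_ann, query_annotations = query_ann,
         ground_truth = list(ortholog_pairs = gt_pairs, paralog_sets = gt_sets))
  })
}

# Substitute a fixed fraction of positions with a different residue, so the
# gapless identity equals 1 - rate up to rounding.
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(rate * length(chars))
  if (n_mut == 0) return(seq)
  pos <- resample(seq_along(chars), n_mut)
  for (p in pos) chars[p] <- resample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}
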