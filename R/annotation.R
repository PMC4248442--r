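#' Percent identity of two protein sequences under global alignment
#'
#' Aligns the two sequences end-to-end with a Needleman--Wunsch global
#' alignment (match +1, mismatch -1, linear gap -2, computed with
#' [Biostrings::pairwiseAlignment()]) and returns
#' `100 * matched columns / alignment length`, where the alignment
#' length includes gap columns. The result is symmetric in its
#' arguments and lies in `[0, 100]`.
#'
#' @param a,b Amino-acid strings (20 standard residues plus `X`).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("HEAGAWGHEE", "HEAGAWGHEE")
#' @export
pairwise_identity <- function(a, b) {
  check_protein(a); check_protein(b)
  # canonical argument order guarantees exact symmetry even when the DP
  # has several co-optimal tracebacks
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- align_global(a, b)
  identity_from_alignment(aln$pattern, aln$subject)
}

check_protein <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(s)) {
    stopf("sequences must be non-empty strings")
  }
  bad <- setdiff(strsplit(s, "")[[1]], c(AA20, "X"))
  if (length(bad)) {
    stopf("illegal residue(s) %s: alphabet is the 20 standard amino acids plus X",
          paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# match +1 / mismatch -1 substitution matrix over the fixture alphabet
identity_submat <- function() {
  alpha <- c(AA20, "X")
  m <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(m) <- 1
  m
}

align_global <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = identity_submat(), gapOpening = 0, gapExtension = 2)
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

identity_from_alignment <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  100 * sum(pc == sc & pc != "-") / length(pc)
}

# Vectorized identity for one pairwiseAlignment result. pattern()/subject()
# trim terminal-overhang columns, so those are added back to the alignment
# length; they contribute gap columns only, never matches.
identity_from_pa <- function(aln, np, ns) {
  pp <- as.character(Biostrings::pattern(aln))
  ss <- as.character(Biostrings::subject(aln))
  matches <- mapply(function(p, s) {
    pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
    sum(pc == sc & pc != "-")
  }, pp, ss, USE.NAMES = FALSE)
  left <- (BiocGenerics::start(Biostrings::pattern(aln)) - 1L) +
    (BiocGenerics::start(Biostrings::subject(aln)) - 1L)
  right <- (np - BiocGenerics::end(Biostrings::pattern(aln))) +
    (ns - BiocGenerics::end(Biostrings::subject(aln)))
  100 * matches / (nchar(pp) + left + right)
}

# Dense percent-identity matrix between two sets of sequences (rows = a).
identity_matrix <- function(a, b) {
  a_chr <- stats::setNames(as.character(a), names(a))
  b_chr <- stats::setNames(as.character(b), names(b))
  m <- matrix(NA_real_, length(a_chr), length(b_chr),
              dimnames = list(names(a_chr), names(b_chr)))
  submat <- identity_submat()
  aset <- Biostrings::AAStringSet(a_chr)
  np <- nchar(a_chr)
  for (j in seq_along(b_chr)) {
    aln <- Biostrings::pairwiseAlignment(
      aset, Biostrings::AAString(b_chr[j]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    m[, j] <- identity_from_pa(aln, np, nchar(b_chr[j]))
  }
  m
}

#' Bidirectional best hits between two proteomes
#'
#' A pair `(q, r)` is reported when `r` is `q`'s unique top-identity hit
#' in the reference, `q` is `r`'s unique top-identity hit in the query,
#' and the identity is at least `threshold`. Identities are rounded to
#' 4 decimals before comparing, and exactly tied top hits disqualify a
#' locus from having a "unique" top hit; remaining order dependence is
#' removed by lexicographic locus order. The result is a partial
#' bijection: no locus appears in more than one pair.
#'
#' @param query,ref Named [Biostrings::AAStringSet] proteomes (or named
#'   character vectors of sequences).
#' @param threshold Minimum percent identity for a reported pair
#'   (default 30).
#' @return A list of class `homology_result` with `pairs` (data.frame:
#'   `query`, `ref`, `identity`), `threshold`, `unmatched_query` and
#'   `unmatched_ref` (character vectors of loci).
#' @export
bidirectional_best_hits <- function(query, ref, threshold = 30) {
  query <- as_named_seqs(query, "query")
  ref <- as_named_seqs(ref, "ref")
  m <- round(identity_matrix(query, ref), 4)

  best_of_row <- unique_top(m)
  best_of_col <- unique_top(t(m))

  pairs <- list()
  for (qi in seq_len(nrow(m))) {
    ri <- best_of_row[qi]
    if (is.na(ri)) next
    if (!isTRUE(best_of_col[[ri]] == qi)) next
    if (m[qi, ri] < threshold) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      query = rownames(m)[qi], ref = colnames(m)[ri],
      identity = m[qi, ri], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(query = character(0), ref = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$query), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, threshold = threshold,
                 unmatched_query = setdiff(rownames(m), pairs$query),
                 unmatched_ref = setdiff(colnames(m), pairs$ref)),
            class = "homology_result")
}

# Index of the unique maximum of each row (NA when the top is tied);
# among equal-identity candidates never reached (ties disqualify), the
# lexicographically first column would win -- documented determinism.
unique_top <- function(m) {
  apply(m, 1L, function(row) {
    ord <- order(-row, colnames(m) %||% seq_along(row))
    top <- ord[1]
    if (length(row) > 1L && row[ord[2]] == row[top]) return(NA_integer_)
    top
  })
}

as_named_seqs <- function(x, what) {
  if (inherits(x, "AAStringSet")) x <- stats::setNames(as.character(x), names(x))
  if (!is.character(x) || length(x) == 0L) stopf("`%s` proteome must be non-empty", what)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stopf("`%s` proteome needs unique locus names", what)
  }
  x
}

#' Transfer functional categories along best-hit pairs
#'
#' Paired query loci inherit the category of their reference partner;
#' unpaired loci are labelled `"unassigned"`. If a locus would receive
#' several categories (impossible under the best-hit bijection, but
#' possible with externally supplied pairs), the single most relevant
#' one is chosen by the fixed priority order of `category_priority`.
#'
#' @param result A `homology_result` from [bidirectional_best_hits()],
#'   or a data.frame of `query`/`ref` pairs.
#' @param ref_annotations data.frame with columns `locus`, `category`
#'   for the reference proteome.
#' @param query_loci Character vector of all query loci to annotate.
#' @param category_priority Character vector; earlier entries win
#'   conflicts.
#' @return data.frame with columns `locus`, `category`.
#' @export
transfer_categories <- function(result, ref_annotations, query_loci,
                                category_priority = FUNCTIONAL_CATEGORIES) {
  pairs <- if (inherits(result, "homology_result")) result$pairs else result
  missing_ref <- setdiff(pairs$ref, ref_annotations$locus)
  if (length(missing_ref)) {
    stopf("reference loci in pairing absent from annotations: %s",
          paste(utils::head(missing_ref, 3), collapse = ", "))
  }
  cat_of <- stats::setNames(ref_annotations$category, ref_annotations$locus)
  out <- stats::setNames(rep("unassigned", length(query_loci)), query_loci)
  for (q in unique(pairs$query)) {
    cats <- unique(cat_of[pairs$ref[pairs$query == q]])
    if (length(cats) > 1L) {
      prio <- match(cats, category_priority)
      cats <- cats[order(ifelse(is.na(prio), Inf, prio), cats)][1]
    }
    if (!q %in% names(out)) stopf("query locus %s not in `query_loci`", q)
    out[q] <- cats
  }
  data.frame(locus = names(out), category = unname(out), stringsAsFactors = FALSE)
}

#' Detect duplicate genes (paralog sets) within one proteome
#'
#' Computes the all-vs-all global-alignment identity matrix (diagonal
#' 100) and reports paralog sets as the connected components, with two
#' or more members, of the graph whose edges join loci with identity at
#' or above `threshold` (self-edges excluded). When genomic `start`
#' coordinates are supplied the pairwise chromosomal separations of
#' within-set members are reported, since duplicated genes typically
#' lie far apart on the chromosome.
#'
#' @param proteome Named [Biostrings::AAStringSet] or named character
#'   vector.
#' @param threshold Percent-identity edge threshold (default 50).
#' @param annotations Optional data.frame with `locus` and `start` for
#'   genomic-separation reporting.
#' @return A list with `sets` (list of character vectors of loci),
#'   `matrix` (dense identity matrix, exportable for dot-plot
#'   rendering) and `separations` (data.frame of within-set pairwise bp
#'   distances, or NULL).
#' @export
find_duplicates <- function(proteome, threshold = 50, annotations = NULL) {
  seqs <- as_named_seqs(proteome, "proteome")
  m <- identity_matrix(seqs, seqs)
  diag(m) <- 100
  # identity is symmetric; co-optimal tracebacks can differ by direction,
  # so the upper triangle is taken as canonical
  m[lower.tri(m)] <- t(m)[lower.tri(m)]

  n <- nrow(m)
  adj <- (m >= threshold)
  diag(adj) <- FALSE
  # union-find over the >=threshold graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in which(adj[i, ])) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sets <- split(rownames(m), comp)
  sets <- unname(sets[vapply(sets, length, integer(1)) >= 2L])
  sets <- lapply(sets, sort)
  sets <- sets[order(vapply(sets, `[`, character(1), 1))]

  seps <- NULL
  if (!is.null(annotations) && all(c("locus", "start") %in% names(annotations))) {
    start_of <- stats::setNames(annotations$start, annotations$locus)
    rows <- list()
    for (s in sets) {
      cmb <- utils::combn(s, 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        rows[[length(rows) + 1L]] <- data.frame(
          locus1 = a, locus2 = b,
          separation_bp = abs(start_of[[a]] - start_of[[b]]),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) seps <- do.call(rbind, rows)
  }
  list(sets = sets, matrix = m, separations = seps)
}

#' Distribution of enzymes over top-level EC classes
#'
#' Counts annotated loci per top-level Enzyme Commission class (1
#' oxidoreductases ... 6 ligases). Loci without an EC annotation are
#' excluded; malformed EC strings trigger a per-record warning and are
#' excluded, so the counts sum to the number of well-formed
#' EC-annotated loci.
#'
#' @param annotations data.frame with columns `locus` and `ec`
#'   (`NA` = no annotation).
#' @return Named integer vector of length 6 (`"1"` ... `"6"`).
#' @examples
#' ec_class_distribution(data.frame(locus = c("a", "b"),
#'                                  ec = c("1.1.1.1", "5.3.1.1")))
#' @export
ec_class_distribution <- function(annotations) {
  counts <- stats::setNames(integer(6), as.character(1:6))
  ecs <- annotations$ec[!is.na(annotations$ec) & nzchar(annotations$ec)]
  for (i in seq_along(ecs)) {
    top <- sub("^([0-9]+)\\..*$", "\\1", ecs[i])
    if (!grepl("^[1-6]$", top) || !grepl("^[0-9]+(\\.[0-9n-]+){3}$", ecs[i])) {
      warning(sprintf("malformed EC string '%s' excluded", ecs[i]), call. = FALSE)
      next
    }
    counts[top] <- counts[top] + 1L
  }
  counts
}
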