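# Independent oracles used by the tests. Deliberately naive: full DP
# tables, exhaustive enumeration, brute-force recounts.

# Needleman-Wunsch oracle: full DP table (match +1 / mismatch -1 /
# linear gap -2), optimal score, and the set of percent identities
# (matched columns / alignment length) attained by *all* co-optimal
# alignments, enumerated by traceback. Only for short sequences.
nw_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n)
  S[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], 1, -1),
                           S[i, j + 1] - 2,
                           S[i + 1, j] - 2)
  }
  # enumerate all optimal tracebacks, collecting (matches, columns)
  idents <- new.env()
  walk <- function(i, j, matches, cols) {
    if (i == 0 && j == 0) {
      assign(sprintf("%d/%d", matches, cols), TRUE, envir = idents)
      return(invisible())
    }
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j], 1, -1)) {
      walk(i - 1, j - 1, matches + (A[i] == B[j]), cols + 1)
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) walk(i - 1, j, matches, cols + 1)
    if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] - 2) walk(i, j - 1, matches, cols + 1)
  }
  walk(n, m, 0, 0)
  pairs <- do.call(rbind, lapply(ls(idents), function(k) {
    as.numeric(strsplit(k, "/")[[1]])
  }))
  list(score = S[n + 1, m + 1],
       identities = sort(unique(100 * pairs[, 1] / pairs[, 2])))
}

# Brute-force BBH oracle: recompute the identity matrix cell by cell via
# the package's pairwise_identity, then apply the BBH definition naively.
bbh_oracle <- function(query, ref, threshold) {
  qn <- names(query); rn <- names(ref)
  m <- matrix(NA_real_, length(qn), length(rn), dimnames = list(qn, rn))
  for (q in qn) for (r in rn) m[q, r] <- round(pairwise_identity(query[[q]], ref[[r]]), 4)
  pairs <- list()
  for (q in qn) {
    best_r <- rn[which(m[q, ] == max(m[q, ]))]
    if (length(best_r) != 1) next
    best_q <- qn[which(m[, best_r] == max(m[, best_r]))]
    if (length(best_q) != 1 || best_q != q) next
    if (m[q, best_r] < threshold) next
    pairs[[length(pairs) + 1]] <- data.frame(query = q, ref = best_r,
                                             identity = m[q, best_r])
  }
  if (length(pairs)) do.call(rbind, pairs) else
    data.frame(query = character(0), ref = character(0), identity = numeric(0))
}

# Exhaustive average-linkage agglomeration on a distance matrix:
# repeatedly merge the closest pair of clusters, recomputing average
# inter-cluster distances from the raw matrix.
average_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
      height = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Clusters of an hclust tree in merge order, as sorted member sets.
hclust_merge_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# Minimal flagged-expression table for rule-level tests.
make_flags <- function(loci, expressed, above_median = expressed,
                       norm_avg = ifelse(expressed, 1, -1)) {
  data.frame(gene_locus = loci, norm_avg = norm_avg,
             expressed = expressed, above_median = above_median,
             stringsAsFactors = FALSE)
}

# Brute-force pathway coverage recount.
coverage_oracle <- function(pw, flags) {
  hit <- 0
  for (st in pw$steps) {
    any_expr <- FALSE
    for (g in st$genes) {
      row <- which(flags$gene_locus == g)
      if (length(row) && flags$expressed[row]) any_expr <- TRUE
    }
    if (any_expr) hit <- hit + 1
  }
  hit / length(pw$steps)
}
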