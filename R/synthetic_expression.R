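#' Simulate a two-replicate expression array with embedded duplicate-gene sets
#'
#' Draws a shared per-gene signal on the log2 scale and adds independent
#' replicate noise so that the noise fraction of total variance equals
#' `config$replicate_noise_ratio_expr`; the expected replicate Pearson
#' correlation is therefore `1 - ratio` (0.99 at the default). Raw
#' intensities are obtained by exponentiation around a positive baseline,
#' so they are strictly positive, and continuous draws make ties events
#' of probability zero.
#'
#' Duplicate-gene (paralog) sets are embedded by selection rather than by
#' overwriting values: `n_duplicate_sets` pairs are chosen such that one
#' member's averaged normalized value lies above the 60th percentile
#' (hence above the median, with margin) and the other's below the 20th
#' percentile (below the median and below the default "expressed" cut).
#' Selection leaves the marginal distribution, and thus the replicate
#' correlation calibration, untouched.
#'
#' @param config A [fixture_config()].
#' @return A list with
#'   \describe{
#'     \item{expression}{data.frame with columns `gene_locus`, `probe_id`,
#'       `raw_rep1`, `raw_rep2` (positive fluorescence units).}
#'     \item{ground_truth}{list with `duplicate_sets`, a data.frame of
#'       columns `set_id`, `locus`, `active` (exactly one active member
#'       per set).}
#'   }
#' @examples
#' fx <- generate_expression(fixture_config(seed = 1, n_genes = 500))
#' cor(log2(fx$expression$raw_rep1), log2(fx$expression$raw_rep2))
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_genes
  ratio <- config$replicate_noise_ratio_expr
  if (n <= 0) stopf("n_genes must be positive")

  with_seed(sub_seed(config$seed, "expression"), {
    # signal sd 1; noise variance r/(1-r) gives noise/(signal+noise) = r
    signal <- stats::rnorm(n)
    noise_sd <- if (ratio == 0) 0 else sqrt(ratio / (1 - ratio))
    rep1 <- signal + stats::rnorm(n, sd = noise_sd)
    rep2 <- signal + stats::rnorm(n, sd = noise_sd)

    locus <- sprintf("MSMEG_%04d", seq_len(n))
    expr <- data.frame(
      gene_locus = locus,
      probe_id = sprintf("P%05d", seq_len(n)),
      raw_rep1 = 2^(rep1 + 8),   # +8 shifts the log2 baseline; raw > 0 always
      raw_rep2 = 2^(rep2 + 8),
      stringsAsFactors = FALSE
    )

    gt_sets <- select_duplicate_sets(expr, config$n_duplicate_sets)
    list(expression = expr, ground_truth = list(duplicate_sets = gt_sets))
  })
}

# Pick n_sets (active, silent) gene pairs from the already-drawn values:
# active member above the 60th percentile of averaged normalized values,
# silent member below the 20th. Uses the current RNG stream.
select_duplicate_sets <- function(expr, n_sets) {
  if (n_sets == 0L) {
    return(data.frame(set_id = character(0), locus = character(0),
                      active = logical(0), stringsAsFactors = FALSE))
  }
  avg <- (log2(expr$raw_rep1) + log2(expr$raw_rep2)) / 2
  hi_pool <- which(avg > stats::quantile(avg, 0.60, type = 7))
  lo_pool <- which(avg < stats::quantile(avg, 0.20, type = 7))
  if (length(hi_pool) < n_sets || length(lo_pool) < n_sets) {
    stopf("array too small to embed %d duplicate sets", n_sets)
  }
  hi <- sample(hi_pool, n_sets)
  lo <- sample(lo_pool, n_sets)
  data.frame(
    set_id = rep(sprintf("dup%02d", seq_len(n_sets)), each = 2L),
    locus = as.vector(rbind(expr$gene_locus[hi], expr$gene_locus[lo])),
    active = rep(c(TRUE, FALSE), times = n_sets),
    stringsAsFactors = FALSE
  )
}

#' Simulate pathway definitions with known feasibility status
#'
#' Builds `config$n_pathways` ordered-step pathway definitions whose
#' member genes are drawn from the expression fixture so that the
#' intended coverage-based status holds exactly under the default
#' expression flags (expressed = averaged normalized value above the
#' 25th percentile): feasible pathways have every step covered by at
#' least one expressed gene; inactive pathways contain no expressed
#' gene at all; partially expressed pathways have coverage strictly
#' between 0 and 0.75; mostly expressed pathways have coverage in
#' `[0.75, 1)`.
#'
#' @param config A [fixture_config()].
#' @param expr The expression fixture from [generate_expression()] (the
#'   list, or its `expression` data.frame).
#' @param expressed_percentile Percentile cut defining "expressed",
#'   matching the one the classifier will use (default 25).
#' @return A list with `pathways` (a list of pathway definitions, each
#'   with `pathway_id`, `name`, `steps`; every step has `step_index`,
#'   `ec`, `genes`) and `ground_truth` (named character vector of
#'   status by pathway id).
#' @export
generate_pathways <- function(config, expr, expressed_percentile = 25) {
  stopifnot(inherits(config, "fixture_config"))
  if (is.list(expr) && !is.data.frame(expr)) expr <- expr$expression
  if (!all(c("gene_locus", "raw_rep1", "raw_rep2") %in% names(expr))) {
    stopf("`expr` is not an expression fixture table")
  }

  avg <- (log2(expr$raw_rep1) + log2(expr$raw_rep2)) / 2
  cut <- stats::quantile(avg, expressed_percentile / 100, type = 7)
  expressed_pool <- expr$gene_locus[avg > cut]
  silent_pool <- expr$gene_locus[avg <= cut]
  if (length(expressed_pool) < 10L || length(silent_pool) < 10L) {
    stopf("gene pool too small to build pathway fixtures")
  }

  comp <- config$pathway_composition
  statuses <- rep(names(comp), times = comp)

  with_seed(sub_seed(config$seed, "pathways"), {
    # shuffle so status is not a function of pathway index
    statuses <- sample(statuses)
    pathways <- vector("list", config$n_pathways)
    for (i in seq_len(config$n_pathways)) {
      pathways[[i]] <- build_pathway(sprintf("pw%03d", i), statuses[i],
                                     expressed_pool, silent_pool)
    }
    names(statuses) <- vapply(pathways, `[[`, character(1), "pathway_id")
    list(pathways = pathways, ground_truth = list(pathway_status = statuses))
  })
}

# One pathway with steps engineered to the requested coverage band.
build_pathway <- function(id, status, expressed_pool, silent_pool) {
  n_steps <- if (status == "mostly") sample(4:15, 1) else sample(3:15, 1)
  covered <- switch(status,
    feasible = n_steps,
    inactive = 0L,
    # coverage strictly below 0.75 but above 0
    partial = resample(seq_len(ceiling(0.75 * n_steps) - 1L), 1),
    # coverage in [0.75, 1)
    mostly = resample(seq.int(ceiling(0.75 * n_steps), n_steps - 1L), 1)
  )
  is_covered <- sample(rep(c(TRUE, FALSE), c(covered, n_steps - covered)))
  steps <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    n_genes <- sample(1:3, 1)
    genes <- if (is_covered[s]) {
      # at least one expressed alternative; the rest can be anything silent
      c(sample(expressed_pool, 1), sample(silent_pool, n_genes - 1L))
    } else {
      sample(silent_pool, n_genes)
    }
    steps[[s]] <- list(
      step_index = s,
      ec = sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                   sample(1:9, 1), sample(1:99, 1)),
      genes = sample(genes)  # order within a step carries no meaning
    )
  }
  list(pathway_id = id, name = paste("synthetic pathway", id), steps = steps)
}
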