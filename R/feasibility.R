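#' Classify one pathway's feasibility from expression flags
#'
#' A reaction step is covered when at least one of its alternative
#' genes is expressed; coverage is the fraction of covered steps. The
#' status is a deterministic function of coverage: `inactive` when no
#' member gene anywhere in the pathway is expressed (coverage 0),
#' `feasible` when every step is covered (coverage 1),
#' `mostly_expressed` when coverage is in `[mostly_threshold, 1)`
#' (default 0.75), and `partially_expressed` otherwise. Loci absent
#' from the expression table are counted as not expressed
#' (conservative: missing evidence penalizes coverage) and reported in
#' the `unmeasured` field.
#'
#' @param pw A pathway definition: list with `pathway_id` and `steps`,
#'   each step a list with `step_index` and non-empty `genes`.
#' @param flags Flagged expression table from [expression_flags()].
#' @param mostly_threshold Coverage cut separating `mostly_expressed`
#'   from `partially_expressed` (default 0.75).
#' @return A list of class `feasibility_call`: `pathway_id`,
#'   `coverage`, `status`, `active_gene_per_step` (list, `character(0)`
#'   where unresolved) and `unmeasured`.
#' @export
classify_pathway <- function(pw, flags, mostly_threshold = 0.75) {
  if (is.null(pw$steps) || !length(pw$steps)) {
    stopf("pathway %s has an empty step list", pw$pathway_id %||% "<unnamed>")
  }
  covered <- logical(length(pw$steps))
  active <- vector("list", length(pw$steps))
  unmeasured <- character(0)
  for (i in seq_along(pw$steps)) {
    genes <- pw$steps[[i]]$genes
    if (!length(genes)) stopf("pathway %s step %d has no genes", pw$pathway_id, i)
    ex <- flag_lookup(flags, genes, "expressed")
    unmeasured <- c(unmeasured, attr(ex, "unmeasured"))
    covered[i] <- any(ex)
    active[[i]] <- resolve_paralogs(genes, flags)$loci
  }
  coverage <- mean(covered)
  status <- status_from_coverage(coverage, mostly_threshold)
  structure(list(pathway_id = pw$pathway_id, coverage = coverage,
                 status = status, active_gene_per_step = active,
                 unmeasured = unique(unmeasured)),
            class = "feasibility_call")
}

# coverage == 0 iff no member gene is expressed, so the verbal rule
# "inactive when nothing is expressed" reduces to a coverage test.
status_from_coverage <- function(coverage, mostly_threshold = 0.75) {
  if (coverage == 0) "inactive"
  else if (coverage == 1) "feasible"
  else if (coverage >= mostly_threshold) "mostly_expressed"
  else "partially_expressed"
}

PATHWAY_STATUSES <- c("feasible", "mostly_expressed", "partially_expressed", "inactive")

#' Resolve which duplicate gene is the active one at a reaction step
#'
#' Returns every locus flagged above-median (the expressed alternative
#' in the duplicate-gene analysis). When no alternative is above the
#' median but some are expressed, the single highest-expressed locus is
#' returned (lexicographic locus order breaks exact ties). When nothing
#' is expressed the step is `unresolved`.
#'
#' @param step_genes Non-empty character vector of alternative loci.
#' @param flags Flagged expression table from [expression_flags()].
#' @return List with `loci` (character, possibly empty) and `status`
#'   (`"resolved"` or `"unresolved"`).
#' @export
resolve_paralogs <- function(step_genes, flags) {
  if (!length(step_genes)) stopf("`step_genes` must be non-empty")
  am <- flag_lookup(flags, step_genes, "above_median")
  if (any(am)) {
    return(list(loci = sort(step_genes[am]), status = "resolved"))
  }
  ex <- flag_lookup(flags, step_genes, "expressed")
  if (any(ex)) {
    lev <- flags$norm_avg[match(step_genes, flags$gene_locus)]
    lev[!ex] <- -Inf
    cand <- step_genes[which(lev == max(lev, na.rm = TRUE))]
    return(list(loci = sort(cand)[1], status = "resolved"))
  }
  list(loci = character(0), status = "unresolved")
}

#' Summarize feasibility calls
#'
#' @param calls List of `feasibility_call` objects.
#' @return List with `summary` (named counts over the four statuses,
#'   summing to the number of pathways) and `table` (per-pathway
#'   data.frame: `pathway_id`, `status`, `coverage`, `n_steps`,
#'   `active_genes`).
#' @export
feasibility_report <- function(calls) {
  ids <- vapply(calls, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids)) {
    stopf("duplicate pathway_id in calls: %s", ids[duplicated(ids)][1])
  }
  status <- vapply(calls, `[[`, character(1), "status")
  counts <- stats::setNames(integer(length(PATHWAY_STATUSES)), PATHWAY_STATUSES)
  tb <- table(factor(status, levels = PATHWAY_STATUSES))
  counts[names(tb)] <- as.integer(tb)
  tab <- data.frame(
    pathway_id = ids, status = status,
    coverage = vapply(calls, `[[`, numeric(1), "coverage"),
    n_steps = vapply(calls, function(c) length(c$active_gene_per_step), integer(1)),
    active_genes = vapply(calls, function(c) {
      paste(vapply(c$active_gene_per_step, function(g) {
        if (length(g)) paste(g, collapse = ",") else "none"
      }, character(1)), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  list(summary = counts, table = tab)
}

#' Screen a transporter locus list for expressed members
#'
#' @param transporters Character vector of transporter loci (possibly
#'   empty). Loci missing from the expression table are treated as not
#'   expressed and reported via the `unmeasured` attribute.
#' @param flags Flagged expression table from [expression_flags()].
#' @return The expressed subset of `transporters` (always a subset of
#'   the input).
#' @export
transporter_screen <- function(transporters, flags) {
  if (!length(transporters)) return(character(0))
  ex <- flag_lookup(flags, transporters, "expressed")
  out <- transporters[ex]
  attr(out, "unmeasured") <- attr(ex, "unmeasured")
  out
}
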