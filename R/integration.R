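#' Look up a condition in the compound-to-network map
#'
#' Nutrient names are matched exactly after case-folding and
#' whitespace normalization. A condition present in the table but with
#' no entry metabolite is reported as unmapped; a condition absent
#' from the table is an error (a lookup failure, not an unmapped
#' compound).
#'
#' @param condition Nutrient/condition name.
#' @param compound_map Compound-map data.frame (see
#'   [generate_compound_map()]).
#' @return List with `condition`, `mapped` (logical),
#'   `entry_metabolites`, `transporter_loci`, `enzyme_loci`,
#'   `inducible`.
#' @export
map_compound <- function(condition, compound_map) {
  key <- norm_name(condition)
  idx <- match(key, norm_name(compound_map$condition))
  if (is.na(idx)) stopf("condition '%s' absent from the compound map", condition)
  row <- compound_map[idx, ]
  mets <- split_loci(row$entry_metabolites)
  list(condition = row$condition, mapped = length(mets) > 0L,
       entry_metabolites = mets,
       transporter_loci = split_loci(row$transporter_loci),
       enzyme_loci = split_loci(row$enzyme_loci),
       inducible = isTRUE(row$inducible))
}

norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Number of mapped conditions in a compound map
#' @param compound_map Compound-map data.frame.
#' @return Integer count of conditions with at least one entry
#'   metabolite.
#' @export
count_mapped <- function(compound_map) {
  sum(nzchar(compound_map$entry_metabolites) & !is.na(compound_map$entry_metabolites))
}

#' Predict nutrient utilization from transporter and enzyme evidence
#'
#' Implements the two-clause rationalization of PM growth patterns: a
#' mapped compound is predicted `supported` iff (a) at least one
#' transporter locus is annotated for its uptake and (b) at least one
#' utilizing enzyme is expressed, or the uptake/utilization system is
#' flagged inducible by its substrate. Either failing clause is named
#' in the rationale (the way a non-expressed adenosine deaminase /
#' kinase / phosphoribosyltransferase set explains the failure to grow
#' on adenosine). Unmapped compounds yield prediction `"unknown"`.
#'
#' @param mapping A mapping record from [map_compound()].
#' @param flags Flagged expression table from [expression_flags()].
#' @return List with `condition`, `prediction` (`"supported"`,
#'   `"not_supported"` or `"unknown"`) and `rationale`.
#' @export
predict_utilization <- function(mapping, flags) {
  if (!isTRUE(mapping$mapped)) {
    return(list(condition = mapping$condition, prediction = "unknown",
                rationale = "compound not mapped onto the metabolic network"))
  }
  has_transporter <- length(mapping$transporter_loci) > 0L
  enz_expressed <- length(mapping$enzyme_loci) > 0L &&
    any(flag_lookup(flags, mapping$enzyme_loci, "expressed"))
  if (!has_transporter) {
    return(list(condition = mapping$condition, prediction = "not_supported",
                rationale = "no transporter annotated for nutrient uptake"))
  }
  if (!enz_expressed && !isTRUE(mapping$inducible)) {
    return(list(condition = mapping$condition, prediction = "not_supported",
                rationale = "utilizing enzymes not expressed in the reference condition"))
  }
  rat <- if (enz_expressed) {
    "transporter annotated and utilizing enzyme expressed"
  } else {
    "transporter annotated; utilization system flagged substrate-inducible"
  }
  list(condition = mapping$condition, prediction = "supported", rationale = rat)
}

#' Predict utilization for every condition of a compound map
#' @param compound_map Compound-map data.frame.
#' @param flags Flagged expression table.
#' @return data.frame `condition`, `prediction`, `rationale`.
#' @export
predict_all_utilization <- function(compound_map, flags) {
  rows <- lapply(compound_map$condition, function(cond) {
    as.data.frame(predict_utilization(map_compound(cond, compound_map), flags),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance of utilization predictions with observed growth calls
#'
#' Cross-tabulates predicted support against observed growth over the
#' mapped conditions (observed `high`/`moderate` count as growth,
#' `none` as no growth). Unmapped conditions are excluded from the
#' table and counted separately.
#'
#' @param predictions data.frame from [predict_all_utilization()].
#' @param calls Growth calls data.frame with `condition`, `class`.
#' @return List with `table` (2x2), `agreement` (fraction in `[0,1]`)
#'   and `n_unmapped`.
#' @export
concordance <- function(predictions, calls) {
  merged <- merge(predictions, calls[, c("condition", "class")], by = "condition")
  unmapped <- merged$prediction == "unknown"
  m <- merged[!unmapped, ]
  pred <- factor(m$prediction, levels = c("supported", "not_supported"))
  obs <- factor(ifelse(m$class %in% c("high", "moderate"), "grows", "no_growth"),
                levels = c("grows", "no_growth"))
  tab <- table(predicted = pred, observed = obs)
  agree <- if (nrow(m)) {
    mean((m$prediction == "supported") == (m$class %in% c("high", "moderate")))
  } else NA_real_
  list(table = tab, agreement = agree, n_unmapped = sum(unmapped))
}

#' Compare nutrient utilization between two species
#'
#' From a utilization matrix (growth ✓ / no-growth X / NA per species),
#' counts the NA-free rows where both species grow (`common`), where
#' only one grows (`uniqueA`, `uniqueB`), and where neither grows
#' (`both_no_growth`); rows with any NA are excluded from all counts.
#' The differentially utilized rows are returned for reporting.
#'
#' @param um Utilization data.frame with a `source` column and one call
#'   column per species (values `"growth"`, `"no_growth"`, `"NA"`/NA).
#' @param species_a,species_b Names of the two call columns (e.g.
#'   `"mtb_call"`, `"msm_call"`).
#' @return List with `common`, `uniqueA`, `uniqueB`, `both_no_growth`,
#'   `n_informative` and `differential` (data.frame of the one-sided
#'   rows).
#' @export
compare_species <- function(um, species_a, species_b) {
  for (sp in c(species_a, species_b)) {
    if (!sp %in% names(um)) stopf("unknown species column '%s'", sp)
  }
  a <- um[[species_a]]; b <- um[[species_b]]
  ok_vals <- c("growth", "no_growth")
  keep <- a %in% ok_vals & b %in% ok_vals
  a <- a[keep]; b <- b[keep]
  diff_rows <- um[keep, , drop = FALSE][
    (a == "growth") != (b == "growth"), , drop = FALSE]
  list(common = sum(a == "growth" & b == "growth"),
       uniqueA = sum(a == "growth" & b == "no_growth"),
       uniqueB = sum(b == "growth" & a == "no_growth"),
       both_no_growth = sum(a == "no_growth" & b == "no_growth"),
       n_informative = sum(keep),
       differential = diff_rows)
}

#' Overlay feasibility calls and PM probing onto a network table
#'
#' Produces graph-tool-friendly tables: a node table of the PM-probed
#' compounds that map into the network (with their entry metabolites)
#' and an edge table of pathway reaction steps flagged by whether any
#' encoding gene is expressed.
#'
#' @param pathways List of pathway definitions.
#' @param flags Flagged expression table.
#' @param compound_map Compound-map data.frame.
#' @return List with `nodes` (data.frame `condition`,
#'   `entry_metabolites`, `pm_probed`) and `edges` (data.frame
#'   `pathway_id`, `step_index`, `ec`, `genes`, `expressed`).
#' @export
network_overlay <- function(pathways, flags, compound_map) {
  mapped <- compound_map[nzchar(compound_map$entry_metabolites) &
                           !is.na(compound_map$entry_metabolites), , drop = FALSE]
  nodes <- data.frame(condition = mapped$condition,
                      entry_metabolites = mapped$entry_metabolites,
                      pm_probed = rep(TRUE, nrow(mapped)),
                      stringsAsFactors = FALSE)
  edges <- list()
  for (pw in pathways) {
    for (st in pw$steps) {
      edges[[length(edges) + 1L]] <- data.frame(
        pathway_id = pw$pathway_id, step_index = st$step_index,
        ec = st$ec %||% NA_character_, genes = paste(st$genes, collapse = ";"),
        expressed = any(flag_lookup(flags, st$genes, "expressed")),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(pathway_id = character(0), step_index = integer(0),
               ec = character(0), genes = character(0), expressed = logical(0))
  list(nodes = nodes, edges = edges)
}
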