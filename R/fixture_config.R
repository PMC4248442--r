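#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic fixtures: array size, pathway
#' composition, duplicate-gene sets, phenotype-microarray (PM) plate
#' composition and noise levels. The defaults reproduce the study
#' conditions the pipeline is designed for: a 6,761-gene two-replicate
#' expression array with replicate correlation 0.99, 338 pathways split
#' 257 feasible / 14 inactive / 57 partially expressed / 10 mostly
#' expressed, 24 duplicate-gene sets with exactly one above-median
#' member each, three PM plates totalling 284 test wells in growth
#' classes 167 high / 96 moderate / 21 none with 48-h replicate
#' correlation 0.93, and 135 PM conditions mappable onto the metabolic
#' network.
#'
#' @param seed Integer seed; all fixture randomness derives from it.
#' @param n_genes Number of probed genes on the array.
#' @param n_pathways Number of pathway definitions.
#' @param pathway_composition Named counts per feasibility status
#'   (`feasible`, `inactive`, `partial`, `mostly`); must sum to
#'   `n_pathways`.
#' @param n_duplicate_sets Number of embedded duplicate-gene (paralog)
#'   sets, each with exactly one above-median member.
#' @param replicate_noise_ratio_expr Fraction of total log-intensity
#'   variance that is independent replicate noise, in `[0, 1)`. The
#'   expected replicate Pearson correlation is `1 - ratio`.
#' @param pm_composition Named counts of PM test wells per growth class
#'   (`high`, `moderate`, `none`); must sum to 284, the three-plate
#'   test-well total (PM1 95 + PM3 95 + PM5 94).
#' @param pm_noise_ratio Fraction of cross-well 48-h signal variance
#'   that is independent replicate noise, in `[0, 1)`; the expected
#'   48-h cross-replicate correlation is `1 - ratio`.
#' @param n_mapped_compounds Number of PM conditions that carry at
#'   least one metabolic-network entry metabolite.
#' @param pm_kinetics Per-class logistic parameters `A` (plateau, OU),
#'   `k` (rate, per h) and `t0` (midpoint, h) of the respiration model
#'   `y(t) = A / (1 + exp(-k (t - t0)))`.
#'
#' @return An object of class `fixture_config` (a validated list).
#' @examples
#' cfg <- fixture_config(seed = 1)
#' cfg$pm_composition
#' @export
fixture_config <- function(seed = 42L,
                           n_genes = 6761L,
                           n_pathways = 338L,
                           pathway_composition = c(feasible = 257L, inactive = 14L,
                                                   partial = 57L, mostly = 10L),
                           n_duplicate_sets = 24L,
                           replicate_noise_ratio_expr = 0.01,
                           pm_composition = c(high = 167L, moderate = 96L, none = 21L),
                           pm_noise_ratio = 0.07,
                           n_mapped_compounds = 135L,
                           pm_kinetics = list(
                             high     = c(A = 250, k = 0.15, t0 = 18),
                             moderate = c(A = 120, k = 0.10, t0 = 30),
                             none     = c(A = 10,  k = 0,    t0 = 0))) {
  if (length(seed) != 1L || is.na(seed)) stopf("`seed` must be a single integer")
  if (n_genes <= 0) stopf("`n_genes` must be positive")
  if (n_pathways <= 0) stopf("`n_pathways` must be positive")
  need <- c("feasible", "inactive", "partial", "mostly")
  if (!setequal(names(pathway_composition), need)) {
    stopf("`pathway_composition` must have names %s", paste(need, collapse = ", "))
  }
  pathway_composition <- pathway_composition[need]
  if (sum(pathway_composition) != n_pathways) {
    stopf("`pathway_composition` sums to %d, not n_pathways = %d",
          sum(pathway_composition), n_pathways)
  }
  needc <- c("high", "moderate", "none")
  if (!setequal(names(pm_composition), needc)) {
    stopf("`pm_composition` must have names %s", paste(needc, collapse = ", "))
  }
  pm_composition <- pm_composition[needc]
  if (sum(pm_composition) != 284L) {
    stopf("`pm_composition` sums to %d; the three-plate test-well total is 284",
          sum(pm_composition))
  }
  for (r in c(replicate_noise_ratio_expr, pm_noise_ratio)) {
    if (r < 0 || r >= 1) stopf("variance fractions must lie in [0, 1)")
  }
  if (n_duplicate_sets < 0) stopf("`n_duplicate_sets` must be non-negative")
  if (n_mapped_compounds < 0 || n_mapped_compounds > 284L) {
    stopf("`n_mapped_compounds` must be between 0 and the number of test wells (284)")
  }
  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_pathways = as.integer(n_pathways),
    pathway_composition = as.integer(pathway_composition) |>
      stats::setNames(names(pathway_composition)),
    n_duplicate_sets = as.integer(n_duplicate_sets),
    replicate_noise_ratio_expr = replicate_noise_ratio_expr,
    pm_composition = as.integer(pm_composition) |> stats::setNames(names(pm_composition)),
    pm_noise_ratio = pm_noise_ratio,
    n_mapped_compounds = as.integer(n_mapped_compounds),
    pm_kinetics = pm_kinetics
  ), class = "fixture_config")
}

#' @export
print.fixture_config <- function(x, ...) {
  cat("Synthetic fixture configuration\n")
  cat("  seed:", x$seed, "  genes:", x$n_genes, "  pathways:", x$n_pathways, "\n")
  cat("  pathway composition:",
      paste(names(x$pathway_composition), x$pathway_composition,
            sep = "=", collapse = ", "), "\n")
  cat("  PM composition:",
      paste(names(x$pm_composition), x$pm_composition, sep = "=", collapse = ", "),
      "\n")
  cat("  noise ratios: expression", x$replicate_noise_ratio_expr,
      "| PM", x$pm_noise_ratio, "\n")
  invisible(x)
}
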