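test_that("fixture_config validates compositions and noise fractions", {
  expect_s3_class(fixture_config(seed = 1), "fixture_config")
  expect_error(fixture_config(n_genes = 0), "positive")
  expect_error(fixture_config(replicate_noise_ratio_expr = 1), "\\[0, 1\\)")
  expect_error(fixture_config(pathway_composition = c(feasible = 338, inactive = 0,
                                                      partial = 0, mostly = 1)),
               "sums to")
  expect_error(fixture_config(pm_composition = c(high = 100, moderate = 100,
                                                 none = 100)), "284")
  expect_error(fixture_config(n_mapped_compounds = 300), "between 0 and")
})

test_that("expression generator is deterministic and leaves global RNG alone", {
  cfg <- fixture_config(seed = 7, n_genes = 800)
  a <- generate_expression(cfg)
  set.seed(123); before <- runif(3)
  b <- generate_expression(cfg)
  set.seed(123); after <- runif(3)
  expect_identical(a, b)
  expect_identical(before, after)
})

test_that("expression arrays have positive distinct intensities and embedded duplicates", {
  cfg <- fixture_config(seed = 3)
  fx <- generate_expression(cfg)
  e <- fx$expression
  expect_equal(nrow(e), 6761)
  expect_true(all(e$raw_rep1 > 0 & e$raw_rep2 > 0))
  expect_false(anyDuplicated(e$raw_rep1) > 0)

  gt <- fx$ground_truth$duplicate_sets
  expect_equal(length(unique(gt$set_id)), 24)
  # exactly one ground-truth label per embedded gene
  expect_false(anyDuplicated(gt$locus) > 0)
  # exactly one member per set exceeds the array median of averaged values
  flags <- expression_flags(normalize_expression(e))
  am <- flags$above_median[match(gt$locus, flags$gene_locus)]
  per_set <- tapply(am, gt$set_id, sum)
  expect_true(all(per_set == 1))
})

test_that("zero replicate noise gives identical replicates, r exactly 1", {
  fx <- generate_expression(fixture_config(seed = 5, n_genes = 500,
                                           replicate_noise_ratio_expr = 0))
  expect_identical(fx$expression$raw_rep1, fx$expression$raw_rep2)
  expect_equal(replicate_correlation(log2(fx$expression$raw_rep1),
                                     log2(fx$expression$raw_rep2)), 1)
})

test_that("replicate correlation is calibrated to the signal fraction", {
  rs <- vapply(seq_len(200), function(s) {
    e <- generate_expression(fixture_config(seed = s))$expression
    replicate_correlation(log2(e$raw_rep1), log2(e$raw_rep2))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.99), 0.005)
})

test_that("pathway fixture statuses hold exactly under a brute-force coverage recount", {
  cfg <- fixture_config(seed = 11)
  fx <- generate_expression(cfg)
  flags <- expression_flags(normalize_expression(fx$expression))
  pws <- generate_pathways(cfg, fx)
  expect_length(pws$pathways, 338)
  gt <- pws$ground_truth$pathway_status
  band <- list(feasible = c(1, 1), inactive = c(0, 0),
               partial = c(1e-9, 0.75 - 1e-9), mostly = c(0.75, 1 - 1e-9))
  for (pw in pws$pathways[seq(1, 338, by = 7)]) {
    cov <- coverage_oracle(pw, flags)
    b <- band[[gt[[pw$pathway_id]]]]
    expect_gte(cov, b[1]); expect_lte(cov, b[2])
    steps <- vapply(pw$steps, `[[`, integer(1), "step_index")
    expect_identical(steps, seq_along(steps))  # contiguous from 1
  }
})

test_that("degenerate all-feasible composition yields only feasible pathways", {
  cfg <- fixture_config(seed = 2, n_pathways = 12,
                        pathway_composition = c(feasible = 12, inactive = 0,
                                                partial = 0, mostly = 0))
  fx <- generate_expression(cfg)
  flags <- expression_flags(normalize_expression(fx$expression))
  pws <- generate_pathways(cfg, fx)
  st <- vapply(pws$pathways, function(p) classify_pathway(p, flags)$status,
               character(1))
  expect_true(all(st == "feasible"))
})

test_that("PM plate fixture has 284 labelled test wells on a shared grid", {
  cfg <- fixture_config(seed = 13)
  pm <- generate_pm_plates(cfg)
  expect_equal(sum(pm$plate_map$role == "test"), 284)
  expect_equal(sum(pm$plate_map$role == "control"), 4)
  gt <- pm$ground_truth$growth_class
  expect_equal(nrow(gt), 284)
  expect_false(anyDuplicated(gt$condition) > 0)   # one label per well
  expect_equal(unname(table(gt$class)[c("high", "moderate", "none")]),
               c(167, 96, 21), ignore_attr = TRUE)
  expect_true(all(pm$kinetics$omnilog_units >= 0))
  expect_identical(sort(unique(pm$kinetics$time_h)), seq(0, 96, by = 0.25))
  # glucose anchor present on PM1 and high-growth
  expect_equal(gt$class[gt$condition == "D-Glucose"], "high")
  expect_identical(generate_pm_plates(cfg)$kinetics, pm$kinetics)  # determinism
})

test_that("no-growth wells are flat at baseline when noise is zero", {
  cfg <- fixture_config(seed = 4, pm_noise_ratio = 0)
  pm <- generate_pm_plates(cfg)
  gt <- pm$ground_truth$growth_class
  none_cond <- gt$condition[gt$class == "none"][1]
  y <- pm$kinetics$omnilog_units[pm$kinetics$condition == none_cond]
  expect_true(all(y == y[1]))
  expect_lt(y[1], 10)
})

test_that("compound map marks exactly the configured number of conditions as mapped", {
  cfg <- fixture_config(seed = 17)
  pm <- generate_pm_plates(cfg)
  fx <- generate_expression(cfg)
  cm <- generate_compound_map(cfg, pm, fx)
  expect_equal(count_mapped(cm$compound_map), 135)
  expect_setequal(cm$ground_truth$mapped_compounds,
                  cm$compound_map$condition[nzchar(cm$compound_map$entry_metabolites)])
  # zero mapped compounds -> everything unmapped
  cfg0 <- fixture_config(seed = 17, n_mapped_compounds = 0)
  cm0 <- generate_compound_map(cfg0, pm, fx)
  expect_equal(count_mapped(cm0$compound_map), 0)
})

test_that("proteome fixture hits its identity targets and embeds 24 paralog sets", {
  cfg <- fixture_config(seed = 19)
  px <- generate_proteomes(cfg)
  gt <- px$ground_truth$ortholog_pairs
  qs <- as.character(px$query); rs <- as.character(px$ref)
  for (i in seq(1, nrow(gt), by = 8)) {
    got <- pairwise_identity(qs[[gt$query[i]]], rs[[gt$ref[i]]])
    expect_lt(abs(got - gt$target_identity[i]), 2)  # alignment oracle check
  }
  expect_equal(nrow(px$ground_truth$paralog_sets), 24)
  # paralog copies are placed far from their originals on the chromosome
  ann <- px$query_annotations
  sep <- abs(ann$start[match(px$ground_truth$paralog_sets$member1, ann$locus)] -
             ann$start[match(px$ground_truth$paralog_sets$member2, ann$locus)])
  expect_true(all(sep > 1e6))
})
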