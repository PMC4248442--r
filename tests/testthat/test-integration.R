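toy_map <- data.frame(
  condition = c("glucose", "adenosine", "mystery", "mannitol"),
  entry_metabolites = c("g6p", "adenine", "", "fructose"),
  transporter_loci = c("t1", "t3", "", "t2"),
  enzyme_loci = c("e1;e2", "e3", "", "e4"),
  inducible = c(FALSE, FALSE, FALSE, TRUE),
  steps_to_network = c(0L, 1L, NA, 1L),
  stringsAsFactors = FALSE)

toy_flags <- make_flags(c("t1", "t2", "e1", "e2", "e3", "e4"),
                        expressed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

test_that("compound lookup distinguishes unmapped from unknown", {
  hit <- map_compound("glucose", toy_map)
  expect_true(hit$mapped)
  expect_equal(hit$entry_metabolites, "g6p")
  expect_false(map_compound("mystery", toy_map)$mapped)
  expect_equal(map_compound("  GLUCOSE ", toy_map)$condition, "glucose")
  expect_error(map_compound("unobtainium", toy_map), "absent")
  expect_equal(count_mapped(toy_map), 3L)
})

test_that("utilization prediction applies the transporter-and-enzyme rule", {
  sup <- predict_utilization(map_compound("glucose", toy_map), toy_flags)
  expect_equal(sup$prediction, "supported")
  # enzymes present but silent, no inducible flag -> enzyme clause fails
  no_enz <- predict_utilization(map_compound("adenosine", toy_map), toy_flags)
  expect_equal(no_enz$prediction, "not_supported")
  expect_match(no_enz$rationale, "enzyme")
  # silent enzymes rescued by the substrate-inducible flag
  ind <- predict_utilization(map_compound("mannitol", toy_map), toy_flags)
  expect_equal(ind$prediction, "supported")
  expect_match(ind$rationale, "inducible")
  # no transporter annotated
  m2 <- toy_map; m2$transporter_loci[1] <- ""
  no_t <- predict_utilization(map_compound("glucose", m2), toy_flags)
  expect_equal(no_t$prediction, "not_supported")
  expect_match(no_t$rationale, "transporter")
  expect_equal(predict_utilization(map_compound("mystery", toy_map),
                                   toy_flags)$prediction, "unknown")
})

test_that("prediction is monotone in evidence", {
  set.seed(31)
  loci <- sprintf("L%02d", 1:10)
  for (i in 1:20) {
    fl <- make_flags(loci, expressed = runif(10) < 0.4)
    rec <- list(condition = "x", mapped = TRUE,
                entry_metabolites = "m",
                transporter_loci = if (runif(1) < 0.5) sample(loci, 1) else character(0),
                enzyme_loci = sample(loci, 2), inducible = FALSE)
    base <- predict_utilization(rec, fl)$prediction
    # add an expressed enzyme and a transporter: never supported -> not_supported
    rec2 <- rec
    rec2$transporter_loci <- union(rec2$transporter_loci, loci[1])
    rec2$enzyme_loci <- union(rec2$enzyme_loci, loci[fl$expressed][1])
    more <- predict_utilization(rec2, fl)$prediction
    expect_false(base == "supported" && more == "not_supported")
  }
})

test_that("concordance tabulates predictions against observed growth", {
  preds <- data.frame(condition = c("a", "b", "c", "d"),
                      prediction = c("supported", "not_supported",
                                     "supported", "unknown"),
                      rationale = "")
  calls <- data.frame(condition = c("a", "b", "c", "d"),
                      class = c("high", "none", "moderate", "high"))
  cc <- concordance(preds, calls)
  expect_equal(cc$agreement, 1)
  expect_equal(cc$n_unmapped, 1L)
  expect_equal(sum(cc$table), 3)
  # inverted predictions -> agreement 0
  preds$prediction <- c("not_supported", "supported", "not_supported", "unknown")
  expect_equal(concordance(preds, calls)$agreement, 0)
})

test_that("predictions agree with growth classes on the noise-free-rule fixture", {
  cfg <- fixture_config(seed = 42)
  pm <- generate_pm_plates(cfg)
  fx <- generate_expression(cfg)
  flags <- expression_flags(normalize_expression(fx$expression))
  cm <- generate_compound_map(cfg, pm, fx)
  preds <- predict_all_utilization(cm$compound_map, flags)
  calls <- classify_plateset(pm$kinetics, pm$plate_map)
  cc <- concordance(preds, calls)
  expect_gte(cc$agreement, 0.95)
  expect_equal(cc$n_unmapped, 284L - 135L)
})

test_that("the packaged cross-species utilization table yields 31 common and 9 unique", {
  um <- read_utilization_matrix(system.file("extdata",
                                            "table2_msm_mtb_utilization.tsv",
                                            package = "feaspath"))
  cs <- compare_species(um, "mtb_call", "msm_call")
  expect_equal(cs$common, 31L)
  expect_equal(cs$uniqueA + cs$uniqueB, 9L)
  expect_equal(cs$uniqueA, 1L)  # D-serine as a carbon source: Mtb only
  expect_equal(cs$uniqueB, 8L)
  expect_setequal(cs$differential$source, um$source[um$differential])
  # the both-no-growth adenosine row contributes to neither count
  expect_equal(cs$both_no_growth, 1L)
  expect_false("Adenosine" %in% cs$differential$source)
  # partition: common + uniques + bothX = informative rows
  expect_equal(cs$common + cs$uniqueA + cs$uniqueB + cs$both_no_growth,
               cs$n_informative)
  # symmetry up to swapping the unique counts
  sw <- compare_species(um, "msm_call", "mtb_call")
  expect_equal(sw$common, cs$common)
  expect_equal(sw$uniqueA, cs$uniqueB)
  expect_equal(sw$uniqueB, cs$uniqueA)
  # identical columns -> no unique rows
  um2 <- um; um2$msm_call <- um2$mtb_call
  same <- compare_species(um2, "mtb_call", "msm_call")
  expect_equal(same$uniqueA + same$uniqueB, 0L)
  expect_error(compare_species(um, "mtb_call", "ghost_call"), "unknown species")
})

test_that("network overlay tables are consistent with their inputs", {
  empty <- network_overlay(list(), toy_flags,
                           toy_map[0, , drop = FALSE])
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  cfg <- fixture_config(seed = 11, n_pathways = 20,
                        pathway_composition = c(feasible = 12, inactive = 2,
                                                partial = 4, mostly = 2))
  fx <- generate_expression(cfg)
  flags <- expression_flags(normalize_expression(fx$expression))
  pws <- generate_pathways(cfg, fx)
  pm <- generate_pm_plates(cfg)
  cm <- generate_compound_map(cfg, pm, fx)
  ov <- network_overlay(pws$pathways, flags, cm$compound_map)
  # PM-flagged nodes equal the mapped compound count
  expect_equal(nrow(ov$nodes), count_mapped(cm$compound_map))
  expect_true(all(ov$nodes$pm_probed))
  # every expressed edge really has an expressed gene behind it
  for (i in which(ov$edges$expressed)[1:20]) {
    genes <- strsplit(ov$edges$genes[i], ";")[[1]]
    expect_true(any(flags$expressed[match(genes, flags$gene_locus)]))
  }
})
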