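#' Simulate phenotype-microarray respiration kinetics for three plates
#'
#' Emulates a Biolog PM experiment: plates PM1 (95 test wells + 1
#' negative control), PM3 (95 + 1) and PM5 (94 + 2), i.e. 284 test
#' conditions, read at 15-minute intervals over 0--96 h. Each well's
#' respiration trace follows the logistic model
#' `y(t) = A / (1 + exp(-k (t - t0)))` with class-specific parameters
#' (`config$pm_kinetics`); the "none" class has `k = 0`, a flat
#' baseline. Two biological replicates share the well parameters and
#' receive independent additive Gaussian noise whose standard deviation
#' is calibrated so the expected cross-replicate Pearson correlation of
#' 48-h values across test wells equals `1 - config$pm_noise_ratio`
#' (0.93 at the default). Signals are clipped at 0 OU.
#'
#' One PM1 test well is always named `"D-Glucose"` and assigned to the
#' high-growth class; it serves as the positive anchor for
#' [classify_growth()], mirroring the use of the glucose well to
#' validate PM growth profiles against batch culture.
#'
#' @param config A [fixture_config()].
#' @return A list with
#'   \describe{
#'     \item{kinetics}{long data.frame: `plate`, `well`, `condition`,
#'       `replicate`, `time_h`, `omnilog_units`.}
#'     \item{plate_map}{data.frame: `plate`, `well`, `condition`,
#'       `role` ("test" or "control").}
#'     \item{ground_truth}{list with `growth_class`, a data.frame of
#'       `plate`, `well`, `condition`, `class` for the 284 test wells.}
#'   }
#' @export
generate_pm_plates <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  comp <- config$pm_composition
  if (sum(comp) != 284L) stopf("pm_composition must sum to 284")

  wells96 <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  plate_map <- rbind(
    data.frame(plate = "PM1", well = wells96,
               role = ifelse(wells96 == "A1", "control", "test")),
    data.frame(plate = "PM3", well = wells96,
               role = ifelse(wells96 == "A1", "control", "test")),
    data.frame(plate = "PM5", well = wells96,
               role = ifelse(wells96 %in% c("A1", "A2"), "control", "test"))
  )
  plate_map$condition <- ifelse(
    plate_map$role == "control",
    paste0(plate_map$plate, "_", plate_map$well, "_negative_control"),
    paste0(plate_map$plate, "_", plate_map$well)
  )

  with_seed(sub_seed(config$seed, "pm"), {
    test_idx <- which(plate_map$role == "test")
    # glucose anchor: a fixed PM1 test well, always high growth
    glc <- which(plate_map$plate == "PM1" & plate_map$well == "C9")
    plate_map$condition[glc] <- "D-Glucose"
    classes <- rep(NA_character_, nrow(plate_map))
    classes[glc] <- "high"
    rest <- setdiff(test_idx, glc)
    pool <- rep(names(comp), times = comp - c(high = 1L, moderate = 0L, none = 0L))
    classes[rest] <- sample(pool)

    times <- seq(0, 96, by = 0.25)
    noise_sd <- pm_noise_sd(config, times = 48)

    nt <- length(times)
    nw <- nrow(plate_map)
    well_class <- ifelse(plate_map$role == "control", "none", classes)
    mean_mat <- vapply(well_class, function(cls) {
      p <- config$pm_kinetics[[cls]]
      logistic_curve(times, p[["A"]], p[["k"]], p[["t0"]])
    }, numeric(nt))                                   # nt x nw
    sig <- function() pmax(as.vector(mean_mat) + stats::rnorm(nt * nw, sd = noise_sd), 0)
    kinetics <- data.frame(
      plate = rep(rep(plate_map$plate, each = nt), 2L),
      well = rep(rep(plate_map$well, each = nt), 2L),
      condition = rep(rep(plate_map$condition, each = nt), 2L),
      replicate = rep(1:2, each = nt * nw),
      time_h = rep(times, nw * 2L),
      omnilog_units = c(sig(), sig()),
      stringsAsFactors = FALSE
    )
    gt <- data.frame(plate = plate_map$plate[test_idx],
                     well = plate_map$well[test_idx],
                     condition = plate_map$condition[test_idx],
                     class = classes[test_idx], stringsAsFactors = FALSE)
    list(kinetics = kinetics,
         plate_map = plate_map[, c("plate", "well", "condition", "role")],
         ground_truth = list(growth_class = gt))
  })
}

logistic_curve <- function(t, A, k, t0) A / (1 + exp(-k * (t - t0)))

# Noise sd such that, at the reference time, the expected cross-replicate
# correlation over test wells equals 1 - pm_noise_ratio. Between-well
# variance is computed analytically from the noise-free class values and
# the configured class composition.
pm_noise_sd <- function(config, times = 48) {
  ratio <- config$pm_noise_ratio
  if (ratio == 0) return(0)
  comp <- config$pm_composition
  v <- vapply(names(comp), function(cl) {
    p <- config$pm_kinetics[[cl]]
    logistic_curve(times, p[["A"]], p[["k"]], p[["t0"]])
  }, numeric(length(times)))
  w <- comp / sum(comp)
  m <- sum(w * v)
  var_between <- sum(w * (v - m)^2)
  sqrt(ratio / (1 - ratio) * var_between)
}

#' Simulate the compound-to-network map for the PM conditions
#'
#' Of the 284 tested conditions, `config$n_mapped_compounds` (default
#' 135) are assigned one or two metabolic-network entry metabolites;
#' the rest carry none. Mapped compounds also receive transporter and
#' utilizing-enzyme locus lists consistent with their ground-truth
#' growth class: growth-supporting compounds (high or moderate class)
#' get an annotated transporter and at least one expressed enzyme (or,
#' for a few, unexpressed enzymes with the `inducible` flag set, the
#' way sugar uptake systems are induced by their own substrate);
#' no-growth compounds lack either the transporter annotation or any
#' expressed enzyme.
#'
#' @param config A [fixture_config()].
#' @param pm The PM fixture from [generate_pm_plates()].
#' @param expr The expression fixture from [generate_expression()].
#' @param expressed_percentile Percentile cut defining "expressed"
#'   (default 25), matching downstream flags.
#' @return A list with `compound_map` (data.frame: `condition`,
#'   `entry_metabolites`, `transporter_loci`, `enzyme_loci`,
#'   `inducible`, `steps_to_network`; locus/metabolite lists are
#'   ";"-joined strings, empty when absent) and `ground_truth` (list
#'   with `mapped_compounds`, the mapped condition names).
#' @export
generate_compound_map <- function(config, pm, expr, expressed_percentile = 25) {
  stopifnot(inherits(config, "fixture_config"))
  gt_class <- pm$ground_truth$growth_class
  if (is.null(gt_class)) stopf("`pm` must be the output of generate_pm_plates()")
  if (is.list(expr) && !is.data.frame(expr)) expr <- expr$expression
  n_map <- config$n_mapped_compounds
  if (n_map > nrow(gt_class)) {
    stopf("n_mapped_compounds (%d) exceeds the number of test wells (%d)",
          n_map, nrow(gt_class))
  }

  avg <- (log2(expr$raw_rep1) + log2(expr$raw_rep2)) / 2
  cut <- stats::quantile(avg, expressed_percentile / 100, type = 7)
  expressed_pool <- expr$gene_locus[avg > cut]
  silent_pool <- expr$gene_locus[avg <= cut]

  with_seed(sub_seed(config$seed, "compounds"), {
    conds <- gt_class$condition
    mapped <- if (n_map > 0) sort(resample(conds, n_map)) else character(0)
    cm <- data.frame(condition = conds,
                     entry_metabolites = "", transporter_loci = "",
                     enzyme_loci = "", inducible = FALSE,
                     steps_to_network = NA_integer_,
                     stringsAsFactors = FALSE)
    met_counter <- 0L
    for (i in seq_len(nrow(cm))) {
      if (!(cm$condition[i] %in% mapped)) next
      n_met <- sample(1:2, 1)
      cm$entry_metabolites[i] <- paste(
        sprintf("met_%04d", met_counter + seq_len(n_met)), collapse = ";")
      met_counter <- met_counter + n_met
      cm$steps_to_network[i] <- sample(0:2, 1)
      cls <- gt_class$class[match(cm$condition[i], gt_class$condition)]
      if (cls %in% c("high", "moderate")) {
        cm$transporter_loci[i] <- resample(expressed_pool, 1)
        # a small fraction mimic substrate-inducible uptake systems:
        # enzymes silent in the reference condition but flagged inducible
        if (stats::runif(1) < 0.05) {
          cm$enzyme_loci[i] <- paste(resample(silent_pool, 2), collapse = ";")
          cm$inducible[i] <- TRUE
        } else {
          cm$enzyme_loci[i] <- paste(
            c(resample(expressed_pool, 1), resample(silent_pool, 1)),
            collapse = ";")
        }
      } else {
        # no-growth: either no transporter, or all enzymes unexpressed
        if (stats::runif(1) < 0.5) {
          cm$transporter_loci[i] <- ""
          cm$enzyme_loci[i] <- paste(resample(expressed_pool, 1), collapse = ";")
        } else {
          cm$transporter_loci[i] <- paste(resample(expressed_pool, 1), collapse = ";")
          cm$enzyme_loci[i] <- paste(resample(silent_pool, 2), collapse = ";")
        }
      }
    }
    list(compound_map = cm,
         ground_truth = list(mapped_compounds = mapped))
  })
}
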