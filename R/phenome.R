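#' Kinetic growth metrics for one respiration curve
#'
#' @param times Strictly increasing time grid in hours.
#' @param signal Non-negative respiration readout (OmniLog units, OU).
#' @param at Reference time for the point readout (default 48 h),
#'   linearly interpolated.
#' @return List with `max_signal` (OU), `auc` (trapezoidal area, OU h),
#'   `value_at_48h` (OU, at `at`), and `lag_time` (first time the
#'   signal exceeds 10% of its maximum; `NA` for a flat curve).
#' @examples
#' compute_metrics(c(0, 48, 96), c(0, 100, 100))
#' @export
compute_metrics <- function(times, signal, at = 48) {
  if (length(times) < 2L) stopf("need at least 2 time points")
  if (length(times) != length(signal)) stopf("times and signal differ in length")
  if (is.unsorted(times, strictly = TRUE)) stopf("times must be strictly increasing")
  n <- length(times)
  auc <- sum(diff(times) * (signal[-1] + signal[-n]) / 2)
  mx <- max(signal)
  v48 <- if (at <= max(times) && at >= min(times)) {
    stats::approx(times, signal, xout = at)$y
  } else NA_real_
  lag <- NA_real_
  if (mx > 0) {
    above <- which(signal > 0.1 * mx)
    if (length(above)) lag <- times[above[1]]
  }
  list(max_signal = mx, auc = auc, value_at_48h = v48, lag_time = lag)
}

#' Average replicate curves per condition
#'
#' @param kinetics Long-format kinetics data.frame (`condition`,
#'   `replicate`, `time_h`, `omnilog_units`); all replicates of a
#'   condition must share the time grid.
#' @return data.frame `condition`, `time_h`, `mean_ou`, `sd_ou`.
#' @export
aggregate_replicates <- function(kinetics) {
  need <- c("condition", "replicate", "time_h", "omnilog_units")
  if (!all(need %in% names(kinetics))) {
    stopf("kinetics must have columns %s", paste(need, collapse = ", "))
  }
  # all replicates of a condition must sample the same grid
  key_rep <- paste(kinetics$condition, kinetics$replicate, sep = "\r")
  grids <- tapply(kinetics$time_h, key_rep, function(t) paste(sort(t), collapse = ","))
  grid_cond <- sub("\r.*$", "", names(grids))
  per_cond <- tapply(unname(grids), grid_cond, function(g) length(unique(g)))
  if (any(per_cond > 1L)) {
    stopf("replicates of '%s' disagree on the time grid",
          names(per_cond)[per_cond > 1L][1])
  }
  key <- paste(kinetics$condition, kinetics$time_h, sep = "\r")
  s1 <- rowsum(kinetics$omnilog_units, key)
  s2 <- rowsum(kinetics$omnilog_units^2, key)
  n <- rowsum(rep(1, nrow(kinetics)), key)
  first <- !duplicated(key)
  idx <- match(rownames(s1), key[first])
  out <- data.frame(condition = kinetics$condition[first][idx],
                    time_h = kinetics$time_h[first][idx],
                    mean_ou = as.vector(s1 / n),
                    sd_ou = sqrt(pmax(as.vector((s2 - s1^2 / n) / pmax(n - 1, 1)), 0)),
                    stringsAsFactors = FALSE)
  out$sd_ou[as.vector(n) < 2] <- NA_real_
  out <- out[order(out$condition, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Discretize growth metrics into high / moderate / none
#'
#' A condition shows no significant growth when its maximum signal
#' exceeds the plate's negative control by less than `delta_none`
#' (default 50 OU); among growing conditions, growth is `high` when the
#' area under the curve reaches `rho_high` (default 0.6) of the
#' positive anchor's AUC, else `moderate`. The rule is monotone:
#' pointwise-increasing a curve can never demote its class.
#'
#' @param metrics,neg_control,pos_anchor Metric lists from
#'   [compute_metrics()]: the condition, the plate's negative control,
#'   and the positive anchor (the PM1 glucose well).
#' @param delta_none,rho_high Threshold parameters.
#' @return Character scalar: `"high"`, `"moderate"` or `"none"`.
#' @export
classify_growth <- function(metrics, neg_control, pos_anchor,
                            delta_none = 50, rho_high = 0.6) {
  if (is.null(neg_control$max_signal) || is.null(pos_anchor$auc)) {
    stopf("negative-control and positive-anchor metrics are required")
  }
  if (metrics$max_signal - neg_control$max_signal < delta_none) return("none")
  if (metrics$auc >= rho_high * pos_anchor$auc) return("high")
  "moderate"
}

#' Classify every test condition of a PM plate set
#'
#' Convenience wrapper: aggregates replicates, computes metrics per
#' condition, uses each plate's negative-control wells (averaged) as
#' that plate's baseline and the PM1 glucose well as the global
#' positive anchor, and applies [classify_growth()] to every test
#' condition.
#'
#' @param kinetics Long-format kinetics (as from
#'   [generate_pm_plates()]).
#' @param plate_map Plate map with `plate`, `well`, `condition`,
#'   `role`.
#' @param anchor_condition Condition name of the positive anchor
#'   (default `"D-Glucose"`).
#' @inheritParams classify_growth
#' @return data.frame `plate`, `well`, `condition`, `class`.
#' @export
classify_plateset <- function(kinetics, plate_map, anchor_condition = "D-Glucose",
                              delta_none = 50, rho_high = 0.6) {
  agg <- aggregate_replicates(kinetics)
  by_cond <- split(agg[, c("time_h", "mean_ou")], agg$condition)
  metrics_of <- function(cond) {
    cc <- by_cond[[cond]]
    if (is.null(cc)) stopf("no kinetics for condition '%s'", cond)
    compute_metrics(cc$time_h, cc$mean_ou)
  }
  if (!anchor_condition %in% plate_map$condition) {
    stopf("anchor condition '%s' not found in the plate map", anchor_condition)
  }
  anchor <- metrics_of(anchor_condition)
  # per-plate baseline: average the control wells' metrics
  plates <- unique(plate_map$plate)
  neg_of <- lapply(stats::setNames(plates, plates), function(pl) {
    ctrl <- plate_map$condition[plate_map$plate == pl & plate_map$role == "control"]
    if (!length(ctrl)) stopf("plate %s has no negative-control well", pl)
    ms <- lapply(ctrl, metrics_of)
    list(max_signal = mean(vapply(ms, `[[`, numeric(1), "max_signal")),
         auc = mean(vapply(ms, `[[`, numeric(1), "auc")))
  })
  tests <- plate_map[plate_map$role == "test", ]
  tests$class <- vapply(seq_len(nrow(tests)), function(i) {
    classify_growth(metrics_of(tests$condition[i]), neg_of[[tests$plate[i]]],
                    anchor, delta_none, rho_high)
  }, character(1))
  rownames(tests) <- NULL
  tests[, c("plate", "well", "condition", "class")]
}

#' Cross-replicate correlation of well readouts at a fixed time
#'
#' Interpolates every test well of both replicates at time `t` and
#' returns the Pearson correlation of the paired values across all
#' test wells of all plates.
#'
#' @param kinetics Long-format kinetics with two replicates.
#' @param t Readout time in hours (default 48).
#' @param plate_map Optional plate map; when given, control wells are
#'   excluded.
#' @return Pearson correlation.
#' @export
correlation_at_time <- function(kinetics, t = 48, plate_map = NULL) {
  if (!is.null(plate_map)) {
    keep <- plate_map$condition[plate_map$role == "test"]
    kinetics <- kinetics[kinetics$condition %in% keep, ]
  }
  conds <- unique(kinetics$condition)
  groups <- split(kinetics[, c("time_h", "omnilog_units")],
                  list(kinetics$condition, kinetics$replicate), sep = "\r")
  val <- function(cond, r) {
    cc <- groups[[paste(cond, r, sep = "\r")]]
    if (is.null(cc) || !nrow(cc)) {
      stopf("replicate %d missing for condition '%s'", r, cond)
    }
    if (t < min(cc$time_h) || t > max(cc$time_h)) {
      stopf("t = %g outside the measured range for '%s'", t, cond)
    }
    stats::approx(cc$time_h, cc$omnilog_units, xout = t)$y
  }
  a <- vapply(conds, val, numeric(1), r = 1)
  b <- vapply(conds, val, numeric(1), r = 2)
  replicate_correlation(a, b)
}

#' Hierarchical clustering of conditions by curve shape
#'
#' Agglomerative clustering with distance `1 - Pearson r` between
#' condition feature rows (e.g. time-sampled mean curves) and average
#' linkage, the combination conventionally used for expression-profile
#' clustering. Constant rows have no defined correlation and are
#' dropped with a warning.
#'
#' @param features Numeric matrix, conditions in rows (rownames =
#'   condition names), feature samples in columns.
#' @param k Number of clusters to cut (optional; `labels` is NULL when
#'   missing).
#' @return List with `hclust` (the tree), `labels` (named cluster
#'   assignment or NULL), `newick` (the dendrogram as a Newick string)
#'   and `dropped` (constant rows removed).
#' @export
cluster_conditions <- function(features, k = NULL) {
  if (is.null(rownames(features))) stopf("`features` needs condition rownames")
  sds <- apply(features, 1, stats::sd)
  dropped <- rownames(features)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d constant condition row(s): %s", length(dropped),
                    paste(utils::head(dropped, 3), collapse = ", ")), call. = FALSE)
    features <- features[sds > 0, , drop = FALSE]
  }
  if (nrow(features) < 2L) stopf("need at least 2 non-constant conditions")
  if (!is.null(k) && k > nrow(features)) {
    stopf("k = %d exceeds the %d usable conditions", k, nrow(features))
  }
  d <- stats::as.dist(1 - stats::cor(t(features)))
  hc <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, labels = labels, newick = newick, dropped = dropped)
}

#' Condition-by-time matrix of aggregated curves
#'
#' Reshapes the output of [aggregate_replicates()] into a dense matrix
#' (conditions in rows, time points in columns), the input both for
#' [cluster_conditions()] and for level-plot style rendering.
#'
#' @param agg Aggregated curves from [aggregate_replicates()].
#' @param conditions Optional subset/order of conditions.
#' @return Numeric matrix with condition rownames and time colnames.
#' @export
condition_time_matrix <- function(agg, conditions = NULL) {
  conds <- conditions %||% unique(agg$condition)
  times <- sort(unique(agg$time_h))
  m <- matrix(NA_real_, length(conds), length(times),
              dimnames = list(conds, times))
  for (cond in conds) {
    cc <- agg[agg$condition == cond, ]
    m[cond, as.character(cc$time_h)] <- cc$mean_ou
  }
  if (anyNA(m)) stopf("conditions do not share the time grid")
  m
}
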