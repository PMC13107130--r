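#' Metric direction conventions
#'
#' For each per-model metric, whether an increase from the old to the new
#' gene model is read as evidence of improvement (`"increase"`) or whether
#' a decrease is (`"decrease"`). Error-type scores — mean PAE and the
#' Foldseek E-value — are decrease-good; every confidence, similarity and
#' domain-length score is increase-good; mean disorder is decrease-good
#' (curation tends to remove spuriously translated disordered sequence).
#'
#' @param metrics Metric names to return directions for; defaults to all
#'   declared metrics.
#' @return Named character vector, values `"increase"` / `"decrease"`.
#' @export
metric_directions <- function(metrics = NULL) {
  dirs <- c(
    median_plddt = "increase", mean_plddt = "increase", ptm = "increase",
    mean_pae = "decrease",
    n_plddt_gt_50 = "increase", n_plddt_gt_60 = "increase",
    n_plddt_gt_70 = "increase", n_plddt_gt_80 = "increase",
    n_plddt_gt_90 = "increase",
    fs_lddt = "increase", fs_alntmscore = "increase",
    fs_bitscore = "increase", fs_evalue = "decrease",
    ipr_max_len = "increase", ipr_total_len = "increase",
    n_ipr_domains = "increase", mean_disorder = "decrease",
    n_residues = "increase")
  if (is.null(metrics)) return(dirs)
  miss <- setdiff(metrics, names(dirs))
  if (length(miss))
    stop("no direction declared for metric(s): ", paste(miss, collapse = ", "))
  dirs[metrics]
}

#' Per-metric differences between a new and an old model
#'
#' `new - old` for every requested metric; a metric missing on either
#' side yields `NA` (explicit absence), never 0.
#'
#' @param new,old One-row data frames or `model_scores` for the two
#'   members of a gene pair.
#' @param metrics Metric names; default [canonical_metrics()].
#' @return Named numeric vector of raw deltas.
#' @export
delta_vector <- function(new, old, metrics = canonical_metrics()) {
  new <- as.list(as.data.frame(new)); old <- as.list(as.data.frame(old))
  if (!is.null(new$model_id) && !is.null(old$model_id) &&
      identical(new$model_id, old$model_id))
    stop("new and old score vectors have the same model_id: ", new$model_id)
  vapply(metrics, function(m) {
    a <- new[[m]]; b <- old[[m]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) NA_real_
    else as.numeric(a) - as.numeric(b)
  }, numeric(1))
}

#' Signed score of one metric delta
#'
#' +1 when the delta moves in the metric's good direction, -1 when it
#' moves against it, 0 at exactly zero or when the delta is missing.
#'
#' @param metric Metric name with a declared direction.
#' @param delta Raw delta (new - old); may be `NA`.
#' @param directions Direction table from [metric_directions()].
#' @return -1, 0 or +1.
#' @export
sign_score <- function(metric, delta, directions = metric_directions()) {
  if (!metric %in% names(directions))
    stop("no direction declared for metric: ", metric)
  if (is.na(delta)) return(0)
  s <- sign(delta)
  if (directions[[metric]] == "decrease") -s else s
}

#' Fit a MaxAbs scaler on a collection of deltas
#'
#' For each metric, the scale factor is the maximum absolute value
#' observed across the collection; dividing by it maps the metric into
#' \[-1, 1\] while preserving sign and zeros. A metric whose deltas are
#' all zero (or all missing) gets factor 1 so its scaled values stay 0.
#' Factors are fitted on the collection passed in — one dataset (e.g. one
#' species) at a time, never pooled across datasets.
#'
#' @param deltas Data frame of raw deltas, one column per metric.
#' @param metrics Metrics to fit; default: all columns of `deltas`.
#' @return Object of class `maxabs_scaler`: list with `scale_factors`.
#' @export
maxabs_fit <- function(deltas, metrics = NULL) {
  if (!is.data.frame(deltas)) deltas <- as.data.frame(deltas)
  if (nrow(deltas) == 0L) stop("cannot fit MaxAbs scaler on an empty dataset")
  if (is.null(metrics)) metrics <- names(deltas)
  miss <- setdiff(metrics, names(deltas))
  if (length(miss))
    stop("metrics absent from delta table: ", paste(miss, collapse = ", "))
  factors <- vapply(metrics, function(m) {
    v <- deltas[[m]]
    v <- v[is.finite(v)]
    if (!length(v)) return(1)
    f <- max(abs(v))
    if (f == 0) 1 else f
  }, numeric(1))
  structure(list(scale_factors = factors, metrics = metrics),
            class = "maxabs_scaler")
}

#' Apply a fitted MaxAbs scaler
#' @param scaler A `maxabs_scaler` from [maxabs_fit()].
#' @param deltas Data frame (or named vector) of raw deltas.
#' @return Scaled values, same shape as the input restricted to the
#'   scaler's metrics; missing values stay `NA`.
#' @export
maxabs_transform <- function(scaler, deltas) {
  stopifnot(inherits(scaler, "maxabs_scaler"))
  vec_in <- !is.data.frame(deltas) && is.null(dim(deltas))
  if (vec_in) deltas <- as.data.frame(as.list(deltas))
  out <- deltas[, scaler$metrics, drop = FALSE]
  for (m in scaler$metrics) out[[m]] <- out[[m]] / scaler$scale_factors[[m]]
  if (vec_in) unlist(out[1L, , drop = TRUE]) else out
}

# one data-frame row as a named numeric vector (drop=TRUE loses names
# on single-column frames, so this is spelled out)
row_as_vector <- function(df, i = 1L) {
  stats::setNames(as.numeric(df[i, ]), names(df))
}

#' Combined sum of scaled deltas over a metric subset
#'
#' Sums MaxAbs-scaled deltas over the subset, orienting decrease-good
#' metrics by negation so every term contributes positively when it
#' favours the new model. Missing scaled values contribute 0 and are
#' reported through the `coverage` attribute (present / subset size).
#'
#' @param scaled Named numeric vector of scaled deltas.
#' @param subset Metric names to sum (non-empty).
#' @param directions Direction table from [metric_directions()].
#' @return Sum, with attribute `coverage` = number of non-missing terms.
#' @export
combined_sum <- function(scaled, subset,
                         directions = metric_directions()) {
  if (length(subset) < 1L) stop("empty metric subset")
  vals <- vapply(subset, function(m) {
    v <- if (m %in% names(scaled)) scaled[[m]] else NA_real_
    if (is.na(v)) return(NA_real_)
    if (m %in% names(directions) && directions[[m]] == "decrease") -v else v
  }, numeric(1))
  s <- sum(vals, na.rm = TRUE)
  attr(s, "coverage") <- sum(!is.na(vals))
  s
}

#' Win/lose call from a combined score
#'
#' Strict at zero: positive sums are a win for the new model (+1),
#' negative sums a lose (-1), exactly zero is neither (0).
#'
#' @param sum_value Finite combined score.
#' @return -1, 0 or +1.
#' @export
win_lose <- function(sum_value) {
  if (!is.finite(sum_value)) stop("win_lose requires a finite input")
  sign(sum_value)
}

#' Tally win/lose/no-change outcomes
#' @param signs Vector of -1/0/+1 outcome calls.
#' @return Named integer vector `up`, `same`, `down` (sums to the input
#'   length).
#' @export
tally_outcomes <- function(signs) {
  if (length(signs) < 1L) stop("empty outcome collection")
  c(up = sum(signs > 0), same = sum(signs == 0), down = sum(signs < 0))
}

#' Default scoring contexts for combined sums
#'
#' The four scaling/summing contexts used throughout: all 11 canonical
#' variables, and the best single variable from each tool — count of
#' residues above pLDDT 80, Foldseek bitscore, IPR total domain length —
#' in the three combinations predictor + Foldseek + InterPro,
#' predictor + Foldseek, predictor + InterPro.
#' @return Named list of metric-name vectors.
#' @export
default_contexts <- function() {
  list(
    all11 = canonical_metrics(),
    af3_fs_ipr = c("n_plddt_gt_80", "fs_bitscore", "ipr_total_len"),
    af3_fs = c("n_plddt_gt_80", "fs_bitscore"),
    af3_ipr = c("n_plddt_gt_80", "ipr_total_len"))
}

#' Score all gene pairs of a dataset
#'
#' For every pair: raw deltas over the canonical metrics, per-metric sign
#' scores, MaxAbs-scaled deltas (factors fitted on this dataset's deltas,
#' separately per context), combined sums for each context, and win/lose
#' calls.
#'
#' @param scores Data frame of per-model score vectors (see
#'   [score_table()]), keyed by `model_id`.
#' @param pairs Data frame of pair metadata (see [read_pair_metadata()]).
#' @param contexts Named list of metric subsets; default
#'   [default_contexts()].
#' @param metrics Metrics to difference; default [canonical_metrics()].
#' @return Data frame, one row per pair: `delta_*`, `sign_*`, `scaled_*`
#'   (all-11 context), and per context `sum_<ctx>`, `win_<ctx>`,
#'   `coverage_<ctx>`.
#' @export
score_pairs <- function(scores, pairs, contexts = default_contexts(),
                        metrics = canonical_metrics()) {
  if (anyDuplicated(scores$model_id))
    stop("duplicate model_id in score table")
  rownames(scores) <- scores$model_id
  missing_models <- setdiff(c(pairs$old_model_id, pairs$new_model_id),
                            scores$model_id)
  if (length(missing_models))
    stop("score table lacks model(s): ",
         paste(utils::head(missing_models, 5), collapse = ", "))
  dirs <- metric_directions()

  deltas <- t(vapply(seq_len(nrow(pairs)), function(i) {
    delta_vector(scores[pairs$new_model_id[i], , drop = FALSE],
                 scores[pairs$old_model_id[i], , drop = FALSE],
                 metrics = metrics)
  }, numeric(length(metrics))))
  deltas <- as.data.frame(deltas)
  names(deltas) <- metrics

  signs <- as.data.frame(lapply(metrics, function(m)
    vapply(deltas[[m]], function(d) sign_score(m, d, dirs), numeric(1))))
  names(signs) <- metrics

  out <- data.frame(gene_id = pairs$gene_id, stringsAsFactors = FALSE)
  for (m in metrics) out[[paste0("delta_", m)]] <- deltas[[m]]
  for (m in metrics) out[[paste0("sign_", m)]] <- signs[[m]]

  # scaled values of the all-11 context are reported per metric
  for (ctx in names(contexts)) {
    sub <- contexts[[ctx]]
    scaler <- maxabs_fit(deltas, metrics = sub)
    scaled <- maxabs_transform(scaler, deltas)
    if (ctx == names(contexts)[1L])
      for (m in sub) out[[paste0("scaled_", m)]] <- scaled[[m]]
    sums <- numeric(nrow(deltas)); cov <- integer(nrow(deltas))
    for (i in seq_len(nrow(deltas))) {
      s <- combined_sum(row_as_vector(scaled, i), sub, dirs)
      sums[i] <- as.numeric(s); cov[i] <- attr(s, "coverage")
    }
    out[[paste0("sum_", ctx)]] <- sums
    out[[paste0("win_", ctx)]] <- vapply(sums, win_lose, numeric(1))
    out[[paste0("coverage_", ctx)]] <- cov
  }
  out
}

#' Outcome tallies per metric and context
#'
#' The stacked-bar numbers: for each metric the counts of pairs whose
#' sign score is +1 / 0 / -1, and for each combined context the win /
#' no-change / lose counts.
#'
#' @param pair_scores Data frame from [score_pairs()].
#' @return Data frame with columns `name`, `kind`, `up`, `same`, `down`.
#' @export
tally_table <- function(pair_scores) {
  sign_cols <- grep("^sign_", names(pair_scores), value = TRUE)
  win_cols <- grep("^win_", names(pair_scores), value = TRUE)
  rows <- lapply(c(sign_cols, win_cols), function(cn) {
    t <- tally_outcomes(pair_scores[[cn]])
    data.frame(name = sub("^(sign|win)_", "", cn),
               kind = if (grepl("^sign_", cn)) "metric" else "context",
               up = t[["up"]], same = t[["same"]], down = t[["down"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
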