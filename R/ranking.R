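#' Pooled per-model MaxAbs scaler
#'
#' Fits MaxAbs factors on the per-model metric values of *all* models in
#' the table (both members of every pair pooled), so old and new models
#' are placed on one scale and their combined scores can be
#' rank-compared within a pair.
#'
#' @param scores Per-model score table (see [score_table()]).
#' @param metrics Metrics entering the combined score; default the
#'   three best single variables (count of residues above pLDDT 80,
#'   Foldseek bitscore, IPR total domain length).
#' @return A `maxabs_scaler` fitted on the pooled values.
#' @export
per_model_scaler <- function(scores,
                             metrics = default_contexts()$af3_fs_ipr) {
  maxabs_fit(scores, metrics = metrics)
}

#' Combined MaxAbs-scaled score of one model
#'
#' Sum of the MaxAbs-scaled values of the scaler's metrics for one model
#' (decrease-good metrics oriented by negation, as in [combined_sum()]).
#'
#' @param vector One-row data frame or `model_scores`.
#' @param scaler Pooled scaler from [per_model_scaler()].
#' @return Combined score (numeric scalar).
#' @export
per_model_combined_score <- function(vector, scaler) {
  stopifnot(inherits(scaler, "maxabs_scaler"))
  row <- as.data.frame(vector)
  scaled <- maxabs_transform(scaler, row)
  as.numeric(combined_sum(row_as_vector(scaled), scaler$metrics))
}

#' Within-pair confidences from combined per-model scores
#'
#' For every gene pair, the combined scores of the new and old model
#' under a pooled MaxAbs scaling, their difference (the pair's
#' confidence), and which model the scores rank first.
#'
#' @param scores Per-model score table covering all pair members.
#' @param pairs Pair metadata data frame.
#' @param metrics Metrics of the combined score; default the three best
#'   single variables.
#' @return Data frame `gene_id`, `s_new`, `s_old`, `confidence`,
#'   `predicted_winner` (`"new"` / `"old"` / `"tie"`).
#' @export
pair_confidences <- function(scores, pairs,
                             metrics = default_contexts()$af3_fs_ipr) {
  keep <- scores$model_id %in% c(pairs$old_model_id, pairs$new_model_id)
  scaler <- per_model_scaler(scores[keep, , drop = FALSE], metrics = metrics)
  rownames(scores) <- scores$model_id
  s_new <- vapply(pairs$new_model_id, function(id)
    per_model_combined_score(scores[id, , drop = FALSE], scaler), numeric(1))
  s_old <- vapply(pairs$old_model_id, function(id)
    per_model_combined_score(scores[id, , drop = FALSE], scaler), numeric(1))
  conf <- s_new - s_old
  data.frame(gene_id = pairs$gene_id, s_new = s_new, s_old = s_old,
             confidence = conf,
             predicted_winner = ifelse(conf > 0, "new",
                                       ifelse(conf < 0, "old", "tie")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROC curve and AUC over ranked gene pairs
#'
#' Every pair's ground truth is that the curated (new) model is better,
#' so a pair where the combined scores rank the new model first is a
#' true positive and one ranking the old model first is a false
#' positive. Pairs are ordered by the magnitude of their confidence
#' (|s_new - s_old|) descending; walking down this order accumulates TPs
#' and FPs into a ROC curve, with equal-magnitude groups advancing as a
#' block (diagonal segment). Ties (confidence exactly 0) are excluded
#' from the curve and reported in `n_ties`. AUC is the trapezoidal area,
#' which equals the rank-sum (Mann-Whitney) probability that a random
#' correctly-ranked pair has larger |confidence| than a random
#' incorrectly-ranked one.
#'
#' @param confidences Data frame from [pair_confidences()] (needs a
#'   `confidence` column).
#' @return Object of class `roc_result`: list with `curve` (data frame
#'   `fpr`, `tpr`), `auc`, `n_tp_total`, `n_fp_total`, `n_ties`.
#' @export
roc_from_pairs <- function(confidences) {
  conf <- confidences$confidence
  if (is.null(conf)) stop("'confidences' must have a 'confidence' column")
  n_ties <- sum(conf == 0)
  conf <- conf[conf != 0]
  if (!length(conf))
    stop("all pairs are tied (confidence 0); no ROC curve is defined")
  n_pos <- sum(conf > 0); n_neg <- sum(conf < 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both correctly and incorrectly ranked pairs ",
         "(got ", n_pos, " positive, ", n_neg, " negative)")
  mag <- abs(conf)
  pos <- conf > 0
  # descending by magnitude; equal magnitudes advance as one block
  ord <- order(-mag)
  mag <- mag[ord]; pos <- pos[ord]
  blocks <- cumsum(!duplicated(mag))
  tp_by_block <- tapply(pos, blocks, sum)
  n_by_block <- tapply(pos, blocks, length)
  cum_tp <- cumsum(tp_by_block)
  cum_fp <- cumsum(n_by_block - tp_by_block)
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, n_tp_total = n_pos, n_fp_total = n_neg,
                 n_ties = n_ties),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", format(x$auc, digits = 4),
      " (", x$n_tp_total, " ranked new first, ", x$n_fp_total,
      " old first, ", x$n_ties, " tied)\n", sep = "")
  invisible(x)
}

#' Exhaustive pairwise AUC oracle
#'
#' Independent AUC estimate by direct pairwise comparison: over all
#' (positive, negative) combinations, the fraction where the positive
#' pair's |confidence| exceeds the negative's, plus half the exact-tie
#' fraction. Used to cross-check [roc_from_pairs()].
#'
#' @param confidences Data frame with a `confidence` column.
#' @return AUC in \[0, 1\].
#' @export
auc_oracle <- function(confidences) {
  conf <- confidences$confidence
  conf <- conf[conf != 0]
  p <- abs(conf[conf > 0]); n <- abs(conf[conf < 0])
  if (!length(p) || !length(n))
    stop("AUC oracle requires at least one positive and one negative pair")
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Model-level ROC formulation (sensitivity analysis)
#'
#' Alternative 2N-instance construction: each model is an instance with
#' its pooled combined score, labelled 1 for new models and 0 for old,
#' and the AUC is the standard probability that a random new model
#' outscores a random old one (ties counted half).
#'
#' @param confidences Data frame from [pair_confidences()].
#' @return AUC in \[0, 1\].
#' @export
auc_model_level <- function(confidences) {
  s <- c(confidences$s_new, confidences$s_old)
  lab <- rep(c(1, 0), each = nrow(confidences))
  p <- s[lab == 1]; n <- s[lab == 0]
  mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
}
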