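#' Pipeline configuration
#'
#' Collects input paths and options for the end-to-end analysis. Any
#' field can be left `NULL` when the corresponding stage is not run.
#'
#' @param confidence_dir Directory of per-model `*_confidences.json` /
#'   `*_summary.json` files.
#' @param foldseek_tsv,interproscan_tsv,metadata_csv Input file paths.
#' @param old_fasta,new_fasta Old/new proteome FASTA paths.
#' @param disorder_tsv Optional per-residue disorder TSV
#'   (`model_id`, `residue`, `disorder`).
#' @param out_dir Output directory.
#' @param max_identity Identity filter bound (strict `<`); `NULL`
#'   disables the filter (synthetic data under the null are
#'   sequence-identical, so the filter only applies to real datasets).
#' @param allowed_classes Change classes retained by the filter.
#' @param align Alignment parameters ([alignment_params()]).
#' @param alpha Foldseek E-value significance threshold.
#' @param thresholds,band_edges pLDDT threshold grid and band edges.
#' @param contexts Combined-sum contexts ([default_contexts()]).
#' @param roc_metrics Metrics of the per-model combined ROC score.
#' @param seed Seed recorded in the manifest (used by `simulate`).
#' @param log_level One of `"quiet"`, `"info"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(confidence_dir = NULL, foldseek_tsv = NULL,
                            interproscan_tsv = NULL, metadata_csv = NULL,
                            old_fasta = NULL, new_fasta = NULL,
                            disorder_tsv = NULL, out_dir = ".",
                            max_identity = 80,
                            allowed_classes = "changed",
                            align = alignment_params(), alpha = 0.05,
                            thresholds = c(50, 60, 70, 80, 90),
                            band_edges = c(0, 50, 60, 70, 80, 90),
                            contexts = default_contexts(),
                            roc_metrics = default_contexts()$af3_fs_ipr,
                            seed = 1, log_level = "info") {
  structure(as.list(environment()), class = "pipeline_config")
}

pipe_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[structscore] ", ...)
}

require_inputs <- function(config, fields) {
  for (f in fields) {
    v <- config[[f]]
    if (is.null(v))
      stop("pipeline config lacks required input: ", f, call. = FALSE)
    if (is.character(v) && !file.exists(v))
      stop("input path does not exist: ", v, " (", f, ")", call. = FALSE)
  }
}

write_manifest <- function(config, stage, inputs, out_dir) {
  digests <- lapply(inputs, function(p)
    if (!is.null(p) && file.exists(p) && !dir.exists(p))
      unname(tools::md5sum(p)) else NULL)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("structscore")),
    seed = config$seed,
    config = config[setdiff(names(config), "contexts")],
    input_md5 = digests[!vapply(digests, is.null, logical(1))])
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

read_disorder_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(seq_len(nrow(tab)), tab$model_id), function(i)
    tab$disorder[i][order(tab$residue[i])])
}

#' Run the pair-selection stage
#'
#' Computes old-versus-new global identities and applies the identity /
#' change-class filter; writes `retained_pairs.csv` with per-pair
#' identity and retention decisions.
#'
#' @param config A [pipeline_config()].
#' @return The retained pair data frame (invisibly the CSV is written).
#' @export
run_select <- function(config) {
  require_inputs(config, c("metadata_csv", "old_fasta", "new_fasta"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- read_pair_metadata(config$metadata_csv)
  pipe_log(config, "select: ", nrow(pairs), " candidate pairs")
  ids <- pair_identities(config$old_fasta, config$new_fasta, pairs,
                         config$align)
  if (is.null(config$max_identity)) {
    retained <- pairs[pairs$change_class %in% config$allowed_classes, ,
                      drop = FALSE]
    decisions <- data.frame(gene_id = pairs$gene_id,
                            identity = as.numeric(ids[pairs$gene_id]),
                            change_class = pairs$change_class,
                            retained = pairs$change_class %in%
                              config$allowed_classes)
  } else {
    retained <- filter_pairs(pairs, ids, config$max_identity,
                             config$allowed_classes)
    decisions <- attr(retained, "decisions")
  }
  utils::write.csv(decisions, file.path(config$out_dir, "retained_pairs.csv"),
                   row.names = FALSE)
  write_manifest(config, "select",
                 config[c("metadata_csv", "old_fasta", "new_fasta")],
                 config$out_dir)
  pipe_log(config, "select: retained ", nrow(retained), " pairs")
  invisible(retained)
}

#' Run the per-model scoring stage
#'
#' Reads every model's confidence JSON (and summary JSON when present),
#' Foldseek hits, InterProScan matches and optional disorder tracks for
#' the models named in the metadata, builds the per-model score vectors
#' and writes `model_scores.csv`.
#'
#' @param config A [pipeline_config()].
#' @return The per-model score table.
#' @export
run_score <- function(config) {
  require_inputs(config, c("confidence_dir", "metadata_csv"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- read_pair_metadata(config$metadata_csv)
  models <- c(pairs$old_model_id, pairs$new_model_id)
  fs <- if (!is.null(config$foldseek_tsv))
    read_foldseek_tsv(config$foldseek_tsv) else NULL
  ipr <- if (!is.null(config$interproscan_tsv))
    read_interproscan_tsv(config$interproscan_tsv) else NULL
  dis <- if (!is.null(config$disorder_tsv))
    read_disorder_tsv(config$disorder_tsv) else NULL
  pipe_log(config, "score: ", length(models), " models")
  scores <- lapply(models, function(id) {
    cj <- file.path(config$confidence_dir, paste0(id, "_confidences.json"))
    sj <- file.path(config$confidence_dir, paste0(id, "_summary.json"))
    if (!file.exists(cj)) stop("missing confidence JSON for model ", id)
    pred <- read_af3_confidences(cj, if (file.exists(sj)) sj else NULL,
                                 model_id = id)
    build_score_vector(
      pred,
      hits = if (!is.null(fs)) fs[fs$query == id, , drop = FALSE],
      matches = if (!is.null(ipr)) ipr[ipr$protein_id == id, , drop = FALSE],
      disorder = if (!is.null(dis)) as.numeric(dis[[id]]),
      thresholds = config$thresholds, band_edges = config$band_edges,
      alpha = config$alpha)
  })
  tab <- score_table(scores)
  write_scores_table(tab, file.path(config$out_dir, "model_scores.csv"))
  write_manifest(config, "score",
                 config[c("metadata_csv", "foldseek_tsv",
                          "interproscan_tsv", "disorder_tsv")],
                 config$out_dir)
  invisible(tab)
}

#' Run the pair-delta stage
#'
#' Differences, sign scores, MaxAbs-scaled values, combined sums and
#' win/lose calls per pair; writes `pair_deltas.csv` and `tallies.csv`.
#'
#' @param config A [pipeline_config()].
#' @param scores Optional per-model score table (read from
#'   `model_scores.csv` in `out_dir` when omitted).
#' @param pairs Optional pair metadata (read from `metadata_csv` when
#'   omitted).
#' @return The per-pair delta data frame.
#' @export
run_pairs <- function(config, scores = NULL, pairs = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(scores))
    scores <- read_scores_table(file.path(config$out_dir,
                                          "model_scores.csv"))
  if (is.null(pairs)) {
    require_inputs(config, "metadata_csv")
    pairs <- read_pair_metadata(config$metadata_csv)
  }
  pd <- score_pairs(scores, pairs, contexts = config$contexts)
  write_scores_table(pd, file.path(config$out_dir, "pair_deltas.csv"))
  utils::write.csv(tally_table(pd), file.path(config$out_dir, "tallies.csv"),
                   row.names = FALSE)
  pipe_log(config, "pairs: scored ", nrow(pd), " pairs")
  invisible(pd)
}

#' Run the ROC/AUC stage
#'
#' Pools both members of every pair, fits the per-model MaxAbs scaling,
#' ranks pairs by combined-score confidence and writes `roc_curve.csv`
#' plus a one-line `roc_summary.csv` (AUC, pair counts, ties).
#'
#' @param config A [pipeline_config()].
#' @param scores,pairs As in [run_pairs()].
#' @return The `roc_result`.
#' @export
run_roc <- function(config, scores = NULL, pairs = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(scores))
    scores <- read_scores_table(file.path(config$out_dir,
                                          "model_scores.csv"))
  if (is.null(pairs)) {
    require_inputs(config, "metadata_csv")
    pairs <- read_pair_metadata(config$metadata_csv)
  }
  conf <- pair_confidences(scores, pairs, metrics = config$roc_metrics)
  roc <- roc_from_pairs(conf)
  utils::write.csv(roc$curve, file.path(config$out_dir, "roc_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(auc = roc$auc, n_new_first = roc$n_tp_total,
               n_old_first = roc$n_fp_total, n_ties = roc$n_ties),
    file.path(config$out_dir, "roc_summary.csv"), row.names = FALSE)
  pipe_log(config, "roc: AUC ", format(roc$auc, digits = 4))
  invisible(roc)
}

#' Run the synthetic-data stage
#'
#' @param config A [pipeline_config()]; `seed` seeds the generator.
#' @param n_pairs Number of pairs to simulate.
#' @param ... Further [synthetic_config()] overrides.
#' @return The in-memory dataset (files written under `out_dir/dataset`).
#' @export
run_simulate <- function(config, n_pairs = 100, ...) {
  data_dir <- file.path(config$out_dir, "dataset")
  cfg <- synthetic_config(n_pairs = n_pairs, seed = config$seed, ...)
  pipe_log(config, "simulate: ", n_pairs, " pairs, seed ", config$seed)
  generate_dataset(cfg, data_dir)
}

#' Run the full pipeline on a synthetic or ingested dataset
#'
#' `simulate` (unless all inputs are supplied) then select, score,
#' pairs, roc, writing every stage's outputs and manifests under
#' `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param n_pairs Pairs to simulate when no inputs are given.
#' @param ... Passed to [run_simulate()].
#' @return List with `pairs_retained`, `scores`, `pair_deltas`, `roc`.
#' @export
run_all <- function(config, n_pairs = 100, ...) {
  if (is.null(config$metadata_csv)) {
    run_simulate(config, n_pairs = n_pairs, ...)
    dd <- file.path(config$out_dir, "dataset")
    config$metadata_csv <- file.path(dd, "metadata.csv")
    config$confidence_dir <- file.path(dd, "confidences")
    config$foldseek_tsv <- file.path(dd, "foldseek.tsv")
    config$interproscan_tsv <- file.path(dd, "interproscan.tsv")
    config$old_fasta <- file.path(dd, "proteins_old.faa")
    config$new_fasta <- file.path(dd, "proteins_new.faa")
    config$disorder_tsv <- file.path(dd, "disorder.tsv")
  }
  retained <- run_select(config)
  scores <- run_score(config)
  keep <- retained
  pd <- run_pairs(config, scores = scores, pairs = keep)
  roc <- run_roc(config, scores = scores, pairs = keep)
  invisible(list(pairs_retained = keep, scores = scores,
                 pair_deltas = pd, roc = roc))
}
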