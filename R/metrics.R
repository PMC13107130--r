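#' Count residues above a pLDDT threshold
#'
#' The number of residues whose pLDDT exceeds a confidence threshold —
#' the per-model statistic with the clearest old-versus-new signal in
#' curated gene model comparisons. The comparison is strict (`> threshold`)
#' by default; set `strict = FALSE` for `>=`.
#'
#' @param track Numeric per-residue pLDDT vector in \[0, 100\].
#' @param threshold Threshold in \[0, 100\].
#' @param strict Use strict inequality (default `TRUE`).
#' @return Integer count.
#' @export
count_plddt_ge <- function(track, threshold, strict = TRUE) {
  if (length(track) < 1L) stop("empty pLDDT track")
  if (threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]")
  if (strict) sum(track > threshold) else sum(track >= threshold)
}

#' Band counts of a pLDDT track
#'
#' Counts residues in half-open confidence bands `[e_i, e_{i+1})` defined
#' by increasing edges, plus a terminal band from the last edge to 100
#' inclusive. When the edges start at 0 the bands partition \[0, 100\] and
#' the counts sum to the track length.
#'
#' @param track Numeric per-residue pLDDT vector.
#' @param edges Strictly increasing thresholds within \[0, 100).
#' @return Named integer vector, names like `"[50,90)"` / `"[90,100]"`.
#' @export
plddt_band_counts <- function(track, edges = c(0, 50, 60, 70, 80, 90)) {
  if (length(track) < 1L) stop("empty pLDDT track")
  if (length(edges) < 1L) stop("at least one band edge is required")
  if (any(diff(edges) <= 0)) stop("band edges must be strictly increasing")
  if (any(edges < 0) || any(edges >= 100))
    stop("band edges must lie in [0, 100)")
  lo <- edges
  hi <- c(edges[-1L], 100)
  counts <- integer(length(lo))
  for (i in seq_along(lo)) {
    counts[i] <- if (i == length(lo))
      sum(track >= lo[i] & track <= 100) else
      sum(track >= lo[i] & track < hi[i])
  }
  names(counts) <- c(
    if (length(lo) > 1L) sprintf("[%g,%g)", lo[-length(lo)], hi[-length(hi)]),
    sprintf("[%g,100]", lo[length(lo)]))
  counts
}

#' Median pLDDT of a track
#' @param track Numeric per-residue pLDDT vector.
#' @return Median (mean of the central two values for even length).
#' @export
median_plddt <- function(track) {
  if (length(track) < 1L) stop("empty pLDDT track")
  stats::median(track)
}

#' Mean predicted aligned error
#'
#' Arithmetic mean over all entries of the PAE matrix. The diagonal
#' (self-error, approximately zero) is included by default; excluding it
#' is available since the choice changes the value by O(1/n).
#'
#' @param pae Square non-negative numeric matrix.
#' @param include_diagonal Include diagonal entries (default `TRUE`).
#' @return Mean PAE.
#' @export
mean_pae <- function(pae, include_diagonal = TRUE) {
  pae <- as.matrix(pae)
  if (length(pae) < 1L) stop("empty PAE matrix")
  if (nrow(pae) != ncol(pae)) stop("PAE matrix must be square")
  if (include_diagonal) mean(pae) else mean(pae[row(pae) != col(pae)])
}

#' Select the top Foldseek hit for one query
#'
#' The hit with the lowest E-value; ties broken by the highest bitscore,
#' then lexicographically smallest target id, so selection is
#' deterministic.
#'
#' @param hits Data frame of Foldseek hits sharing one `query` id
#'   (see [read_foldseek_tsv()]).
#' @return One-row data frame, or `NULL` for an empty hit list.
#' @export
select_top_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (length(unique(hits$query)) > 1L)
    stop("hits for multiple queries passed to select_top_hit: ",
         paste(unique(hits$query), collapse = ", "))
  ord <- order(hits$evalue, -hits$bits, hits$target)
  hits[ord[1L], , drop = FALSE]
}

#' Mask Foldseek scores by E-value significance
#'
#' Non-significant structure hits carry no evidence: when the top hit is
#' absent or its E-value is not below `alpha`, the E-value is set to the
#' sentinel 10 and bitscore, LDDT and alntmscore are set to 0; otherwise
#' the scores pass through unchanged. The operation is idempotent.
#'
#' @param top_hit One-row data frame or named list with `evalue`, `bits`,
#'   and optionally `lddt`, `alntmscore`; or `NULL` for no hit.
#' @param alpha Significance threshold on the E-value (default 0.05).
#' @return Named list `evalue`, `bitscore`, `lddt`, `alntmscore`,
#'   `significant`.
#' @export
mask_foldseek <- function(top_hit, alpha = 0.05) {
  if (alpha <= 0) stop("alpha must be positive")
  masked <- list(evalue = 10, bitscore = 0, lddt = 0, alntmscore = 0,
                 significant = FALSE)
  if (is.null(top_hit)) return(masked)
  hit <- as.list(top_hit)
  if (!is.null(hit$bits) && is.null(hit$bitscore)) hit$bitscore <- hit$bits
  if (is.na(hit$evalue) || hit$evalue >= alpha) return(masked)
  list(evalue = as.numeric(hit$evalue),
       bitscore = as.numeric(hit$bitscore),
       lddt = if (is.null(hit$lddt)) NA_real_ else as.numeric(hit$lddt),
       alntmscore = if (is.null(hit$alntmscore)) NA_real_ else
         as.numeric(hit$alntmscore),
       significant = TRUE)
}

#' InterPro domain length summaries for one protein
#'
#' Restricts to matches with an integrated IPR accession, takes the
#' length of the longest domain and the total length of all domains
#' (1-based inclusive coordinates, so length = end - start + 1). The
#' total is a plain sum by default — overlapping domains double-count;
#' `mode = "union"` measures the union of the intervals instead.
#'
#' @param matches Data frame from [read_interproscan_tsv()] for one
#'   protein (may be empty or `NULL`).
#' @param mode `"sum"` (default) or `"union"`.
#' @return Named list `max_len`, `total_len`, `n_domains`.
#' @export
ipr_lengths <- function(matches, mode = c("sum", "union")) {
  mode <- match.arg(mode)
  if (is.null(matches) || nrow(matches) == 0L)
    return(list(max_len = 0L, total_len = 0L, n_domains = 0L))
  keep <- !is.na(matches$ipr_accession)
  matches <- matches[keep, , drop = FALSE]
  if (nrow(matches) == 0L)
    return(list(max_len = 0L, total_len = 0L, n_domains = 0L))
  len <- matches$end - matches$start + 1L
  total <- if (mode == "sum") sum(len) else {
    # union of 1-based inclusive intervals
    ord <- order(matches$start, matches$end)
    s <- matches$start[ord]; e <- matches$end[ord]
    tot <- 0L; cur_s <- s[1L]; cur_e <- e[1L]
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= cur_e + 1L) cur_e <- max(cur_e, e[i]) else {
        tot <- tot + (cur_e - cur_s + 1L); cur_s <- s[i]; cur_e <- e[i]
      }
    }
    tot + (cur_e - cur_s + 1L)
  }
  list(max_len = max(len), total_len = total, n_domains = nrow(matches))
}

#' Mean intrinsic disorder of a protein
#' @param disorder_track Per-residue disorder scores in \[0, 1\].
#' @return Arithmetic mean.
#' @export
mean_disorder <- function(disorder_track) {
  if (length(disorder_track) < 1L) stop("empty disorder track")
  if (any(disorder_track < 0 | disorder_track > 1, na.rm = TRUE) ||
      anyNA(disorder_track))
    stop("disorder scores must lie in [0, 1]")
  mean(disorder_track)
}

#' The canonical 11-variable metric set
#'
#' The per-model variables combined in delta scoring and score fusion:
#' five predictor-confidence variables (median pLDDT, pTM, mean PAE and
#' the counts of residues above pLDDT 80 and 90), four masked Foldseek
#' variables (LDDT, alntmscore, bitscore, E-value) and two InterPro
#' domain-length variables (max and total).
#' @return Character vector of metric names.
#' @export
canonical_metrics <- function() {
  c("median_plddt", "ptm", "mean_pae", "n_plddt_gt_80", "n_plddt_gt_90",
    "fs_lddt", "fs_alntmscore", "fs_bitscore", "fs_evalue",
    "ipr_max_len", "ipr_total_len")
}

#' Build the per-model score vector
#'
#' Assembles every per-model metric from a structure prediction and the
#' optional Foldseek hits, InterProScan matches and disorder track for
#' the same model: pLDDT summaries and threshold/band counts, pTM, mean
#' PAE, E-value-masked Foldseek scores, and IPR domain lengths.
#'
#' @param prediction A [structure_prediction()].
#' @param hits Foldseek hits for this model's query id (or `NULL`).
#' @param matches InterProScan matches for this protein (or `NULL`).
#' @param disorder Optional per-residue disorder track in \[0, 1\].
#' @param thresholds pLDDT thresholds for the `n_plddt_gt_*` counts.
#' @param band_edges Edges for [plddt_band_counts()].
#' @param alpha Foldseek E-value significance threshold.
#' @param strict Strict threshold comparison (see [count_plddt_ge()]).
#' @param ipr_mode Total-length mode (see [ipr_lengths()]).
#' @param pae_diagonal Include the PAE diagonal (see [mean_pae()]).
#' @return Object of class `model_scores`: a named list of metrics;
#'   convert with `as.data.frame()` for tabular output.
#' @export
build_score_vector <- function(prediction, hits = NULL, matches = NULL,
                               disorder = NULL,
                               thresholds = c(50, 60, 70, 80, 90),
                               band_edges = c(0, 50, 60, 70, 80, 90),
                               alpha = 0.05, strict = TRUE,
                               ipr_mode = "sum", pae_diagonal = TRUE) {
  stopifnot(inherits(prediction, "structure_prediction"))
  track <- prediction$plddt
  counts <- vapply(thresholds, function(t)
    count_plddt_ge(track, t, strict = strict), integer(1))
  names(counts) <- sprintf("n_plddt_gt_%g", thresholds)
  fs <- mask_foldseek(select_top_hit(hits), alpha = alpha)
  ipr <- ipr_lengths(matches, mode = ipr_mode)
  out <- c(
    list(model_id = prediction$model_id,
         n_residues = length(track),
         median_plddt = median_plddt(track),
         mean_plddt = mean(track),
         ptm = prediction$ptm,
         mean_pae = if (is.null(prediction$pae)) NA_real_ else
           mean_pae(prediction$pae, include_diagonal = pae_diagonal)),
    as.list(counts),
    list(fs_evalue = fs$evalue, fs_bitscore = fs$bitscore,
         fs_lddt = fs$lddt, fs_alntmscore = fs$alntmscore,
         fs_significant = fs$significant,
         ipr_max_len = ipr$max_len, ipr_total_len = ipr$total_len,
         n_ipr_domains = ipr$n_domains,
         mean_disorder = if (is.null(disorder)) NA_real_ else
           mean_disorder(disorder)))
  out$band_counts <- plddt_band_counts(track, band_edges)
  structure(out, class = "model_scores")
}

#' @export
as.data.frame.model_scores <- function(x, ...) {
  bands <- x$band_counts
  flat <- x[setdiff(names(x), "band_counts")]
  df <- as.data.frame(flat, stringsAsFactors = FALSE)
  bdf <- as.data.frame(as.list(bands))
  names(bdf) <- paste0("band_", gsub("[^0-9]+", "_", names(bands)))
  names(bdf) <- sub("_$", "", names(bdf))
  cbind(df, bdf)
}

#' Combine per-model score vectors into one table
#' @param scores List of `model_scores` objects.
#' @return Data frame, one row per model.
#' @export
score_table <- function(scores) {
  do.call(rbind, lapply(scores, as.data.frame))
}
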