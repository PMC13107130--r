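#' Global alignment parameters
#'
#' Scoring scheme for global protein alignment of old versus new model
#' translations. Gap penalties are expressed as non-positive scores
#' (`gap_open <= gap_extend <= 0`). The identity denominator controls
#' the percent-identity definition: full alignment length including
#' gapped columns (default), the shorter sequence's length, or aligned
#' (ungapped) columns only.
#'
#' @param substitution_matrix Matrix name known to Biostrings (e.g.
#'   `"BLOSUM62"`) or a numeric substitution matrix.
#' @param gap_open,gap_extend Non-positive gap scores (open includes the
#'   first gapped position's extension under the affine model).
#' @param identity_denominator One of `"alignment_length"`,
#'   `"shorter_sequence"`, `"aligned_columns"`.
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = -10, gap_extend = -0.5,
                             identity_denominator = c(
                               "alignment_length", "shorter_sequence",
                               "aligned_columns")) {
  identity_denominator <- match.arg(identity_denominator)
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("gap penalties must satisfy gap_open <= gap_extend <= 0")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 identity_denominator = identity_denominator),
            class = "alignment_params")
}

aa_alphabet_ok <- function(seq) {
  grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seq)
}

#' Global percent identity between two protein sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under the given scoring
#' scheme; identity is the percentage of identical aligned columns over
#' the configured denominator.
#'
#' @param seq_a,seq_b Amino-acid sequences (20-letter alphabet plus X).
#' @param params An [alignment_params()].
#' @return Percent identity in \[0, 100\].
#' @export
global_identity <- function(seq_a, seq_b, params = alignment_params()) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence passed to global_identity")
    if (!aa_alphabet_ok(s))
      stop("illegal characters in protein sequence (allowed: 20 amino ",
           "acids plus X)")
  }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = abs(params$gap_open) - abs(params$gap_extend),
    gapExtension = abs(params$gap_extend))
  pid_type <- switch(params$identity_denominator,
                     alignment_length = "PID1",
                     aligned_columns = "PID2",
                     shorter_sequence = "PID3")
  Biostrings::pid(aln, type = pid_type)
}

#' Raw global alignment score (for oracle checks)
#' @inheritParams global_identity
#' @return Optimal global alignment score.
#' @export
global_alignment_score <- function(seq_a, seq_b, params = alignment_params()) {
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = abs(params$gap_open) - abs(params$gap_extend),
    gapExtension = abs(params$gap_extend))
  Biostrings::score(aln)
}

#' Identity of every gene pair from old/new proteomes
#'
#' @param old_fasta,new_fasta Paths to the old and new protein FASTA
#'   files, sequence names matching the model ids of `pairs`.
#' @param pairs Pair metadata data frame.
#' @param params An [alignment_params()].
#' @return Named numeric vector of percent identities keyed by gene id.
#' @export
pair_identities <- function(old_fasta, new_fasta, pairs,
                            params = alignment_params()) {
  old <- Biostrings::readAAStringSet(old_fasta)
  new <- Biostrings::readAAStringSet(new_fasta)
  names(old) <- sub("\\s.*$", "", names(old))
  names(new) <- sub("\\s.*$", "", names(new))
  miss_old <- setdiff(pairs$old_model_id, names(old))
  miss_new <- setdiff(pairs$new_model_id, names(new))
  if (length(miss_old) || length(miss_new))
    stop("FASTA lacks sequence(s): ",
         paste(utils::head(c(miss_old, miss_new), 5), collapse = ", "))
  ids <- vapply(seq_len(nrow(pairs)), function(i)
    global_identity(as.character(old[[pairs$old_model_id[i]]]),
                    as.character(new[[pairs$new_model_id[i]]]),
                    params), numeric(1))
  stats::setNames(ids, pairs$gene_id)
}

#' Filter gene pairs by identity and change class
#'
#' Dataset-construction rule: retain a pair only when old and new
#' translations share strictly less than `max_identity` percent
#' identity (substantial structural change) and the edit is of an
#' allowed class (`"changed"`: amended exon/intron/UTR boundaries).
#' Retention decisions for every input pair are attached as the
#' `"decisions"` attribute.
#'
#' @param pairs Pair metadata data frame.
#' @param identities Named percent-identity vector keyed by `gene_id`
#'   (see [pair_identities()]).
#' @param max_identity Strict upper identity bound (default 80).
#' @param allowed_classes Retained change classes (default `"changed"`).
#' @return The retained subset of `pairs`, with a `"decisions"`
#'   attribute logging every pair's identity and outcome.
#' @export
filter_pairs <- function(pairs, identities, max_identity = 80,
                         allowed_classes = "changed") {
  miss <- setdiff(pairs$gene_id, names(identities))
  if (length(miss))
    stop("no identity value for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  idv <- as.numeric(identities[pairs$gene_id])
  if (anyNA(idv))
    stop("missing identity value for gene(s): ",
         paste(pairs$gene_id[is.na(idv)], collapse = ", "))
  keep <- idv < max_identity & pairs$change_class %in% allowed_classes
  decisions <- data.frame(gene_id = pairs$gene_id, identity = idv,
                          change_class = pairs$change_class,
                          retained = keep, stringsAsFactors = FALSE)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "decisions") <- decisions
  out
}
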