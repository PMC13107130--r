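#' Read predictor confidence JSON into a structure prediction
#'
#' Parses the confidence output of an AlphaFold-3-class predictor. Two
#' layouts are accepted, because the predictor family splits its scores
#' across files: a "full confidences" JSON carrying either a per-residue
#' `plddt` array or a per-atom `atom_plddts` array (with `atom_res_ids`
#' and optionally `atom_chain_ids` / `atom_names` for grouping), plus an
#' optional `pae` matrix; and a separate "summary" JSON carrying `ptm`.
#' Per-atom values are reduced to one value per residue by `atom_reduce`
#' (arithmetic mean over the residue's atoms by default, or CA only).
#'
#' @param confidence_json Path to the confidence JSON file.
#' @param summary_json Optional path to the summary JSON (read for `ptm`).
#' @param model_id Model identifier; defaults to the `model_id`/`name`
#'   field of the JSON, falling back to the file name.
#' @param atom_reduce Atom-to-residue reduction rule, `"mean"` or `"ca"`.
#' @return A [structure_prediction()].
#' @export
read_af3_confidences <- function(confidence_json, summary_json = NULL,
                                 model_id = NULL,
                                 atom_reduce = c("mean", "ca")) {
  atom_reduce <- match.arg(atom_reduce)
  conf <- tryCatch(jsonlite::read_json(confidence_json, simplifyVector = TRUE),
                   error = function(e)
                     stop("malformed confidence JSON '", confidence_json,
                          "': ", conditionMessage(e)))
  if (is.null(model_id))
    model_id <- conf$model_id %||% conf$name %||%
      sub("\\.json$", "", basename(confidence_json))

  if (!is.null(conf$plddt)) {
    track <- as.numeric(conf$plddt)
  } else if (!is.null(conf$atom_plddts)) {
    if (is.null(conf$atom_res_ids))
      stop("confidence JSON '", confidence_json,
           "' has 'atom_plddts' but no 'atom_res_ids' residue grouping")
    track <- reduce_atoms_to_residues(
      as.numeric(conf$atom_plddts), conf$atom_res_ids,
      atom_names = conf$atom_names, chain_ids = conf$atom_chain_ids,
      reduce = atom_reduce)
  } else {
    stop("confidence JSON '", confidence_json,
         "' contains neither 'plddt' nor 'atom_plddts'")
  }

  pae <- if (!is.null(conf$pae)) as.matrix(conf$pae) else NULL

  ptm <- NA_real_
  if (!is.null(summary_json)) {
    summ <- tryCatch(jsonlite::read_json(summary_json, simplifyVector = TRUE),
                     error = function(e)
                       stop("malformed summary JSON '", summary_json, "': ",
                            conditionMessage(e)))
    if (!is.null(summ$ptm)) ptm <- as.numeric(summ$ptm)
  } else if (!is.null(conf$ptm)) {
    ptm <- as.numeric(conf$ptm)
  }

  structure_prediction(model_id, track, pae = pae, ptm = ptm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-residue pLDDT from an mmCIF file
#'
#' Extracts the `atom_site` loop of an mmCIF file and reads pLDDT from the
#' B-factor column (`B_iso_or_equiv`), the convention used by distributed
#' predictor mmCIF output. Atoms are grouped into residues by chain and
#' sequence id and reduced under the same rule as [read_af3_confidences()],
#' so both carriers of the same model agree.
#'
#' @param mmcif Path to the mmCIF file.
#' @param model_id Model identifier; defaults to the mmCIF data block name.
#' @param atom_reduce Atom-to-residue reduction rule, `"mean"` or `"ca"`.
#' @return A [structure_prediction()] with `pae` and `ptm` absent.
#' @export
read_plddt_from_mmcif <- function(mmcif, model_id = NULL,
                                  atom_reduce = c("mean", "ca")) {
  atom_reduce <- match.arg(atom_reduce)
  lines <- readLines(mmcif, warn = FALSE)
  if (is.null(model_id)) {
    blk <- grep("^data_", lines, value = TRUE)
    model_id <- if (length(blk)) sub("^data_", "", blk[1L]) else
      sub("\\.cif$", "", basename(mmcif))
  }
  # locate the atom_site loop: header lines name the columns in order
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx))
    stop("no atom_site records in '", mmcif, "'")
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body <- lines[seq(max(hdr_idx) + 1L, length(lines))]
  rows <- body[grepl("^(ATOM|HETATM)\\s", body)]
  stop_at <- grep("^(#|loop_|_)", body)
  if (length(stop_at))
    rows <- body[seq_len(stop_at[1L] - 1L)]
  rows <- rows[grepl("^(ATOM|HETATM)\\s", rows)]
  if (!length(rows))
    stop("no atom_site records in '", mmcif, "'")
  fields <- strsplit(trimws(rows), "\\s+")
  bad <- which(lengths(fields) != length(cols))
  if (length(bad))
    stop("atom_site row ", bad[1L], " of '", mmcif, "' has ",
         lengths(fields)[bad[1L]], " fields, expected ", length(cols))
  tab <- do.call(rbind, fields)
  colnames(tab) <- cols
  need <- c("label_seq_id", "B_iso_or_equiv")
  if (!all(need %in% cols))
    stop("atom_site loop of '", mmcif, "' lacks column(s): ",
         paste(setdiff(need, cols), collapse = ", "))
  chain <- if ("label_asym_id" %in% cols) tab[, "label_asym_id"] else NULL
  atom <- if ("label_atom_id" %in% cols) tab[, "label_atom_id"] else NULL
  track <- reduce_atoms_to_residues(
    as.numeric(tab[, "B_iso_or_equiv"]), as.integer(tab[, "label_seq_id"]),
    atom_names = atom, chain_ids = chain, reduce = atom_reduce)
  structure_prediction(model_id, track, source_tool = "mmcif")
}

#' Default Foldseek tabular column layout
#'
#' The conventional 12-column tabular search output with `lddt` and
#' `alntmscore` appended, the layout this package's tools write and read.
#' @return Character vector of column names.
#' @export
foldseek_columns <- function() {
  c("query", "target", "fident", "alnlen", "mismatch", "gapopen",
    "qstart", "qend", "tstart", "tend", "evalue", "bits",
    "lddt", "alntmscore")
}

#' Read Foldseek tabular hits
#'
#' @param tsv Path to a tab-separated Foldseek result file (no header).
#' @param column_names Ordered column labels describing the layout;
#'   defaults to [foldseek_columns()]. Must contain at least `query`,
#'   `target`, `evalue` and `bits`.
#' @return A data frame with one row per hit; numeric columns parsed.
#' @export
read_foldseek_tsv <- function(tsv, column_names = foldseek_columns()) {
  need <- c("query", "target", "evalue", "bits")
  if (!all(need %in% column_names))
    stop("column_names must include: ", paste(need, collapse = ", "))
  lines <- readLines(tsv, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(column_names)),
                    column_names), stringsAsFactors = FALSE)
  if (!length(lines)) return(coerce_foldseek(empty, column_names))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(column_names))
  if (length(bad))
    stop("Foldseek row ", bad[1L], " has ", lengths(fields)[bad[1L]],
         " fields, expected ", length(column_names))
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- column_names
  coerce_foldseek(tab, column_names)
}

coerce_foldseek <- function(tab, column_names) {
  num_cols <- setdiff(column_names, c("query", "target"))
  for (cn in num_cols) tab[[cn]] <- as.numeric(tab[[cn]])
  if (nrow(tab)) {
    if (any(tab$evalue < 0)) stop("negative E-value in Foldseek input")
    if (any(tab$bits < 0)) stop("negative bitscore in Foldseek input")
  }
  tab
}

#' Read InterProScan TSV output
#'
#' Parses the standard InterProScan tab-separated layout (protein id, md5,
#' length, analysis, signature accession/description, start, stop, score,
#' status, date, InterPro accession, description, ...). Coordinates are
#' kept 1-based inclusive; a `-` in the InterPro accession column becomes
#' `NA` so that matches without an integrated IPR entry can be filtered.
#'
#' @param tsv Path to the InterProScan TSV file (no header).
#' @return Data frame with columns `protein_id`, `signature_accession`,
#'   `ipr_accession` (`NA` when not integrated), `start`, `end`.
#' @export
read_interproscan_tsv <- function(tsv) {
  lines <- readLines(tsv, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- data.frame(protein_id = character(0),
                    signature_accession = character(0),
                    ipr_accession = character(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  if (!length(lines)) return(out)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8L)
  if (length(bad))
    stop("InterProScan row ", bad[1L], " has ", lengths(fields)[bad[1L]],
         " fields, expected at least 8")
  get <- function(i) vapply(fields, function(f) f[i], "")
  start <- suppressWarnings(as.integer(get(7L)))
  end <- suppressWarnings(as.integer(get(8L)))
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinates in InterProScan row ",
         which(is.na(start) | is.na(end))[1L])
  ipr <- vapply(fields, function(f) if (length(f) >= 12L) f[12L] else "-", "")
  ipr[ipr == "-" | ipr == ""] <- NA_character_
  bad_coord <- which(start < 1L | end < start)
  if (length(bad_coord))
    stop("invalid coordinates (start ", start[bad_coord[1L]], ", end ",
         end[bad_coord[1L]], ") in InterProScan row ", bad_coord[1L])
  data.frame(protein_id = get(1L), signature_accession = get(5L),
             ipr_accession = ipr, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Declared vocabulary of gene-model change classes
#' @return Character vector of the accepted `change_class` labels.
#' @export
change_classes <- function() {
  c("changed", "split", "merged", "deleted", "created")
}

#' Read gene-pair metadata CSV
#'
#' @param csv Path to a CSV with header columns `gene_id`, `old_model_id`,
#'   `new_model_id`, `change_class` and optionally `species_tag`.
#' @param allowed_classes Vocabulary the `change_class` column is checked
#'   against; defaults to [change_classes()].
#' @return Data frame of validated pair records.
#' @export
read_pair_metadata <- function(csv, allowed_classes = change_classes()) {
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("gene_id", "old_model_id", "new_model_id", "change_class")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pair metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!"species_tag" %in% names(tab)) tab$species_tag <- NA_character_
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in pair metadata: ",
         paste(unique(dup), collapse = ", "))
  unknown <- setdiff(unique(tab$change_class), allowed_classes)
  if (length(unknown))
    stop("unknown change_class value(s): ", paste(unknown, collapse = ", "))
  same <- tab$gene_id[tab$old_model_id == tab$new_model_id]
  if (length(same))
    stop("old and new model ids identical for gene(s): ",
         paste(same, collapse = ", "))
  tab[, c(need, "species_tag")]
}

#' Write / read a scores table
#'
#' CSV round-trip for per-model score vectors and per-pair delta tables:
#' stable column order, missing values as empty cells, full double
#' precision so re-reading reproduces values to well under 1e-9.
#'
#' @param rows Data frame (e.g. from [score_table()] or [score_pairs()]).
#' @param path Output CSV path.
#' @return `write_scores_table()` returns `path` invisibly;
#'   `read_scores_table()` returns the data frame.
#' @export
write_scores_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("'rows' must be a data frame")
  out <- rows
  for (cn in names(out)) {
    if (is.double(out[[cn]]))
      out[[cn]] <- ifelse(is.na(out[[cn]]), NA_character_,
                          formatC(out[[cn]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' @rdname write_scores_table
#' @export
read_scores_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
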