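#' Per-model structure prediction confidence data
#'
#' Container for the confidence output of one modelled protein: the
#' per-residue pLDDT track, optionally the PAE matrix and the global pTM.
#' All readers in the package return this class.
#'
#' @param model_id Identifier of the gene model / protein.
#' @param plddt Numeric vector of per-residue pLDDT values in \[0, 100\],
#'   one per residue, in sequence order.
#' @param pae Optional square numeric matrix of predicted aligned errors
#'   (non-negative), side equal to the number of tokens/residues.
#' @param ptm Optional predicted template-modelling score in \[0, 1\];
#'   `NA` when the predictor did not report one.
#' @param source_tool Label for the predictor family the data came from.
#'
#' @return An object of class `structure_prediction`: a list with elements
#'   `model_id`, `plddt`, `pae` (matrix or `NULL`), `ptm` (`NA` when
#'   absent) and `source_tool`.
#' @export
structure_prediction <- function(model_id, plddt, pae = NULL, ptm = NA_real_,
                                 source_tool = "af3-like") {
  if (!is.character(model_id) || length(model_id) != 1L || is.na(model_id))
    stop("'model_id' must be a single string")
  plddt <- as.numeric(plddt)
  if (length(plddt) < 1L)
    stop("pLDDT track must contain at least one residue")
  if (anyNA(plddt) || any(plddt < 0 | plddt > 100))
    stop("pLDDT values must lie in [0, 100] for model '", model_id, "'")
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae))
      stop("PAE matrix must be square (got ", nrow(pae), " x ", ncol(pae),
           ") for model '", model_id, "'")
    if (anyNA(pae) || any(pae < 0))
      stop("PAE entries must be non-negative for model '", model_id, "'")
  }
  if (!is.na(ptm) && (ptm < 0 || ptm > 1))
    stop("pTM must lie in [0, 1] for model '", model_id, "'")
  structure(
    list(model_id = model_id, plddt = plddt, pae = pae,
         ptm = as.numeric(ptm), source_tool = source_tool),
    class = "structure_prediction"
  )
}

#' @export
print.structure_prediction <- function(x, ...) {
  cat("<structure_prediction> ", x$model_id, "\n",
      "  residues: ", length(x$plddt),
      "  median pLDDT: ", format(stats::median(x$plddt), digits = 4),
      "\n  pTM: ", if (is.na(x$ptm)) "absent" else format(x$ptm, digits = 3),
      "  PAE: ", if (is.null(x$pae)) "absent" else
        paste0(nrow(x$pae), "x", ncol(x$pae)),
      "\n", sep = "")
  invisible(x)
}

# Reduce per-atom pLDDT values to one value per residue.  `reduce` is the
# atom->residue rule: mean over all atoms (default) or the CA atom only.
reduce_atoms_to_residues <- function(plddt, res_ids, atom_names = NULL,
                                     chain_ids = NULL,
                                     reduce = c("mean", "ca")) {
  reduce <- match.arg(reduce)
  if (length(plddt) != length(res_ids))
    stop("per-atom pLDDT list and residue ids differ in length")
  key <- if (is.null(chain_ids)) as.character(res_ids) else
    paste(chain_ids, res_ids, sep = "\r")
  if (reduce == "ca") {
    if (is.null(atom_names))
      stop("CA-only reduction requested but atom names are absent")
    keep <- atom_names == "CA"
    if (!any(keep)) stop("CA-only reduction requested but no CA atoms found")
    plddt <- plddt[keep]; key <- key[keep]
  }
  # preserve order of first appearance, not lexicographic residue order
  grp <- factor(key, levels = unique(key))
  as.numeric(tapply(plddt, grp, mean))
}
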