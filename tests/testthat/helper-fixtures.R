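# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from stored binary data.

write_json_fixture <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  path
}

# minimal mmCIF with the atom_site loop only; one row per atom
write_mmcif_fixture <- function(path, res_ids, b_factors,
                                atom_names = NULL, chain = "A") {
  stopifnot(length(res_ids) == length(b_factors))
  if (is.null(atom_names)) atom_names <- rep("CA", length(res_ids))
  hdr <- c("data_testmodel", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "label_asym_id", "label_seq_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy", "B_iso_or_equiv")))
  rows <- sprintf("ATOM %d C %s ALA %s %d 0.0 0.0 0.0 1.00 %s",
                  seq_along(res_ids), atom_names, chain, res_ids,
                  formatC(b_factors, digits = 10, format = "g"))
  writeLines(c(hdr, rows, "#"), path)
  path
}

make_hits <- function(query, evalue, bits, lddt = NULL, alntmscore = NULL,
                      target = NULL) {
  k <- length(evalue)
  data.frame(query = query,
             target = if (is.null(target)) sprintf("t%02d", seq_len(k))
               else target,
             fident = 0.3, alnlen = 100L, mismatch = 50L, gapopen = 1L,
             qstart = 1L, qend = 100L, tstart = 1L, tend = 100L,
             evalue = evalue, bits = bits,
             lddt = if (is.null(lddt)) 0.8 else lddt,
             alntmscore = if (is.null(alntmscore)) 0.7 else alntmscore,
             stringsAsFactors = FALSE)
}

make_matches <- function(protein_id, start, end, ipr = NULL) {
  k <- length(start)
  data.frame(protein_id = protein_id,
             signature_accession = sprintf("PF%05d", seq_len(k)),
             ipr_accession = if (is.null(ipr))
               sprintf("IPR%06d", seq_len(k)) else ipr,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# a deterministic tiny score table + pairs for pair-scoring tests
make_pair_fixture <- function(n_pairs = 6, seed = 99) {
  cfg <- synthetic_config(n_pairs = n_pairs, seed = seed)
  ds <- generate_pairs(cfg)
  list(ds = ds, scores = synthetic_score_table(ds),
       pairs = ds$metadata)
}

# simple Needleman-Wunsch score with linear gap penalty (oracle)
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- S[i, j] + if (a[i] == b[j]) match else mismatch
    S[i + 1, j + 1] <- max(sub, S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  S[n + 1, m + 1]
}

random_aa <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), n,
               replace = TRUE), collapse = "")
}

# random pair confidences guaranteed to contain both classes
random_confidences <- function(n, allow_ties = TRUE) {
  repeat {
    conf <- sample(c(-1, 1), n, replace = TRUE) *
      sample(seq_len(max(3L, n %/% 2)), n, replace = TRUE) / 7
    if (allow_ties && n > 4) conf[sample(n, max(1, n %/% 10))] <- 0
    nz <- conf[conf != 0]
    if (any(nz > 0) && any(nz < 0)) return(data.frame(confidence = conf))
  }
}
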