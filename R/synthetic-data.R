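#' Configuration of the synthetic gene-model pair generator
#'
#' Defines the study conditions the generator emulates: multi-domain
#' proteins with 20-50% intrinsically disordered content, per-residue
#' confidence emissions for ordered and disordered residues, and the
#' annotation error modes observed in curated gene model comparisons -
#' translated-intron insertion (with depressed confidence in the
#' flanking residues, the "magnifying effect"), domain truncation,
#' spurious terminal extension, and frameshifted tails. Structure-search
#' and domain scores are emitted mechanistically from the resulting
#' residue layout (bitscore proportional to intact ordered length,
#' InterPro domains covering intact ordered runs and missing entirely
#' from about a third of models), so the generator exercises the
#' parsers and metric code, not just the score arithmetic.
#'
#' @param n_pairs Number of gene pairs to generate.
#' @param seed Integer seed; each pair draws from a substream derived
#'   from `(seed, pair index)`.
#' @param domain_count_range,domain_length_range Integer ranges for the
#'   number of ordered domains and their lengths (residues).
#' @param disorder_fraction_range Range of the disordered fraction of
#'   each protein.
#' @param mu_ordered,sd_ordered,mu_disordered,sd_disordered Gaussian
#'   pLDDT emission parameters for ordered / disordered residues.
#' @param error_probability Probability that the old model of a pair
#'   carries one annotation error (the effect size of the dataset).
#' @param error_modes Named non-negative weights over the error modes
#'   `intron_insertion`, `truncation`, `terminal_extension`,
#'   `frameshift_tail`.
#' @param flank_depression_width,flank_depression_depth Width (residues)
#'   and depth (pLDDT units) of the confidence depression flanking a
#'   translated-intron insertion.
#' @param insert_length_range Length range (residues) of insertions,
#'   truncations, extensions and rewritten tails.
#' @param ipr_missing_probability Probability that a model has no
#'   InterPro match at all.
#' @param foldseek_nonsig_probability Baseline probability of a
#'   non-significant top structure hit (raised by 0.2 for corrupted
#'   models).
#' @param noise_sd Gaussian noise (bits) on the emitted bitscore.
#' @param track_jitter_sd Gaussian run-to-run variability (pLDDT units)
#'   added to the old model's track: independent predictions of nearly
#'   identical sequences give correlated but not identical per-residue
#'   confidences.
#' @param region_wobble_sd Regional confidence variability (pLDDT
#'   units): alignment-depth differences between the two predictions
#'   shift the confidence of whole segments (helices, termini), so the
#'   old track additionally receives a per-block offset drawn for each
#'   `region_block_len`-residue block. This is what makes
#'   wrong-direction changes of tens of high-confidence residues occur
#'   by chance, as observed in real old/new comparisons.
#' @param region_block_len Block length (residues) of the regional
#'   wobble.
#' @param ipr_boundary_jitter_sd Gaussian jitter (residues) on InterPro
#'   domain start/end coordinates, emulating alignment shifts of the
#'   statistical domain models between slightly different sequences.
#' @param ipr_dropout_probability Per-domain, per-model probability that
#'   an otherwise intact domain match is missed (profile score falling
#'   below the reporting threshold), so whole-domain gains and losses
#'   occur by chance even between equivalent models.
#' @param bitscore_per_residue Bitscore per intact ordered residue.
#' @param emit_pae Emit small synthetic PAE matrices (intended for
#'   small test proteins; off by default).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 100, seed = 1,
                             domain_count_range = c(1, 3),
                             domain_length_range = c(80, 300),
                             disorder_fraction_range = c(0.2, 0.5),
                             mu_ordered = 88, sd_ordered = 5,
                             mu_disordered = 40, sd_disordered = 8,
                             error_probability = 0.8,
                             error_modes = c(intron_insertion = 0.4,
                                             truncation = 0.25,
                                             terminal_extension = 0.2,
                                             frameshift_tail = 0.15),
                             flank_depression_width = 15,
                             flank_depression_depth = 10,
                             insert_length_range = c(20, 120),
                             ipr_missing_probability = 1 / 3,
                             foldseek_nonsig_probability = 0.1,
                             noise_sd = 10,
                             track_jitter_sd = 2,
                             region_wobble_sd = 3,
                             region_block_len = 40,
                             ipr_boundary_jitter_sd = 5,
                             ipr_dropout_probability = 0.01,
                             bitscore_per_residue = 0.5,
                             emit_pae = FALSE) {
  cfg <- as.list(environment())
  probs <- c(cfg$error_probability, cfg$ipr_missing_probability,
             cfg$foldseek_nonsig_probability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (r in list(cfg$domain_count_range, cfg$domain_length_range,
                 cfg$disorder_fraction_range, cfg$insert_length_range))
    if (length(r) != 2L || r[1] > r[2]) stop("ranges must be ordered pairs")
  if (any(c(mu_ordered, mu_disordered) < 0 |
          c(mu_ordered, mu_disordered) > 100))
    stop("emission means must lie in [0, 100]")
  if (is.null(names(error_modes)) || any(error_modes < 0) ||
      sum(error_modes) <= 0)
    stop("error_modes must be named non-negative weights")
  structure(cfg, class = "synthetic_config")
}

pair_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 65521 * 31627 + index * 9973) %%
               2147483629)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

rint <- function(range) if (range[1] == range[2]) range[1] else
  sample(seq(range[1], range[2]), 1L)

# Emit Foldseek hit rows for one model from its residue layout.
# Whether the fold is represented in the PDB at all is a property of the
# gene, so the baseline non-significance coin (`base_nonsig`) is drawn
# once per pair; corruption adds a model-level chance of losing the hit.
synth_foldseek <- function(config, model_id, labels, damaged, corrupted,
                           base_nonsig) {
  intact <- sum(labels > 0 & !damaged)
  ordered <- max(1L, sum(labels > 0))
  bits <- max(0, config$bitscore_per_residue * intact +
                stats::rnorm(1, 0, config$noise_sd))
  nonsig <- base_nonsig || (corrupted && stats::runif(1) < 0.2)
  if (nonsig) {
    evalue <- stats::runif(1, 0.05, 5)
    bits <- stats::runif(1, 5, 30)
    lddt <- stats::runif(1, 0.2, 0.5)
    alntm <- stats::runif(1, 0.1, 0.4)
  } else {
    evalue <- 10^(-pmax(2, bits / 10))
    lddt <- clamp(0.5 + 0.45 * intact / ordered +
                    stats::rnorm(1, 0, 0.03), 0, 1)
    alntm <- clamp(0.45 + 0.45 * intact / ordered +
                     stats::rnorm(1, 0, 0.05), 0, 1)
  }
  n_decoy <- sample(0:2, 1L)
  ev <- c(evalue, evalue * 10^stats::runif(n_decoy, 1, 4))
  bt <- c(bits, pmax(2, bits * stats::runif(n_decoy, 0.2, 0.8)))
  ld <- c(lddt, clamp(lddt * stats::runif(n_decoy, 0.4, 0.9), 0, 1))
  tm <- c(alntm, clamp(alntm * stats::runif(n_decoy, 0.4, 0.9), 0, 1))
  k <- length(ev)
  alnlen <- pmax(30L, as.integer(round(intact * stats::runif(k, 0.6, 1))))
  data.frame(query = model_id,
             target = sprintf("%s_pdb%02d", model_id, seq_len(k)),
             fident = round(stats::runif(k, 0.1, 0.6), 3),
             alnlen = alnlen,
             mismatch = as.integer(round(alnlen * stats::runif(k, 0.3, 0.7))),
             gapopen = sample(0:5, k, replace = TRUE),
             qstart = 1L, qend = alnlen, tstart = 1L, tend = alnlen,
             evalue = ev, bits = bt, lddt = ld, alntmscore = tm,
             stringsAsFactors = FALSE)
}

# InterPro matches cover maximal intact ordered runs of >= 30 residues.
# Whether a protein family has an integrated InterPro entry is a
# property of the gene, so the missingness coin (`ipr_missing`) is drawn
# once per pair and applied to both annotation versions.
synth_ipr <- function(config, model_id, labels, damaged, ipr_missing) {
  empty <- data.frame(protein_id = character(0),
                      signature_accession = character(0),
                      ipr_accession = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (ipr_missing) return(empty)
  intact <- labels > 0 & !damaged
  r <- rle(intact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 30L
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  if (config$ipr_dropout_probability > 0) {
    hit <- stats::runif(length(starts)) >= config$ipr_dropout_probability
    starts <- starts[hit]; ends <- ends[hit]
    if (!length(starts)) return(empty)
  }
  k <- length(starts)
  if (config$ipr_boundary_jitter_sd > 0) {
    n <- length(labels)
    starts <- pmax(1L, pmin(n, as.integer(round(
      starts + stats::rnorm(k, 0, config$ipr_boundary_jitter_sd)))))
    ends <- pmax(starts, pmin(n, as.integer(round(
      ends + stats::rnorm(k, 0, config$ipr_boundary_jitter_sd)))))
  }
  out <- data.frame(protein_id = model_id,
                    signature_accession = sprintf("PF%05d", sample(
                      10000:99999, k, replace = TRUE)),
                    ipr_accession = sprintf("IPR%06d", sample(
                      100000:999999, k, replace = TRUE)),
                    start = starts, end = ends, stringsAsFactors = FALSE)
  if (stats::runif(1) < 0.2) {
    # an un-integrated signature match, as real InterProScan output has
    w <- sample(k, 1L)
    out <- rbind(out, data.frame(
      protein_id = model_id,
      signature_accession = sprintf("G3DSA:%d.%d.%d.%d",
                                    sample(1:3, 1), sample(10:99, 1),
                                    sample(10:99, 1), sample(10:99, 1)),
      ipr_accession = NA_character_,
      start = out$start[w], end = out$end[w], stringsAsFactors = FALSE))
  }
  out
}

synth_ptm <- function(config, labels, damaged) {
  intact_frac <- sum(labels > 0 & !damaged) / length(labels)
  damage_frac <- sum(damaged) / length(labels)
  clamp(0.85 * intact_frac - 0.1 * damage_frac + stats::rnorm(1, 0, 0.02),
        0.01, 0.99)
}

synth_pae <- function(disorder) {
  n <- length(disorder)
  m <- outer(disorder, disorder, function(a, b) 3 + 12 * (a + b) / 2)
  m <- m + matrix(stats::runif(n * n, 0, 0.5), n, n)
  diag(m) <- 0.5
  m
}

synth_disorder <- function(config, labels) {
  d <- numeric(length(labels))
  d[labels > 0] <- clamp(stats::rnorm(sum(labels > 0), 0.12, 0.06), 0, 1)
  d[labels == 0] <- clamp(stats::rnorm(sum(labels == 0), 0.8, 0.1), 0, 1)
  d
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# independent per-run confidence variability: per-residue jitter plus a
# regional (per-block) offset emulating alignment-depth differences
run_variability <- function(track, config) {
  n <- length(track)
  if (config$track_jitter_sd > 0)
    track <- track + stats::rnorm(n, 0, config$track_jitter_sd)
  if (config$region_wobble_sd > 0) {
    blocks <- ceiling(seq_len(n) / config$region_block_len)
    track <- track + stats::rnorm(max(blocks),
                                  0, config$region_wobble_sd)[blocks]
  }
  clamp(track, 0, 100)
}

finish_bundle <- function(config, model_id, track, labels, damaged,
                          sequence, corrupted, base_nonsig, ipr_missing) {
  # emitted at the precision the predictors print (2 decimals for
  # pLDDT), so written files round-trip the in-memory values exactly
  track <- round(track, 2)
  disorder <- round(synth_disorder(config, labels), 4)
  ptm <- round(synth_ptm(config, labels, damaged), 3)
  pae <- if (config$emit_pae) round(synth_pae(disorder), 2) else NULL
  list(model_id = model_id,
       prediction = structure_prediction(model_id, track, pae = pae,
                                         ptm = ptm,
                                         source_tool = "synthetic"),
       hits = synth_foldseek(config, model_id, labels, damaged, corrupted,
                             base_nonsig),
       ipr = synth_ipr(config, model_id, labels, damaged, ipr_missing),
       disorder = disorder, sequence = sequence,
       labels = labels, damaged = damaged)
}

#' Generate one synthetic old/new gene-model pair
#'
#' Builds the new (curated) model as ordered domains with disordered
#' linkers and termini, then derives the old (pre-curation) model by
#' applying at most one error mode with probability `error_probability`.
#' Emits both models' confidence tracks, pTM, Foldseek hits, InterPro
#' matches, disorder tracks and sequences, plus a ground-truth record.
#'
#' @param config A [synthetic_config()].
#' @param gene_index 1-based index of the pair; determines the RNG
#'   substream together with `config$seed`.
#' @return List with elements `old` and `new` (model bundles: model_id,
#'   prediction, hits, ipr, disorder, sequence) and `truth` (one-row
#'   data frame: gene_id, applied_mode, affected_start, affected_end,
#'   true_winner).
#' @export
generate_pair <- function(config, gene_index) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(pair_seed(config$seed, gene_index))
  gene_id <- sprintf("g%05d", gene_index)

  # --- new (curated) model ----------------------------------------------
  n_dom <- rint(config$domain_count_range)
  dom_len <- vapply(seq_len(n_dom), function(i)
    rint(config$domain_length_range), numeric(1))
  ordered <- sum(dom_len)
  frac <- stats::runif(1, config$disorder_fraction_range[1],
                       config$disorder_fraction_range[2])
  dis_total <- round(ordered * frac / (1 - frac))
  gaps <- as.vector(stats::rmultinom(1, dis_total, rep(1, n_dom + 1L)))
  labels <- integer(0)
  for (i in seq_len(n_dom))
    labels <- c(labels, rep(0L, gaps[i]), rep(i, dom_len[i]))
  labels <- c(labels, rep(0L, gaps[n_dom + 1L]))
  n <- length(labels)
  emit_track <- function(lab) {
    tr <- numeric(length(lab))
    tr[lab > 0] <- stats::rnorm(sum(lab > 0), config$mu_ordered,
                                config$sd_ordered)
    tr[lab == 0] <- stats::rnorm(sum(lab == 0), config$mu_disordered,
                                 config$sd_disordered)
    clamp(tr, 0, 100)
  }
  new_track <- emit_track(labels)
  new_seq <- paste(sample(AA20, n, replace = TRUE), collapse = "")
  new_damaged <- rep(FALSE, n)

  # --- old model: corrupt with one error mode ---------------------------
  mode <- NA_character_
  if (stats::runif(1) < config$error_probability)
    mode <- sample(names(config$error_modes), 1L,
                   prob = config$error_modes)
  old_track <- new_track; old_labels <- labels
  old_damaged <- new_damaged; old_seq <- new_seq
  aff <- c(NA_integer_, NA_integer_)
  fw <- config$flank_depression_width
  ilr <- config$insert_length_range

  if (!is.na(mode)) {
    dom_start <- vapply(seq_len(n_dom), function(i)
      which(labels == i)[1L], integer(1))
    dom_end <- dom_start + dom_len - 1L
    if (mode == "intron_insertion") {
      ok <- dom_len >= 2 * fw + 10
      if (!any(ok)) stop("no domain can host an intron insertion; ",
                         "domain_length_range too small for the flank width")
      d <- if (sum(ok) == 1L) which(ok) else sample(which(ok), 1L)
      p <- sample(seq(dom_start[d] + fw, dom_end[d] - fw), 1L)
      L <- rint(ilr)
      ins_track <- clamp(stats::rnorm(L, config$mu_disordered,
                                      config$sd_disordered), 0, 100)
      old_track <- c(new_track[1:p], ins_track, new_track[(p + 1L):n])
      old_labels <- c(labels[1:p], rep(0L, L), labels[(p + 1L):n])
      old_damaged <- c(new_damaged[1:p], rep(FALSE, L),
                       new_damaged[(p + 1L):n])
      flanks <- c(seq(p - fw + 1L, p), seq(p + L + 1L, p + L + fw))
      old_track[flanks] <- clamp(old_track[flanks] -
                                   config$flank_depression_depth, 0, 100)
      old_damaged[flanks] <- TRUE
      ins_seq <- paste(sample(AA20, L, replace = TRUE), collapse = "")
      old_seq <- paste0(substr(new_seq, 1, p), ins_seq,
                        substr(new_seq, p + 1L, n))
      aff <- c(p + 1L, p + L)
    } else if (mode == "truncation") {
      d <- if (n_dom == 1L) 1L else sample(n_dom, 1L)
      L <- min(rint(ilr), dom_len[d] - 20L)
      L <- max(L, 10L)
      rm_idx <- seq(dom_end[d] - L + 1L, dom_end[d])
      old_track <- new_track[-rm_idx]
      old_labels <- labels[-rm_idx]
      old_damaged <- new_damaged[-rm_idx]
      old_seq <- paste0(substr(new_seq, 1, rm_idx[1L] - 1L),
                        substr(new_seq, rm_idx[length(rm_idx)] + 1L, n))
      aff <- c(rm_idx[1L] - 1L, rm_idx[1L] - 1L)  # junction, old coords
      attr(mode, "removed") <- L
    } else if (mode == "terminal_extension") {
      # the spurious terminus also depresses confidence of the adjacent
      # genuine residues (flanking-sequence effect on the alignment)
      L <- rint(ilr)
      ext_track <- clamp(stats::rnorm(L, config$mu_disordered,
                                      config$sd_disordered), 0, 100)
      ext_seq <- paste(sample(AA20, L, replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5) {
        old_track <- c(ext_track, new_track)
        old_labels <- c(rep(0L, L), labels)
        old_damaged <- c(rep(FALSE, L), new_damaged)
        old_seq <- paste0(ext_seq, new_seq)
        flanks <- seq(L + 1L, min(L + fw, L + n))
        aff <- c(1L, L)
      } else {
        old_track <- c(new_track, ext_track)
        old_labels <- c(labels, rep(0L, L))
        old_damaged <- c(new_damaged, rep(FALSE, L))
        old_seq <- paste0(new_seq, ext_seq)
        flanks <- seq(max(1L, n - fw + 1L), n)
        aff <- c(n + 1L, n + L)
      }
      old_track[flanks] <- clamp(old_track[flanks] -
                                   config$flank_depression_depth, 0, 100)
      old_damaged[flanks] <- TRUE
    } else if (mode == "frameshift_tail") {
      L <- min(rint(ilr), n - 10L)
      idx <- seq(n - L + 1L, n)
      old_track[idx] <- clamp(stats::rnorm(L, config$mu_disordered,
                                           config$sd_disordered), 0, 100)
      old_damaged[idx] <- TRUE
      old_seq <- paste0(substr(new_seq, 1, n - L),
                        paste(sample(AA20, L, replace = TRUE),
                              collapse = ""))
      aff <- c(n - L + 1L, n)
    }
  }

  # each model is an independent prediction run: both tracks receive
  # their own run-to-run variability on top of the shared base emission
  new_track <- run_variability(new_track, config)
  old_track <- run_variability(old_track, config)

  # gene-level properties shared by both annotation versions
  ipr_missing <- stats::runif(1) < config$ipr_missing_probability
  base_nonsig <- stats::runif(1) < config$foldseek_nonsig_probability
  new_bundle <- finish_bundle(config, paste0(gene_id, "_new"), new_track,
                              labels, new_damaged, new_seq,
                              corrupted = FALSE, base_nonsig, ipr_missing)
  old_bundle <- finish_bundle(config, paste0(gene_id, "_old"), old_track,
                              old_labels, old_damaged, old_seq,
                              corrupted = !is.na(mode),
                              base_nonsig, ipr_missing)
  truth <- data.frame(gene_id = gene_id,
                      applied_mode = if (is.na(mode)) "none" else
                        as.character(mode),
                      affected_start = aff[1L], affected_end = aff[2L],
                      true_winner = if (is.na(mode)) "tie" else "new",
                      stringsAsFactors = FALSE)
  list(old = old_bundle, new = new_bundle, truth = truth)
}

#' Generate a full in-memory synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return List with `pairs` (list of [generate_pair()] results),
#'   `truth` (data frame) and `metadata` (pair metadata data frame in
#'   the layout [read_pair_metadata()] validates).
#' @export
generate_pairs <- function(config) {
  pairs <- lapply(seq_len(config$n_pairs), function(i)
    generate_pair(config, i))
  truth <- do.call(rbind, lapply(pairs, `[[`, "truth"))
  metadata <- data.frame(
    gene_id = truth$gene_id,
    old_model_id = paste0(truth$gene_id, "_old"),
    new_model_id = paste0(truth$gene_id, "_new"),
    change_class = "changed", species_tag = "synthetic",
    stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth, metadata = metadata)
}

#' Per-model score table of an in-memory synthetic dataset
#'
#' Runs [build_score_vector()] on every model bundle of the dataset.
#'
#' @param dataset Result of [generate_pairs()].
#' @param ... Passed on to [build_score_vector()].
#' @return Data frame, one row per model (2 per pair).
#' @export
synthetic_score_table <- function(dataset, ...) {
  bundles <- unlist(lapply(dataset$pairs, function(p) list(p$old, p$new)),
                    recursive = FALSE)
  score_table(lapply(bundles, function(b)
    build_score_vector(b$prediction, hits = b$hits, matches = b$ipr,
                       disorder = b$disorder, ...)))
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the package's readers consume: per-model
#' confidence and summary JSONs, one Foldseek TSV, one InterProScan
#' TSV, old/new protein FASTA files, the pair metadata CSV, a
#' per-residue disorder TSV, and the ground-truth CSV. Output is
#' byte-identical across runs with the same config (seeded substreams
#' per pair).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory dataset that was written.
#' @export
generate_dataset <- function(config, out_dir) {
  ds <- generate_pairs(config)
  conf_dir <- file.path(out_dir, "confidences")
  dir.create(conf_dir, recursive = TRUE, showWarnings = FALSE)
  bundles <- unlist(lapply(ds$pairs, function(p) list(p$old, p$new)),
                    recursive = FALSE)
  for (b in bundles) {
    conf <- list(model_id = b$model_id, plddt = b$prediction$plddt)
    if (!is.null(b$prediction$pae)) conf$pae <- b$prediction$pae
    jsonlite::write_json(conf,
                         file.path(conf_dir,
                                   paste0(b$model_id, "_confidences.json")),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(model_id = b$model_id, ptm = b$prediction$ptm),
                         file.path(conf_dir,
                                   paste0(b$model_id, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  fs <- do.call(rbind, lapply(bundles, `[[`, "hits"))
  utils::write.table(fs, file.path(out_dir, "foldseek.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ipr <- do.call(rbind, lapply(bundles, `[[`, "ipr"))
  ipr_rows <- sprintf("%s\tsynthmd5\t0\tPfam\t%s\tdomain\t%d\t%d\t1.0E-10\tT\t2026-01-01\t%s\tdomain",
                      ipr$protein_id, ipr$signature_accession,
                      ipr$start, ipr$end,
                      ifelse(is.na(ipr$ipr_accession), "-",
                             ipr$ipr_accession))
  writeLines(ipr_rows, file.path(out_dir, "interproscan.tsv"))
  old_seqs <- Biostrings::AAStringSet(vapply(ds$pairs, function(p)
    p$old$sequence, ""))
  names(old_seqs) <- vapply(ds$pairs, function(p) p$old$model_id, "")
  new_seqs <- Biostrings::AAStringSet(vapply(ds$pairs, function(p)
    p$new$sequence, ""))
  names(new_seqs) <- vapply(ds$pairs, function(p) p$new$model_id, "")
  Biostrings::writeXStringSet(old_seqs,
                              file.path(out_dir, "proteins_old.faa"))
  Biostrings::writeXStringSet(new_seqs,
                              file.path(out_dir, "proteins_new.faa"))
  utils::write.csv(ds$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  dis <- do.call(rbind, lapply(bundles, function(b)
    data.frame(model_id = b$model_id,
               residue = seq_along(b$disorder),
               disorder = formatC(b$disorder, digits = 17, format = "g"),
               stringsAsFactors = FALSE)))
  utils::write.table(dis, file.path(out_dir, "disorder.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(ds)
}
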