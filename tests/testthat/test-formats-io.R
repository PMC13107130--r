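test_that("confidence JSON reader handles per-atom and per-residue layouts", {
  d <- withr::local_tempdir()
  # per-atom list [(res1,80),(res1,90),(res2,70)] -> mean per residue
  p1 <- write_json_fixture(
    list(model_id = "m1", atom_plddts = c(80, 90, 70),
         atom_res_ids = c(1, 1, 2),
         atom_names = c("N", "CA", "CA")),
    file.path(d, "m1_confidences.json"))
  pred <- read_af3_confidences(p1)
  expect_equal(pred$plddt, c(85, 70))
  expect_true(is.na(pred$ptm))
  # CA-only reduction picks the CA atom
  expect_equal(read_af3_confidences(p1, atom_reduce = "ca")$plddt, c(90, 70))

  # per-residue passthrough plus pTM from the summary file
  p2 <- write_json_fixture(list(model_id = "m2", plddt = c(55.5, 60.1)),
                           file.path(d, "m2_confidences.json"))
  s2 <- write_json_fixture(list(model_id = "m2", ptm = 0.83),
                           file.path(d, "m2_summary.json"))
  pred2 <- read_af3_confidences(p2, s2)
  expect_equal(pred2$plddt, c(55.5, 60.1))
  expect_equal(pred2$ptm, 0.83)
  expect_true(is.na(read_af3_confidences(p2)$ptm))

  # PAE matrix is picked up and validated
  p3 <- write_json_fixture(
    list(model_id = "m3", plddt = c(80, 70),
         pae = matrix(c(0, 4, 2, 0), 2, 2)),
    file.path(d, "m3_confidences.json"))
  expect_equal(dim(read_af3_confidences(p3)$pae), c(2L, 2L))
})

test_that("confidence JSON reader rejects malformed or invalid input", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.json")
  writeLines("{not json", bad)
  expect_error(read_af3_confidences(bad), "malformed")
  p <- write_json_fixture(list(model_id = "m", plddt = c(50, 120)),
                          file.path(d, "range.json"))
  expect_error(read_af3_confidences(p), "\\[0, 100\\]")
  p2 <- write_json_fixture(
    list(model_id = "m", plddt = c(50, 60),
         pae = matrix(0, 2, 3)), file.path(d, "pae.json"))
  expect_error(read_af3_confidences(p2), "square")
  p3 <- write_json_fixture(list(model_id = "m", foo = 1),
                           file.path(d, "empty.json"))
  expect_error(read_af3_confidences(p3), "neither")
})

test_that("mmCIF reader extracts per-residue pLDDT from B-factors", {
  d <- withr::local_tempdir()
  f1 <- write_mmcif_fixture(file.path(d, "a.cif"), c(1, 2), c(90, 40))
  expect_equal(read_plddt_from_mmcif(f1)$plddt, c(90, 40))
  # two atoms per residue -> mean
  f2 <- write_mmcif_fixture(file.path(d, "b.cif"), c(1, 1, 2, 2),
                            c(80, 90, 30, 50),
                            atom_names = c("N", "CA", "N", "CA"))
  expect_equal(read_plddt_from_mmcif(f2)$plddt, c(85, 40))
  expect_equal(read_plddt_from_mmcif(f2, atom_reduce = "ca")$plddt,
               c(90, 50))
  f3 <- file.path(d, "no_atoms.cif")
  writeLines(c("data_x", "_cell.length_a 1.0"), f3)
  expect_error(read_plddt_from_mmcif(f3), "atom_site")
})

test_that("JSON and mmCIF carriers of the same model agree", {
  d <- withr::local_tempdir()
  set.seed(31)
  track <- round(runif(40, 20, 99), 4)
  res_ids <- rep(seq_along(track), each = 2)
  atoms <- rep(c("N", "CA"), length(track))
  b <- track[res_ids]  # both atoms carry the residue value
  pj <- write_json_fixture(
    list(model_id = "x", atom_plddts = b, atom_res_ids = res_ids,
         atom_names = atoms),
    file.path(d, "x_confidences.json"))
  pc <- write_mmcif_fixture(file.path(d, "x.cif"), res_ids, b,
                            atom_names = atoms)
  expect_equal(read_af3_confidences(pj)$plddt,
               read_plddt_from_mmcif(pc)$plddt, tolerance = 1e-6)
})

test_that("Foldseek TSV parsing is strict about layout", {
  d <- withr::local_tempdir()
  f <- file.path(d, "fs.tsv")
  row <- paste("q1", "t1", "0.5", "120", "50", "2", "1", "120", "5", "124",
               "1e-10", "250", "0.9", "0.85", sep = "\t")
  writeLines(row, f)
  hits <- read_foldseek_tsv(f)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$evalue, 1e-10)
  expect_equal(hits$bits, 250)
  expect_equal(hits$lddt, 0.9)
  expect_equal(hits$alntmscore, 0.85)
  # empty file -> empty typed frame
  f0 <- file.path(d, "empty.tsv"); writeLines(character(0), f0)
  expect_equal(nrow(read_foldseek_tsv(f0)), 0L)
  # arity mismatch names the row
  writeLines(c(row, "q2\tt2\t0.1"), f)
  expect_error(read_foldseek_tsv(f), "row 2")
})

test_that("InterProScan TSV parsing handles integrated and orphan rows", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ipr.tsv")
  writeLines(c(
    paste("p1", "md5", "200", "Pfam", "PF00001", "desc", "10", "49",
          "1e-20", "T", "2026-01-01", "IPR000123", "domain", sep = "\t"),
    paste("p1", "md5", "200", "Gene3D", "G3DSA:1.1.1.1", "desc", "5", "60",
          "1e-5", "T", "2026-01-01", "-", "-", sep = "\t")), f)
  m <- read_interproscan_tsv(f)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start[1], 10L)
  expect_equal(m$end[1], 49L)
  expect_equal(m$end[1] - m$start[1] + 1L, 40L)
  expect_true(is.na(m$ipr_accession[2]))
  writeLines("p1\tmd5\t200\tPfam\tPF1\tdesc\tten\t49", f)
  expect_error(read_interproscan_tsv(f), "non-integer")
})

test_that("pair metadata is validated against the change-class vocabulary", {
  d <- withr::local_tempdir()
  f <- file.path(d, "meta.csv")
  writeLines(c("gene_id,old_model_id,new_model_id,change_class,species_tag",
               "g1,g1_old,g1_new,changed,sp",
               "g2,g2_old,g2_new,split,sp"), f)
  tab <- read_pair_metadata(f)
  expect_equal(nrow(tab), 2L)
  writeLines(c("gene_id,old_model_id,new_model_id,change_class",
               "g1,a,b,changed", "g1,c,d,changed"), f)
  expect_error(read_pair_metadata(f), "duplicate gene_id")
  writeLines(c("gene_id,old_model_id,new_model_id,change_class",
               "g1,a,b,improved"), f)
  expect_error(read_pair_metadata(f), "improved")
  writeLines(c("gene_id,old_model_id,new_model_id,change_class",
               "g1,a,a,changed"), f)
  expect_error(read_pair_metadata(f), "identical")
})

test_that("scores tables round-trip through CSV to 1e-9", {
  d <- withr::local_tempdir()
  f <- file.path(d, "scores.csv")
  # single row with a missing value encoded as an empty cell
  df <- data.frame(model_id = "m1", median_plddt = 81.123456789,
                   ptm = NA_real_, n = 5L, stringsAsFactors = FALSE)
  write_scores_table(df, f)
  back <- read_scores_table(f)
  expect_equal(back$median_plddt, df$median_plddt, tolerance = 1e-12)
  expect_true(is.na(back$ptm))
  # empty collection -> header-only file
  write_scores_table(df[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_scores_table(f)), 0L)
  # 500-row random table
  set.seed(7)
  big <- data.frame(id = sprintf("m%03d", 1:500),
                    a = rnorm(500) * 1e3, b = runif(500),
                    c = sample(c(NA, 1:10), 500, replace = TRUE))
  write_scores_table(big, f)
  back <- read_scores_table(f)
  expect_equal(back$a, big$a, tolerance = 1e-9)
  expect_equal(back$b, big$b, tolerance = 1e-9)
  expect_identical(is.na(back$c), is.na(big$c))
})

test_that("generated dataset files round-trip against in-memory truth", {
  d <- withr::local_tempdir()
  cfg <- synthetic_config(n_pairs = 4, seed = 123)
  ds <- generate_dataset(cfg, d)
  bundles <- unlist(lapply(ds$pairs, function(p) list(p$old, p$new)),
                    recursive = FALSE)
  for (b in bundles) {
    pred <- read_af3_confidences(
      file.path(d, "confidences", paste0(b$model_id, "_confidences.json")),
      file.path(d, "confidences", paste0(b$model_id, "_summary.json")))
    # bit-exact track round trip
    expect_identical(pred$plddt, b$prediction$plddt)
    expect_equal(pred$ptm, b$prediction$ptm, tolerance = 1e-12)
  }
  fs <- read_foldseek_tsv(file.path(d, "foldseek.tsv"))
  expect_equal(nrow(fs), sum(vapply(bundles, function(b) nrow(b$hits), 0L)))
  ipr <- read_interproscan_tsv(file.path(d, "interproscan.tsv"))
  expect_equal(nrow(ipr), sum(vapply(bundles, function(b) nrow(b$ipr), 0L)))
  # per-protein IPR-integrated counts match the generator's truth
  for (b in bundles) {
    got <- ipr[ipr$protein_id == b$model_id, , drop = FALSE]
    expect_equal(sum(!is.na(got$ipr_accession)),
                 sum(!is.na(b$ipr$ipr_accession)))
  }
  meta <- read_pair_metadata(file.path(d, "metadata.csv"))
  expect_equal(meta$gene_id, ds$metadata$gene_id)
})
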