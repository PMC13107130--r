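test_that("delta vectors are elementwise new minus old with explicit absence", {
  new <- data.frame(model_id = "a_new", n_plddt_gt_80 = 288,
                    fs_bitscore = 120, ptm = NA_real_)
  old <- data.frame(model_id = "a_old", n_plddt_gt_80 = 299,
                    fs_bitscore = 100, ptm = 0.5)
  d <- delta_vector(new, old, metrics = c("n_plddt_gt_80", "fs_bitscore",
                                          "ptm"))
  expect_equal(d[["n_plddt_gt_80"]], -11)   # 288 - 299
  expect_equal(d[["fs_bitscore"]], 20)
  expect_true(is.na(d[["ptm"]]))            # absent, not zero
  # identical vectors -> all-zero deltas
  same <- new; same$model_id <- "a_old2"
  expect_true(all(delta_vector(new, same,
                               c("n_plddt_gt_80", "fs_bitscore")) == 0))
  expect_error(delta_vector(new, new, "ptm"), "same model_id")
  set.seed(21)
  for (rep in 1:10) {
    a <- as.data.frame(as.list(rnorm(5))); names(a) <- letters[1:5]
    b <- as.data.frame(as.list(rnorm(5))); names(b) <- letters[1:5]
    d <- delta_vector(a, b, letters[1:5])
    for (m in letters[1:5]) expect_equal(d[[m]], a[[m]] - b[[m]])
  }
})

test_that("sign scores respect per-metric direction conventions", {
  expect_equal(sign_score("n_plddt_gt_80", 12), 1)
  expect_equal(sign_score("mean_pae", 2.0), -1)   # decrease-good
  expect_equal(sign_score("mean_pae", -2.0), 1)
  expect_equal(sign_score("fs_evalue", -9.99), 1)
  expect_equal(sign_score("fs_bitscore", 0), 0)
  expect_equal(sign_score("ptm", NA), 0)
  expect_error(sign_score("unknown_metric", 1), "no direction")
  # antisymmetry for every declared metric
  set.seed(22)
  for (m in names(metric_directions())) {
    d <- rnorm(1)
    expect_equal(sign_score(m, d), -sign_score(m, -d))
  }
})

test_that("MaxAbs fitting and transform follow the definition", {
  df <- data.frame(x = c(-4, 2, 0))
  sc <- maxabs_fit(df)
  expect_equal(unname(sc$scale_factors), 4)
  expect_equal(maxabs_transform(sc, df)$x, c(-1, 0.5, 0))
  # degenerate all-zero metric keeps factor 1
  z <- maxabs_fit(data.frame(x = c(0, 0)))
  expect_equal(unname(z$scale_factors), 1)
  expect_equal(maxabs_transform(z, data.frame(x = c(0, 0)))$x, c(0, 0))
  expect_error(maxabs_fit(data.frame(x = numeric(0))), "empty")
  # scaled values stay in [-1, 1] and NAs propagate
  set.seed(23)
  df2 <- data.frame(a = c(rnorm(20), NA), b = runif(21, -5, 5))
  sc2 <- maxabs_fit(df2)
  out <- maxabs_transform(sc2, df2)
  expect_true(all(abs(out$a) <= 1, na.rm = TRUE))
  expect_true(is.na(out$a[21]))
})

test_that("MaxAbs scaling matches the scikit-learn reference to 1e-12", {
  set.seed(24)
  X <- matrix(rnorm(60, sd = 10), 20, 3)
  X[3, 2] <- 0
  d <- withr::local_tempdir()
  fin <- file.path(d, "in.csv"); fout <- file.path(d, "out.csv")
  utils::write.table(X, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- file.path(d, "maxabs.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.preprocessing import MaxAbsScaler",
    "X = np.loadtxt(sys.argv[1], delimiter=',')",
    "np.savetxt(sys.argv[2], MaxAbsScaler().fit_transform(X),",
    "           delimiter=',', fmt='%.17g')"), script)
  status <- system2("python", c(script, fin, fout), stdout = TRUE,
                    stderr = TRUE)
  expect_true(file.exists(fout))
  ref <- as.matrix(utils::read.csv(fout, header = FALSE))
  df <- as.data.frame(X); names(df) <- c("a", "b", "c")
  ours <- as.matrix(maxabs_transform(maxabs_fit(df), df))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("combined sums orient decrease-good metrics and report coverage", {
  scaled <- c(a = 0.5, b = -0.2, c = 0.1)
  dirs <- c(a = "increase", b = "increase", c = "increase")
  s <- combined_sum(scaled, c("a", "b", "c"), dirs)
  expect_equal(as.numeric(s), 0.4)
  expect_equal(attr(s, "coverage"), 3L)
  # decrease-good metric contributes with flipped sign
  s2 <- combined_sum(c(fs_evalue = -0.5, fs_bitscore = 0.2),
                     c("fs_evalue", "fs_bitscore"))
  expect_equal(as.numeric(s2), 0.7)
  # absences contribute zero and reduce coverage
  s3 <- combined_sum(c(a = NA_real_, b = NA_real_), c("a", "b"), dirs)
  expect_equal(as.numeric(s3), 0)
  expect_equal(attr(s3, "coverage"), 0L)
  expect_error(combined_sum(scaled, character(0)), "empty")
  set.seed(25)
  for (rep in 1:10) {
    v <- setNames(rnorm(6), letters[1:6])
    dd <- setNames(rep("increase", 6), letters[1:6])
    expect_equal(as.numeric(combined_sum(v, letters[1:6], dd)), sum(v))
  }
})

test_that("win/lose is a strict sign at zero", {
  expect_equal(win_lose(0.4), 1)
  expect_equal(win_lose(-1e-9), -1)
  expect_equal(win_lose(0), 0)
  expect_error(win_lose(NaN), "finite")
  expect_error(win_lose(Inf), "finite")
})

test_that("tallies conserve the collection size", {
  expect_equal(tally_outcomes(c(1, 1, -1)),
               c(up = 2L, same = 0L, down = 1L))
  expect_equal(tally_outcomes(rep(0, 7))[["same"]], 7L)
  set.seed(26)
  for (rep in 1:10) {
    s <- sample(c(-1, 0, 1), 50, replace = TRUE)
    expect_equal(sum(tally_outcomes(s)), 50L)
  }
})

test_that("pair scoring is scale-invariant and antisymmetric", {
  fx <- make_pair_fixture(n_pairs = 8, seed = 42)
  pd <- score_pairs(fx$scores, fx$pairs)
  expect_equal(nrow(pd), 8L)
  # win = sign(sum) everywhere
  for (ctx in names(default_contexts()))
    expect_equal(pd[[paste0("win_", ctx)]],
                 sign(pd[[paste0("sum_", ctx)]]))

  # positive rescaling of one metric leaves scaled deltas, signs and
  # win/lose calls unchanged
  sc2 <- fx$scores
  sc2$fs_bitscore <- sc2$fs_bitscore * 137.5
  pd2 <- score_pairs(sc2, fx$pairs)
  expect_equal(pd2$scaled_fs_bitscore, pd$scaled_fs_bitscore,
               tolerance = 1e-12)
  expect_equal(pd2$sign_fs_bitscore, pd$sign_fs_bitscore)
  expect_equal(pd2$win_af3_fs_ipr, pd$win_af3_fs_ipr)
  expect_equal(pd2$sum_af3_fs_ipr, pd$sum_af3_fs_ipr, tolerance = 1e-12)

  # swapping old and new negates deltas, signs and sums, and maps
  # wins onto losses
  swapped <- fx$pairs
  swapped$old_model_id <- fx$pairs$new_model_id
  swapped$new_model_id <- fx$pairs$old_model_id
  pd3 <- score_pairs(fx$scores, swapped)
  for (m in canonical_metrics()) {
    expect_equal(pd3[[paste0("delta_", m)]], -pd[[paste0("delta_", m)]])
    expect_equal(pd3[[paste0("sign_", m)]], -pd[[paste0("sign_", m)]])
  }
  expect_equal(pd3$sum_af3_fs_ipr, -pd$sum_af3_fs_ipr, tolerance = 1e-12)
  expect_equal(pd3$win_af3_fs_ipr, -pd$win_af3_fs_ipr)
})

test_that("tally table covers every metric and context", {
  fx <- make_pair_fixture(n_pairs = 5, seed = 43)
  pd <- score_pairs(fx$scores, fx$pairs)
  tt <- tally_table(pd)
  expect_setequal(tt$name[tt$kind == "context"], names(default_contexts()))
  expect_true(all(tt$up + tt$same + tt$down == 5L))
})
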