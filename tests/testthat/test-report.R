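test_that("keyword filtering is case-insensitive substring matching", {
  ann <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    description = c("DNA polymerase III", "membrane transporter",
                    "Transcription_factor domain protein",
                    "putative rna-binding protein", "ATPase"),
    stringsAsFactors = FALSE)
  hits <- keyword_filter(ann)
  expect_setequal(hits, c("a", "c", "d"))
  expect_length(keyword_filter(ann, keywords = "zinc finger"), 0)
})

test_that("recovery summary reproduces the published worked example", {
  # 474 targets; 352 with a unanimous helix, 65 more at 0.875, 37 more at
  # 0.75, 20 below threshold
  ids <- sprintf("t%03d", 1:474)
  idx <- c(rep(1, 352), rep(0.875, 65), rep(0.75, 37), rep(0.5, 20))
  rows <- data.frame(protein_id = ids, nabh_index = idx,
                     stringsAsFactors = FALSE)
  rec <- recovery_summary(rows, targets = ids, set_name = "dsRBP")
  expect_equal(rec$count_1, 352)
  expect_equal(round(rec$rate_1, 3), 0.743)
  expect_equal(rec$count_0.875, 417)
  expect_equal(rec$count_0.75, 454)
  expect_equal(rec$rate_0.75, 454 / 474)
  expect_equal(rec$with_helix, 474)
  expect_error(recovery_summary(rows, targets = character(0)), "empty")
})

test_that("recovery counts are non-increasing in the cutoff on random tables", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    rows <- data.frame(
      protein_id = sample(sprintf("p%02d", 1:15), n, replace = TRUE),
      nabh_index = sample((0:8) / 8, n, replace = TRUE),
      stringsAsFactors = FALSE)
    targets <- sprintf("p%02d", 1:15)
    rec <- recovery_summary(rows, targets)
    expect_true(rec$count_1 <= rec$count_0.875)
    expect_true(rec$count_0.875 <= rec$count_0.75)
    expect_true(all(c(rec$rate_1, rec$rate_0.875, rec$rate_0.75) >= 0))
    expect_true(all(c(rec$rate_1, rec$rate_0.875, rec$rate_0.75) <= 1))
    # all-unanimous table gives rate 1 everywhere
  }
  rows1 <- data.frame(protein_id = c("p1", "p2"), nabh_index = c(1, 1))
  rec1 <- recovery_summary(rows1, targets = c("p1", "p2"))
  expect_equal(c(rec1$rate_1, rec1$rate_0.875, rec1$rate_0.75), c(1, 1, 1))
})

test_that("the pipeline scores every extracted helix and is reproducible", {
  fx <- tiny_ensemble()
  toy <- generate_toy_proteome(n_nabp = 3, n_other = 5, seed = 8,
                               min_length = 60, max_length = 90)
  rows <- run_pipeline(toy$records, fx$ensemble)
  segs <- scan_proteins(toy$records)
  expect_equal(nrow(rows), nrow(segs))  # conservation: one row per helix
  expect_equal(rows$start1, rows$start0 + 1L)
  expect_equal(rows$nabh_index,
               rowMeans(as.matrix(rows[, paste0("m", 1:8)])))
  expect_true(all(rows$displayed == as.integer(rows$nabh_index >= 0.75 - 1e-9)))
  # planted proteins surface with a confident helix
  planted <- rows[rows$protein_id %in% toy$nabp_ids, ]
  expect_true(all(toy$nabp_ids %in% planted$protein_id))
  expect_true(any(planted$tier %in% c("strong", "likely")))
  # a protein with no qualifying window yields zero rows
  inert <- data.frame(id = "flat", description = "",
                      sequence = strrep("GS", 40), stringsAsFactors = FALSE)
  expect_equal(nrow(run_pipeline(inert, fx$ensemble)), 0)
  # byte-identical CSV across repeat runs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(rows, f1)
  write_results_csv(run_pipeline(toy$records, fx$ensemble), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the pipeline accepts FASTA and bundle paths and checks alignment", {
  fx <- tiny_ensemble()
  toy <- generate_toy_proteome(n_nabp = 1, n_other = 2, seed = 4,
                               min_length = 60, max_length = 80)
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(toy$records, fasta)
  bundle <- withr::local_tempdir()
  save_bundle(fx$ensemble, bundle)
  rows <- run_pipeline(fasta, bundle)
  expect_identical(rows, run_pipeline(toy$records, fx$ensemble))
  # corrupting the manifest's feature order must be a hard error
  man <- file.path(bundle, "manifest.txt")
  lines <- readLines(man)
  lines <- sub("^feature_order: .*", "feature_order: a,b,c", lines)
  writeLines(lines, man)
  expect_error(run_pipeline(fasta, bundle), "feature order")
})
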