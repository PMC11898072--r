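test_that("generators honour class sizes, length and determinism", {
  sp <- synthetic_spec(n_pos = 40, n_neg_albumin = 15, n_neg_random = 25,
                       seed = 5)
  pos <- generate_positive(sp)
  neg <- generate_negative(sp)
  expect_equal(nrow(pos), 40)
  expect_equal(nrow(neg), 40)
  expect_true(all(nchar(c(pos$sequence, neg$sequence)) == 22))
  expect_equal(sum(grepl("albumin", neg$description)), 15)
  expect_equal(sum(grepl("random", neg$description)), 25)
  # byte-identical for equal seeds, different for different seeds
  expect_identical(generate_positive(sp), pos)
  sp2 <- synthetic_spec(n_pos = 40, n_neg_albumin = 15, n_neg_random = 25,
                        seed = 6)
  expect_false(identical(generate_positive(sp2)$sequence, pos$sequence))
})

test_that("default spec reproduces the published training design", {
  sp <- synthetic_spec()
  expect_equal(sp$n_pos, 2560L)
  expect_equal(sp$n_neg_albumin, 701L)
  expect_equal(sp$n_neg_random, 1859L)
  expect_equal(sp$length, 22L)
  expect_error(synthetic_spec(length = 5), "length")
})

test_that("positives carry the R3H motif and basic enrichment", {
  sp <- synthetic_spec(n_pos = 200, n_neg_albumin = 0, n_neg_random = 200,
                       seed = 0)
  pos <- generate_positive(sp)
  expect_true(all(grepl("R...H", pos$sequence)))
  neg <- generate_negative(sp)
  fb <- function(seqs) mean(vapply(seqs, class_frequency, 0,
                                   cls = c("K", "R"), USE.NAMES = FALSE))
  expect_gt(fb(pos$sequence), fb(neg$sequence))
})

test_that("uniform negatives have ~0.05 per-residue frequency", {
  sp <- synthetic_spec(n_pos = 0, n_neg_albumin = 0, n_neg_random = 400,
                       seed = 1)
  neg <- generate_negative(sp)
  chars <- unlist(strsplit(neg$sequence, ""))
  n <- length(chars)  # 400 * 22 draws
  sigma <- sqrt(0.05 * 0.95 / n)
  for (aa in amino_acids()) {
    expect_lt(abs(mean(chars == aa) - 0.05), 3 * sigma + 1e-12)
  }
})

test_that("the toy proteome plants detectable, keyword-annotated proteins", {
  toy <- generate_toy_proteome(n_nabp = 10, n_other = 90, seed = 0)
  expect_equal(nrow(toy$records), 100)
  expect_length(toy$nabp_ids, 10)
  # every planted protein carries at least one extractable helix
  for (id in toy$nabp_ids) {
    s <- toy$records$sequence[toy$records$id == id]
    expect_gt(nrow(extract_helices(s, id = id)), 0)
  }
  # keyword filter recovers exactly the planted ids
  expect_setequal(keyword_filter(toy$annotations), toy$nabp_ids)
  # determinism
  again <- generate_toy_proteome(n_nabp = 10, n_other = 90, seed = 0)
  expect_identical(again$records, toy$records)
  # degenerate sizes
  none <- generate_toy_proteome(n_nabp = 0, n_other = 5, seed = 1)
  expect_length(none$nabp_ids, 0)
  expect_equal(nrow(none$records), 5)
})

test_that("annotation tables round-trip as TSV", {
  toy <- generate_toy_proteome(n_nabp = 3, n_other = 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(toy$annotations, f)
  expect_equal(read_annotations(f), toy$annotations)
})

test_that("FASTA-pair loading matches the in-memory labelled dataset", {
  sp <- synthetic_spec(n_pos = 15, n_neg_albumin = 5, n_neg_random = 10,
                       seed = 9)
  pos <- generate_positive(sp)
  neg <- generate_negative(sp)
  fp <- withr::local_tempfile(fileext = ".fasta")
  fn <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pos, fp)
  write_fasta(neg, fn)
  ds <- load_training_set(fp, fn)
  expect_equal(sum(ds$y), 15)
  expect_equal(sum(!ds$y), 15)
  expect_equal(unname(ds$x), unname(generate_training_set(sp)$x))
})
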