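test_that("class frequencies are simple fractions in [0, 1]", {
  expect_equal(class_frequency("KKKK", c("K", "R")), 1)
  expect_equal(class_frequency("ACDEFGHIKLMNPQRSTVWY", c("D", "E")), 0.10)
  expect_equal(class_frequency("GAGA", c("K", "R")), 0)
  expect_error(class_frequency("", c("K")), "empty")
})

test_that("scale averages are means and permutation invariant", {
  sc <- scale_config()$scales$hydropathy
  expect_equal(scale_average("AAAA", sc), unname(sc["A"]))
  expect_equal(scale_average("AG", sc), unname((sc["A"] + sc["G"]) / 2))
  expect_equal(scale_average("KR", sc), scale_average("RK", sc))
  expect_error(scale_average("AK", c(A = 1)), "does not define")
})

test_that("Henderson-Hasselbalch charge matches hand calculations", {
  expect_equal(charge_at_ph("AAAA"), 0)
  # lysine side chain, pKa 10.5: 1 / (1 + 10^(7.4 - 10.5))
  expect_equal(charge_at_ph("K"), 1 / (1 + 10^(7.4 - 10.5)), tolerance = 1e-10)
  # half-dissociation exactly at the pKa
  expect_equal(charge_at_ph("D", pH = 3.9), -0.5)
  # termini add one basic and one acidic group
  expect_lt(charge_at_ph("AAAA", include_termini = TRUE), 0)
})

test_that("charge is monotonically non-increasing in pH", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_protein(12)
    ph <- seq(0, 14, length.out = 30)
    q <- vapply(ph, function(p) charge_at_ph(s, p), 0)
    expect_true(all(diff(q) <= 1e-12), info = s)
  }
})

test_that("the isoelectric point is the zero of the charge curve", {
  cfg <- scale_config()
  expect_equal(isoelectric_point("AAAA"), 7)      # no ionizable groups
  expect_gt(isoelectric_point("KK"), 7.4)         # net positive at neutral pH
  # independent oracle: uniroot on the exported charge function
  set.seed(8)
  for (i in 1:20) {
    s <- paste0(random_protein(10), "DK")  # guarantee both group types
    p <- isoelectric_point(s, cfg)
    expect_lt(abs(charge_at_ph(s, p, cfg)), 1e-3)
    oracle <- stats::uniroot(function(ph) charge_at_ph(s, ph, cfg),
                             c(0, 14), tol = 1e-9)$root
    expect_equal(p, oracle, tolerance = 1e-3)
  }
  # composition-only: invariant under sequence permutation
  expect_equal(isoelectric_point("KRDEAY"), isoelectric_point("YAEDRK"))
})

test_that("instability index follows the dipeptide formula", {
  cfg <- scale_config()
  # single dipeptide: 10/2 * DIWV
  expect_equal(instability_index("MK", cfg), 5 * cfg$diwv["M", "K"])
  expect_equal(instability_index("GG", cfg), 5 * cfg$diwv["G", "G"])
  # all-ones dipeptide weights: 10 * (L - 1) / L
  expect_equal(instability_index("AIAIAIAI", cfg), 10 * 7 / 8)
  expect_error(instability_index("A", cfg), "at least 2")
  # frozen values from an independent reference implementation
  expect_equal(instability_index("MKELLNRAQHAEKLMRQAEKHA"), 11.013636,
               tolerance = 1e-6)
  expect_equal(instability_index("ACDEFGHIKLMNPQRSTVWY"), 84.74,
               tolerance = 1e-6)
  expect_equal(instability_index("KRKRHHEEDDAALLMMQQWWYC"), 75.527273,
               tolerance = 1e-6)
})

test_that("the descriptor has 20 canonical, deterministic, bounded values", {
  f <- compute_features("MKELLNRAQHAEKLMRQAEKHA")
  expect_length(f, 20)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_identical(f, compute_features("MKELLNRAQHAEKLMRQAEKHA"))
  freq <- f[startsWith(names(f), "freq_")]
  expect_true(all(freq >= 0 & freq <= 1))
  expect_gte(f[["isoelectric_point"]], 0)
  expect_lte(f[["isoelectric_point"]], 14)
  # frequency over the full alphabet is 1 by definition
  expect_equal(class_frequency("MKELLNRAQ", amino_acids()), 1)
})

test_that("a polylysine peptide is maximally basic and strongly charged", {
  f <- compute_features(strrep("K", 22))
  expect_equal(f[["freq_basic"]], 1)
  expect_gt(f[["charge_at_pH7.4"]], 20)
})

test_that("feature matrices stack descriptors row-wise", {
  seqs <- c("MKELLNRAQHAE", "AAAAAAAAAAAA")
  m <- compute_feature_matrix(seqs)
  expect_equal(dim(m), c(2L, 20L))
  expect_identical(colnames(m), feature_names())
  expect_equal(m[1, ], compute_features(seqs[1]))
})

test_that("scale configurations round-trip through YAML and hash stably", {
  cfg <- scale_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scale_config(cfg, f)
  back <- read_scale_config(f)
  expect_equal(back$classes, cfg$classes)
  expect_equal(back$scales, cfg$scales, tolerance = 1e-12)
  expect_equal(unname(back$diwv), unname(cfg$diwv), tolerance = 1e-12)
  expect_identical(scale_config_hash(back), scale_config_hash(cfg))
  cfg2 <- cfg
  cfg2$scales$redox["C"] <- 0.9
  expect_false(identical(scale_config_hash(cfg2), scale_config_hash(cfg)))
})
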