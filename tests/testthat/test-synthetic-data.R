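# Generator: preset compositions, determinism, mixture structure, lengths.

test_that("presets encode the published dataset compositions", {
  cfg <- default_config("balanced_type", seed = 7)
  expect_identical(unname(cfg$per_class_counts),
                   rep(260L, 11L))
  expect_identical(names(cfg$per_class_counts), incident_type_labels())

  cfg <- default_config("balanced_severity", seed = 7)
  expect_identical(unname(cfg$per_class_counts), rep(290L, 4L))

  cfg <- default_config("stratified_independent", seed = 7, task = "type")
  expect_identical(
    cfg$per_class_counts,
    c(falls = 872, medications = 1053, pressure_injury = 190,
      aggression = 487, documentation = 252, blood_product = 59,
      patient_identification = 86, infection = 22, clinical_handover = 87,
      deteriorating_patient = 14, others = 2878))
  expect_identical(sum(cfg$per_class_counts), 6000)

  cfg <- default_config("stratified_original", seed = 7, task = "severity")
  expect_identical(cfg$per_class_counts,
                   c(SAC1 = 25, SAC2 = 95, SAC3 = 2198, SAC4 = 2519))

  # independent preset uses the independent-system length model
  cfg <- default_config("stratified_independent", seed = 7)
  expect_equal(cfg$length_mean, 63.4)
  expect_equal(cfg$length_max, 404)

  expect_error(default_config("nope"), "balanced_type")
})

test_that("config invariants are validated", {
  expect_error(tiny_config(overlap = 1.5), "\\[0, 1\\]")
  expect_error(tiny_config(length_min = 0), "length_min")
  bad <- function() {
    pools <- list(a = c("x", "y"), b = c("y", "z"))
    generator_config(c("a", "b"), c(a = 2L, b = 2L), pools,
                     length_mean = 10, length_sd = 2, length_min = 5,
                     length_max = 20)
  }
  expect_error(bad(), "disjoint")
  expect_error(
    generator_config(c("a", "b"), c(a = 2L, b = 2L),
                     list(a = character(0), b = "z"),
                     length_mean = 10, length_sd = 2, length_min = 5,
                     length_max = 20),
    "empty class_term_pools")
})

test_that("generated corpora conserve counts and are deterministic", {
  cfg <- default_config("balanced_type", seed = 7)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp), 2860L)
  expect_true(all(table(corp$incident_type) == 260L))
  corp2 <- generate_corpus(default_config("balanced_type", seed = 7))
  expect_identical(corp, corp2)
  corp3 <- generate_corpus(default_config("balanced_type", seed = 8))
  expect_false(identical(corp$narrative, corp3$narrative))
})

test_that("word counts respect the truncated-normal bounds", {
  cfg <- tiny_config(k = 3, n = 100, seed = 4)
  corp <- generate_corpus(cfg)
  wc <- lengths(strsplit(corp$narrative, " ", fixed = TRUE))
  expect_true(all(wc >= cfg$length_min & wc <= cfg$length_max))
  expect_true(all(nzchar(corp$narrative)))
})

test_that("overlap = 0 yields pure class vocabularies", {
  cfg <- tiny_config(k = 4, n = 25, overlap = 0, seed = 2)
  corp <- generate_corpus(cfg)
  toks <- strsplit(corp$narrative, " ", fixed = TRUE)
  for (k in names(cfg$per_class_counts)) {
    other_terms <- unlist(cfg$class_term_pools[
      setdiff(names(cfg$class_term_pools), k)])
    rows <- which(corp$incident_type == k)
    expect_false(any(unlist(toks[rows]) %in% other_terms), info = k)
  }
})

test_that("discriminative terms concentrate in their own class", {
  # mean within-class frequency of class-k terms strictly exceeds their
  # frequency in other classes (counted over the generated corpus)
  cfg <- tiny_config(k = 3, n = 2000, overlap = 0.2, seed = 9)
  corp <- generate_corpus(cfg)
  toks <- strsplit(corp$narrative, " ", fixed = TRUE)
  for (k in names(cfg$class_term_pools)) {
    own_rows <- corp$incident_type == k
    pool <- cfg$class_term_pools[[k]]
    freq_in <- mean(vapply(toks[own_rows],
                           function(t) mean(t %in% pool), numeric(1)))
    freq_out <- mean(vapply(toks[!own_rows],
                            function(t) mean(t %in% pool), numeric(1)))
    expect_gt(freq_in, freq_out)
  }
})

test_that("severity corpora carry level-indicative keywords", {
  cfg <- default_config("balanced_severity", seed = 5, sac23_blend = 0,
                        overlap = 0)
  corp <- generate_corpus(cfg)
  kw <- default_severity_keywords()
  sac1_tok <- unlist(strsplit(corp$narrative[corp$severity == "SAC1"], " "))
  # every SAC1 report got 1-3 phrases; pool tokens must appear
  expect_true(any(sac1_tok == "death") || any(sac1_tok == "suicide"))
  # with no blending, SAC4-only phrases stay out of SAC1 reports
  expect_false(any(sac1_tok == "nearmiss"))
})

test_that("corpus summaries reproduce the design totals", {
  s <- summarize_corpus(generate_corpus(default_config("balanced_type", 1)))
  expect_equal(s$total, 2860L)
  s <- summarize_corpus(generate_corpus(default_config("balanced_severity", 1)))
  expect_equal(s$total, 1160L)
  one <- data.frame(report_id = "r1", narrative = "a b c d e",
                    incident_type = "falls", severity = NA, source = "x")
  s <- summarize_corpus(one)
  expect_equal(s$total, 1L)
  expect_equal(s$mean_length, 5)
  expect_equal(s$sd_length, 0)
  s <- summarize_corpus(one[0, ])
  expect_equal(s$total, 0L)
  expect_false(s$lengths_defined)
})

test_that("JSONL and CSV round-trips preserve the corpus", {
  corp <- tiny_corpus(k = 2, n = 5, seed = 3)
  for (ext in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_corpus(corp, path)
    back <- read_corpus(path)
    expect_equal(back$narrative, corp$narrative)
    expect_equal(back$incident_type, corp$incident_type)
    expect_equal(back$report_id, corp$report_id)
  }
})
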