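test_that("generation bookkeeping, determinism and FASTA round-trip", {
  spec <- synthetic_spec(n_positive = 5, n_negative = 5, length = 300,
                         seed = 1)
  set <- generate_synthetic(spec)
  expect_equal(length(set), 10L)
  expect_true(all(nchar(set$records$sequence) == 300))
  expect_equal(label_counts(set), c(positive = 5L, negative = 5L))

  # byte-identical FASTA for the same seed
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  for (d in c(d1, d2))
    generate_to_fasta(spec, file.path(d, "p.fa"), file.path(d, "n.fa"),
                      file.path(d, "spec.json"))
  expect_identical(readLines(file.path(d1, "p.fa")),
                   readLines(file.path(d2, "p.fa")))
  expect_identical(readLines(file.path(d1, "n.fa")),
                   readLines(file.path(d2, "n.fa")))
  side <- jsonlite::read_json(file.path(d1, "spec.json"))
  expect_equal(side$seed, 1L)
  expect_equal(side$motif, "GGG")

  # round-trips through sequence_io
  back <- read_labeled_fasta(file.path(d1, "p.fa"), file.path(d1, "n.fa"))
  expect_equal(back$records$sequence, set$records$sequence)
})

test_that("planting rate 1 with 3 copies puts >= 3 motif occurrences in positives", {
  spec <- synthetic_spec(n_positive = 30, n_negative = 5, length = 120,
                         motif = "GGG", planting_rate = 1, copies = 3, seed = 2)
  set <- generate_synthetic(spec)
  pos <- set$records$sequence[set$records$label == "positive"]
  for (s in pos)
    expect_gte(count_motif_oracle(s, "GGG"), 3)
  # rate 0: no systematic enrichment
  spec0 <- synthetic_spec(n_positive = 30, n_negative = 30, length = 120,
                          planting_rate = 0, seed = 2)
  set0 <- generate_synthetic(spec0)
  cnt <- vapply(set0$records$sequence, count_motif_oracle, numeric(1), "GGG")
  lab <- set0$records$label
  expect_lt(abs(mean(cnt[lab == "positive"]) - mean(cnt[lab == "negative"])), 1)
})

test_that("motif placement errors when copies cannot fit", {
  expect_error(generate_synthetic(
    synthetic_spec(n_positive = 1, n_negative = 1, length = 10,
                   motif = "ACGTA", copies = 3, seed = 1)),
    "cannot fit")
  expect_error(synthetic_spec(length = 3, motif = "ACGT"), "motif length")
  expect_error(synthetic_spec(background = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(synthetic_spec(planting_rate = 2), "planting_rate")
})

test_that("empirical composition converges to the stated probabilities", {
  spec <- synthetic_spec(n_positive = 0, n_negative = 200, length = 300,
                         background = c(0.4, 0.3, 0.2, 0.1), motif = "",
                         seed = 5)
  set <- generate_synthetic(spec)
  chars <- strsplit(paste(set$records$sequence, collapse = ""), "")[[1]]
  freq <- table(factor(chars, levels = c("A", "C", "G", "T"))) / length(chars)
  expect_equal(as.numeric(freq), c(0.4, 0.3, 0.2, 0.1), tolerance = 0.02)
})

test_that("a +0.3 GC-skew offset is recovered in the class-mean difference", {
  spec <- synthetic_spec(n_positive = 200, n_negative = 200, length = 300,
                         motif = "", gc_skew_offset = 0.3, seed = 6)
  set <- generate_synthetic(spec)
  fm <- extract_features(set, "base_content")
  gc_skew <- fm$x[, "base:gc_skew"]
  diff <- mean(gc_skew[fm$labels == "positive"]) -
          mean(gc_skew[fm$labels == "negative"])
  expect_equal(diff, 0.3, tolerance = 0.05)
})

test_that("two_species warns on coinciding specs and respects seeds", {
  a <- synthetic_spec(n_positive = 3, n_negative = 3, length = 50, seed = 7)
  b <- synthetic_spec(n_positive = 3, n_negative = 3, length = 50, seed = 8)
  expect_warning(two_species(a, a), "coincide")
  pair <- two_species(a, b)
  expect_equal(pair[[1]]$species, "synthetic_A")
  expect_false(identical(pair[[1]]$records$sequence,
                         pair[[2]]$records$sequence))
})
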