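test_that("read_labeled_fasta merges, labels by file, and normalizes case", {
  pos <- write_fasta_file(c("p1", "p2"), c("ACGTAC", "acgtgt"),
                          tempfile(fileext = ".fa"))
  neg <- write_fasta_file(c("n1", "n2", "n3"),
                          c("TTTTTT", "CCCCCC", "GGGGGG"),
                          tempfile(fileext = ".fa"), width = 3)  # wrapped lines
  set <- read_labeled_fasta(pos, neg, species = "sp", expected_length = 6)
  expect_s3_class(set, "labeled_seq_set")
  expect_equal(length(set), 5L)
  expect_equal(label_counts(set), c(positive = 2L, negative = 3L))
  expect_equal(set$records$sequence[set$records$id == "p2"], "ACGTGT")
  expect_equal(set$species, "sp")
})

test_that("ingestion rejects bad alphabets, duplicates and empty files", {
  pos <- write_fasta_file("p1", "ACGX", tempfile(fileext = ".fa"))
  neg <- write_fasta_file("n1", "ACGT", tempfile(fileext = ".fa"))
  expect_error(read_labeled_fasta(pos, neg, expected_length = NULL), "p1")

  dup_neg <- write_fasta_file("p1", "ACGT", tempfile(fileext = ".fa"))
  ok_pos <- write_fasta_file("p1", "ACGT", tempfile(fileext = ".fa"))
  expect_error(read_labeled_fasta(ok_pos, dup_neg, expected_length = NULL),
               "duplicate")

  empty <- tempfile(fileext = ".fa"); file.create(empty)
  expect_error(read_labeled_fasta(ok_pos, empty, expected_length = NULL),
               "empty|malformed")

  # N accepted at ingestion
  npos <- write_fasta_file("p1", "ACNGT", tempfile(fileext = ".fa"))
  nneg <- write_fasta_file("n1", "ACGTT", tempfile(fileext = ".fa"))
  expect_silent(read_labeled_fasta(npos, nneg, expected_length = NULL))
})

test_that("length validation warns (or errors) on off-length sequences", {
  pos <- write_fasta_file("p1", "ACGTA", tempfile(fileext = ".fa"))
  neg <- write_fasta_file("n1", "ACGT", tempfile(fileext = ".fa"))
  expect_warning(read_labeled_fasta(pos, neg, expected_length = 4), "length")
  expect_error(read_labeled_fasta(pos, neg, expected_length = 4,
                                  warn_only = FALSE), "length")
})

test_that("FASTA round-trip reproduces the identical set", {
  set.seed(41)
  set <- toy_set(replicate(4, random_dna(30)), replicate(5, random_dna(30)),
                 species = "rt")
  fp <- tempfile(fileext = ".fa"); fn <- tempfile(fileext = ".fa")
  write_labeled_fasta(set, fp, fn)
  back <- read_labeled_fasta(fp, fn, species = "rt", expected_length = NULL)
  expect_equal(back$records, set$records)
})

test_that("split is stratified, per-class floor rounding, seeded, a partition", {
  set.seed(7)
  set <- toy_set(replicate(8, random_dna(20)), replicate(8, random_dna(20)))
  sp <- split_train_test(set, 0.2, seed = 3)
  expect_equal(label_counts(sp$test), c(positive = 1L, negative = 1L))
  expect_equal(label_counts(sp$train), c(positive = 7L, negative = 7L))

  set10 <- toy_set(replicate(10, random_dna(20)), replicate(10, random_dna(20)))
  sp10 <- split_train_test(set10, 0.2, seed = 3)
  expect_equal(label_counts(sp10$test), c(positive = 2L, negative = 2L))

  # determinism and partition
  sp10b <- split_train_test(set10, 0.2, seed = 3)
  expect_identical(sp10b$test$records$id, sp10$test$records$id)
  expect_length(intersect(sp10$train$records$id, sp10$test$records$id), 0)
  expect_setequal(c(sp10$train$records$id, sp10$test$records$id),
                  set10$records$id)

  expect_error(split_train_test(toy_set("ACGT", c("AAAA", "TTTT")), 0.2),
               "at least 2")
  expect_error(split_train_test(set10, 1.2), "test_fraction")
})

test_that("split manifest records every id with its partition", {
  set.seed(8)
  set <- toy_set(replicate(5, random_dna(10)), replicate(5, random_dna(10)))
  sp <- split_train_test(set, 0.2, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_split_manifest(sp, path)
  man <- read.table(path, header = TRUE, sep = "\t")
  expect_setequal(man$id, set$records$id)
  expect_equal(sort(unique(man$partition)), c("test", "train"))
})
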