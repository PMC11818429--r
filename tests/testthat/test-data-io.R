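test_that("label encoding follows the fixed AMP/ACP/ADP/AHP/AIP order", {
  expect_identical(encode_labels(c("AMP", "ACP")), c(1L, 1L, 0L, 0L, 0L))
  expect_identical(encode_labels(character(0)), rep(0L, 5L))
  expect_identical(encode_labels("AIP"), c(0L, 0L, 0L, 0L, 1L))
  expect_error(encode_labels("AXP"), "valid names")
  expect_identical(decode_labels(c(1L, 1L, 0L, 0L, 0L)), c("AMP", "ACP"))
})

test_that("FASTA round trip preserves records and label headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pep1|AMP,ACP", "GFMKYIGPLIPHAVKAISDLI",
               ">pep2|01000", "ACDEFGHIK",
               ">pep3", "KLMNPQR"), f)
  recs <- read_peptides(f)
  expect_equal(nrow(recs), 3L)
  expect_identical(unname(label_matrix(recs)[1L, ]), c(1L, 1L, 0L, 0L, 0L))
  expect_identical(unname(label_matrix(recs)[2L, ]), c(0L, 1L, 0L, 0L, 0L))
  expect_identical(unname(label_matrix(recs)[3L, ]), rep(0L, 5L))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_peptides(recs, out, "fasta")
  expect_identical(read_peptides(out), recs)
})

test_that("CSV dialect round trips and infers ids when absent", {
  recs <- small_fixture(n_per = 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peptides(recs, f, "csv")
  back <- read_peptides(f)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(label_matrix(back), label_matrix(recs))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,labels", "ACDK,\"AMP,AIP\"", "GGGG,"), f2)
  got <- read_peptides(f2)
  expect_identical(got$id, c("pep1", "pep2"))
  expect_identical(unname(label_matrix(got)[1L, ]), c(1L, 0L, 0L, 0L, 1L))
})

test_that("validation rejects non-standard residues naming the record", {
  expect_error(peptide_set("p1", "ACDX"), "non-standard residue 'X'")
  expect_error(peptide_set("p1", "ACDX"), "p1")
  expect_warning(v <- validate_peptides(peptide_set("p1", "ACDK")),
                 NA)
  expect_warning(read_lower <- peptide_set("p2", "acdk"), "upper-cased")
  expect_identical(read_lower$sequence, "ACDK")
})

test_that("empty input files yield empty datasets with a warning", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_warning(recs <- read_peptides(f), "empty")
  expect_equal(nrow(recs), 0L)
})

test_that("deduplicate merges duplicate sequences by label union", {
  recs <- peptide_set(c("a", "b", "c"), c("AAAA", "AAAA", "CCCC"),
                      rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0),
                            c(0, 0, 1, 0, 0)))
  expect_message(out <- deduplicate(recs), "merged")
  expect_equal(nrow(out), 2L)
  expect_identical(unname(label_matrix(out)[1L, ]), c(1L, 1L, 0L, 0L, 0L))
  # idempotent, and a no-op on distinct input
  expect_identical(deduplicate(out), out)
  distinct <- small_fixture(n_per = 4L)
  expect_identical(deduplicate(distinct), distinct)
})

test_that("group-stratified split partitions records as specified", {
  recs <- small_fixture(n_per = 20L)  # 5 combos x 20
  sp <- split_train_test(recs, 0.8, seed = 11L)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_length(intersect(sp$train$sequence, sp$test$sequence), 0L)
  expect_setequal(c(sp$train$id, sp$test$id), recs$id)
  # every combination with >= 2 members appears on both sides
  combos <- function(x) unique(apply(label_matrix(x), 1L, paste,
                                     collapse = ""))
  expect_setequal(combos(sp$train), combos(sp$test))
  # determinism
  sp2 <- split_train_test(recs, 0.8, seed = 11L)
  expect_identical(sp$train$id, sp2$train$id)
  # a 5-member group yields 4 train / 1 test
  five <- recs[1:5, ]
  sp5 <- split_train_test(five, 0.8, seed = 2L)
  expect_equal(nrow(sp5$train), 4L)
  expect_equal(nrow(sp5$test), 1L)
  expect_error(split_train_test(recs, 1.2), "between 0 and 1")
})

test_that("prediction tables round trip", {
  probs <- matrix(runif(10), 2L, 5L)
  dec <- decide(probs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(c("a", "b"), probs, dec, f)
  back <- read_predictions(f)
  expect_equal(as.matrix(back[, paste0("prob_", label_space())]),
               probs, ignore_attr = TRUE)
  expect_equal(as.matrix(back[, paste0("pred_", label_space())]),
               dec, ignore_attr = TRUE)
})
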