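ref6 <- c(T1 = "TGCAAT")

test_that("read_indels classifies pure indels and skips the rest", {
  vcf <- write_test_vcf(c(
    "T1\t3\t.\tCA\tC\t.\tPASS\t.",      # deletion, length 1
    "T1\t3\t.\tC\tCAG\t.\tPASS\t.",     # insertion, length 2
    "T1\t3\t.\tCA\tCG\t.\tPASS\t."))    # MNP: skipped
  calls <- read_indels(vcf, ref6)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$kind, c("deletion", "insertion"))
  expect_equal(calls$length, c(1L, 2L))
  expect_equal(attr(calls, "n_skipped"), 1L)
  # deletion of an A anchored on the C, left-normalized within the AA run
  expect_equal(calls$int_start[1], 3L)
  expect_equal(calls$int_end[1], 4L)
})

test_that("multi-allelic records are split per ALT allele", {
  vcf <- write_test_vcf("T1\t3\t.\tC\tCA,CTT\t.\tPASS\t.")
  calls <- read_indels(vcf, ref6)
  expect_equal(nrow(calls), 2L)
  expect_equal(sort(calls$length), c(1L, 2L))
})

test_that("FILTER handling and unknown transcripts behave as configured", {
  vcf <- write_test_vcf(c(
    "T1\t3\t.\tC\tCA\t.\tq10\t.",
    "T9\t3\t.\tC\tCA\t.\tPASS\t."))
  expect_warning(calls <- read_indels(vcf, ref6), "dropped")
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "n_filtered"), 1L)
  expect_equal(attr(calls, "n_dropped_seq"), 1L)
  suppressWarnings(calls2 <- read_indels(vcf, ref6, keep_filtered = TRUE))
  expect_equal(nrow(calls2), 1L)
})

test_that("a REF allele inconsistent with the reference is an error", {
  vcf <- write_test_vcf("T1\t3\t.\tGA\tG\t.\tPASS\t.")
  expect_error(read_indels(vcf, ref6), "does not match reference")
})

test_that("left normalization matches the string-edit oracle", {
  # worked example: deletion inside a homopolymer shifts to the run start
  call <- data.frame(seq_id = "q", pos = 2L, ref = "AA", alt = "A",
                     kind = "deletion", length = 1L, int_start = 3L,
                     int_end = 4L, stringsAsFactors = FALSE)
  norm <- left_normalize(call, c(q = "CAAAT"))
  expect_equal(norm$pos, 0L)
  expect_equal(norm$ref, "CA")
  expect_equal(norm$alt, "C")
  # every equivalent phase of a repeat insertion lands on one representation
  s <- c(q = "GACACT")
  reps <- lapply(list(c(1L, "AC"), c(2L, "CA"), c(3L, "AC")), function(x) {
    p <- as.integer(x[1]); ins <- x[2]
    call <- data.frame(seq_id = "q", pos = p - 1L,
                       ref = substr(s, p, p),
                       alt = paste0(substr(s, p, p), ins),
                       kind = "insertion", length = 2L,
                       int_start = p, int_end = p,
                       stringsAsFactors = FALSE)
    left_normalize(call, s)
  })
  expect_true(all(vapply(reps, function(r) r$pos == reps[[1]]$pos,
                         logical(1))))
  expect_true(all(vapply(reps, function(r) r$alt == reps[[1]]$alt,
                         logical(1))))

  set.seed(404)
  for (i in 1:150) {
    sq <- random_seq(sample(20:60, 1)); n <- nchar(sq)
    if (i %% 2 == 0) {
      d <- sample(1:4, 1); a <- sample(1:(n - d - 1), 1)
      call <- data.frame(seq_id = "q", pos = a - 1L,
                         ref = substr(sq, a, a + d),
                         alt = substr(sq, a, a), kind = "deletion",
                         length = d, int_start = a, int_end = a + d,
                         stringsAsFactors = FALSE)
      norm <- left_normalize(call, c(q = sq))
      expect_equal(apply_deletion(sq, norm$int_start, d),
                   apply_deletion(sq, a, d))
      expect_equal(norm$int_start, oracle_leftmost_deletion(sq, a, d))
      expect_identical(left_normalize(norm, c(q = sq)), norm)
    } else {
      d <- sample(1:4, 1); p <- sample(1:(n - 2), 1)
      ins <- random_seq(d)
      call <- data.frame(seq_id = "q", pos = p - 1L,
                         ref = substr(sq, p, p),
                         alt = paste0(substr(sq, p, p), ins),
                         kind = "insertion", length = d,
                         int_start = p, int_end = p,
                         stringsAsFactors = FALSE)
      norm <- left_normalize(call, c(q = sq))
      orc <- oracle_leftmost_insertion(sq, p, ins)
      expect_equal(apply_insertion(sq, norm$int_start,
                                   substr(norm$alt, 2, d + 1)),
                   apply_insertion(sq, p, ins))
      expect_equal(norm$int_start, orc$point)
      expect_identical(left_normalize(norm, c(q = sq)), norm)
    }
  }
})

test_that("known-variant filtering matches by normalized key", {
  ref <- c(T1 = "TGCAATTGCAAT")
  vcf <- write_test_vcf(c(
    "T1\t3\t.\tCA\tC\t.\tPASS\t.",
    "T1\t9\t.\tCA\tC\t.\tPASS\t.",
    "T1\t9\t.\tC\tCG\t.\tPASS\t."))
  calls <- read_indels(vcf, ref)
  # empty known set is the identity
  kept <- filter_known(calls, NULL)
  expect_equal(nrow(kept), nrow(calls))
  expect_equal(attr(kept, "n_removed"), 0L)
  # a matching key is removed; a different ALT at the same position stays
  known <- write_test_vcf("T1\t9\t.\tCA\tC\t.\t.\t.")
  ks <- read_known_variants(known, ref)
  kept <- filter_known(calls, ks)
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_false(any(kept$pos == 8L & kept$kind == "deletion"))
  # conservation: |output| + removed == |input|
  expect_equal(nrow(kept) + attr(kept, "n_removed"), nrow(calls))
})

test_that("known filtering works across representations of the same edit", {
  # the known VCF reports the deletion at a different phase of the run;
  # normalization on both sides makes the keys collide anyway
  ref <- c(T1 = "TGCAAAAT")
  sample_vcf <- write_test_vcf("T1\t3\t.\tCA\tC\t.\tPASS\t.")
  known_vcf <- write_test_vcf("T1\t6\t.\tAA\tA\t.\t.\t.")
  calls <- read_indels(sample_vcf, ref)
  ks <- read_known_variants(known_vcf, ref)
  expect_equal(nrow(filter_known(calls, ks)), 0L)
})
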