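one_tract <- data.frame(seq_id = "T1", start = 10L, end = 20L, unit = "A",
                        copies = 10, stringsAsFactors = FALSE)

mk_call <- function(kind, pos, len = 1L, seq_id = "T1") {
  data.frame(seq_id = seq_id, pos = pos, ref = "A", alt = "AT", kind = kind,
             length = len, int_start = pos + 1L,
             int_end = pos + 1L + if (kind == "deletion") len else 0L,
             known = FALSE, stringsAsFactors = FALSE)
}

test_that("deletions intersect tracts by interval overlap", {
  ann <- annotate_indels(mk_call("deletion", 11L, 2L), one_tract)  # [12,14)
  expect_true(ann$in_ms)
  expect_equal(ann$ms_id, "T1:10-20")
  ann <- annotate_indels(mk_call("deletion", 24L, 2L), one_tract)  # [25,27)
  expect_false(ann$in_ms)
  # overlap at a single base suffices
  ann <- annotate_indels(mk_call("deletion", 18L, 5L), one_tract)  # [19,24)
  expect_true(ann$in_ms)
})

test_that("insertions intersect tracts including the left-flank anchor", {
  # left-normalized tract-lengthening insertions sit one base left of the
  # tract, so the anchor position start-1 must count as inside
  ann <- annotate_indels(mk_call("insertion", 9L), one_tract)
  expect_true(ann$in_ms)
  ann <- annotate_indels(mk_call("insertion", 19L), one_tract)
  expect_true(ann$in_ms)
  ann <- annotate_indels(mk_call("insertion", 8L), one_tract)
  expect_false(ann$in_ms)
  ann <- annotate_indels(mk_call("insertion", 20L), one_tract)
  expect_false(ann$in_ms)
})

test_that("tie-break picks the smallest start, then the longest tract", {
  two <- data.frame(seq_id = "T1", start = c(10L, 14L), end = c(20L, 30L),
                    unit = c("A", "C"), copies = c(10, 16),
                    stringsAsFactors = FALSE)
  ann <- annotate_indels(mk_call("deletion", 15L, 2L), two)
  expect_equal(ann$ms_id, "T1:10-20")
  nested <- data.frame(seq_id = "T1", start = c(10L, 10L),
                       end = c(20L, 26L), unit = c("A", "AC"),
                       copies = c(10, 8), stringsAsFactors = FALSE)
  ann <- annotate_indels(mk_call("deletion", 12L, 1L), nested)
  expect_equal(ann$ms_id, "T1:10-26")
})

test_that("region assignment partitions the transcript by anchor position", {
  model <- data.frame(seq_id = "T1", length = 500L, cds_start = 100L,
                      cds_end = 400L, stringsAsFactors = FALSE)
  expect_equal(assign_region(50L, model), "five_prime_utr")
  expect_equal(assign_region(99L, model), "five_prime_utr")
  expect_equal(assign_region(100L, model), "cds")
  expect_equal(assign_region(150L, model), "cds")
  expect_equal(assign_region(399L, model), "cds")
  expect_equal(assign_region(400L, model), "three_prime_utr")
  nc <- data.frame(seq_id = "T1", length = 500L, cds_start = NA_integer_,
                   cds_end = NA_integer_, stringsAsFactors = FALSE)
  expect_equal(assign_region(150L, nc), "ncRNA")
  expect_error(assign_region(500L, model), "outside")
  expect_error(assign_region(-1L, model), "outside")
})

test_that("transcript model I/O validates CDS bounds", {
  m <- data.frame(seq_id = c("T1", "T2"), length = c(500L, 300L),
                  cds_start = c(100L, NA), cds_end = c(400L, NA),
                  stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_transcript_models(m, f)
  expect_equal(read_transcript_models(f), m)
  writeLines(c("seq_id\tlength\tcds_start\tcds_end", "T1\t500\t400\t100"), f)
  expect_error(read_transcript_models(f), "CDS bounds")
})

test_that("altered-tract counting collapses multiple indels per tract", {
  expect_equal(altered_microsatellite_count(
    annotate_indels(mk_call("deletion", 30L), one_tract)), 0L)
  three_in_one <- do.call(rbind, lapply(c(11L, 13L, 15L),
                                        function(p) mk_call("deletion", p)))
  expect_equal(altered_microsatellite_count(
    annotate_indels(three_in_one, one_tract)), 1L)
  two <- data.frame(seq_id = "T1", start = c(10L, 40L), end = c(20L, 50L),
                    unit = c("A", "C"), copies = c(10, 10),
                    stringsAsFactors = FALSE)
  in_two <- rbind(mk_call("deletion", 11L), mk_call("deletion", 41L))
  expect_equal(altered_microsatellite_count(annotate_indels(in_two, two)),
               2L)
})

test_that("region proportions sum to one or are flagged undefined", {
  ann <- fake_annotated(kind = rep("deletion", 4), in_ms = rep(TRUE, 4),
                        region = c("cds", "cds", "five_prime_utr",
                                   "three_prime_utr"))
  props <- region_proportions(ann)
  expect_equal(unname(props["cds"]), 0.5)
  expect_equal(unname(props["five_prime_utr"]), 0.25)
  expect_equal(unname(props["three_prime_utr"]), 0.25)
  expect_equal(unname(props["ncRNA"]), 0)
  expect_equal(sum(props), 1, tolerance = 1e-12)
  all_cds <- fake_annotated(kind = "deletion", in_ms = rep(TRUE, 3),
                            region = "cds")
  expect_equal(unname(region_proportions(all_cds)["cds"]), 1)
  none <- fake_annotated(kind = "deletion", in_ms = rep(FALSE, 3))
  expect_true(attr(region_proportions(none), "undefined"))
  expect_true(all(is.na(region_proportions(none))))
})

test_that("annotation is invariant to input order", {
  set.seed(31)
  tr <- simulate_transcriptome(small_params(), seed = 8)
  smp <- simulate_sample(tr, small_params(), seed = 9)
  ann <- annotate_indels(smp$calls, tr$catalogue, tr$models)
  perm <- sample(nrow(smp$calls))
  ann_shuf <- annotate_indels(smp$calls[perm, ], tr$catalogue, tr$models)
  reord <- ann_shuf[order(perm), ]
  rownames(reord) <- NULL
  expect_equal(reord, ann, ignore_attr = TRUE)
  # altered tracts never exceed microsatellite indel events
  expect_lte(altered_microsatellite_count(ann), sum(ann$in_ms))
})
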