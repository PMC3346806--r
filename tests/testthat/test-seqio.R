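test_that("FASTA reading extracts UniProt-style accessions and keeps order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">tr|Q1T7F1|Q1T7F1_HUMAN Uncharacterized protein",
    "MKTCCAGS",
    ">plain_id some hypothetical thing",
    "ACDEFGHIK"
  ), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$accession, "Q1T7F1")
  expect_equal(recs[[1]]$id, "Q1T7F1_HUMAN")
  expect_equal(recs[[2]]$accession, "")
  expect_equal(recs[[2]]$id, "plain_id")
  expect_equal(recs[[2]]$residues, "ACDEFGHIK")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_length(read_fasta(empty), 0)
})

test_that("residue sanitization maps U/O and ambiguity codes per policy", {
  r <- new_sequence_record("x", residues = "ACUOBZJ")
  expect_equal(r$residues, "ACCKXXX")
  expect_equal(r$n_nonstandard, 3)
  # X never counts as a cysteine
  expect_equal(chemoscan:::cys_count("XCX"), 1)
})

test_that("keyword filter is whole-word and case-insensitive", {
  mk <- function(desc) new_sequence_record("q", description = desc, residues = "ACDE")
  recs <- list(mk("hypothetical protein LOC12345"),
               mk("Interleukin-8 precursor"),
               mk("Putative uncharacterized protein"),
               mk("orfeome clone"))  # no whole-word 'orf'
  kept <- keyword_filter(recs)
  expect_equal(vapply(kept, function(r) r$description, character(1)),
               c("hypothetical protein LOC12345", "Putative uncharacterized protein"))
})

test_that("cysteine/length filter applies the 55 aa / 2 Cys thresholds inclusively", {
  mk <- function(n, ncys) {
    new_sequence_record("q", residues = paste(c(rep("C", ncys),
                                                rep("A", n - ncys)), collapse = ""))
  }
  expect_true(cys_length_filter(mk(55, 2))$pass)
  r <- cys_length_filter(mk(54, 10))
  expect_false(r$pass); expect_equal(r$reason, "length")
  r <- cys_length_filter(mk(100, 1))
  expect_false(r$pass); expect_equal(r$reason, "cysteines")
})

test_that("homology hit parsing handles the 12-column dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t45.0\t60\t5\t1\t1\t60\t1\t60\t1e-10\t100.5",
               "q2\ts2\t20.0\t30\t5\t1\t1\t30\t1\t30\t0.5\t22.0"), f)
  h <- parse_homology_hits(f)
  expect_equal(nrow(h), 2)
  expect_equal(h$percent_similarity[1], 45.0)
  expect_equal(h$alignment_length[1], 60L)
  expect_equal(h$evalue[1], 1e-10)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(parse_homology_hits(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t45.0\t60\t5\t1\t1\t60\t1\t60\t1e-10", bad)
  expect_error(parse_homology_hits(bad), "line 1")
})

test_that("annotation filter requires all three thresholds and is monotone", {
  rec <- new_sequence_record("q1", residues = strrep("A", 60))
  hit <- function(len, ev, sim) {
    tibble::tibble(query_id = "q1", subject_id = "s",
                   percent_similarity = sim, alignment_length = len, evalue = ev)
  }
  expect_false(annotation_filter(rec, hit(60, 1e-10, 45))$keep)
  expect_true(annotation_filter(rec, hit(40, 1e-10, 90))$keep)   # length <= 50
  expect_true(annotation_filter(rec, hit(60, 0.001, 45))$keep)   # e-value above
  expect_true(annotation_filter(rec, hit(60, 1e-10, 30))$keep)   # sim not > 30

  # monotonicity: relaxing any threshold never discards a previously kept record
  set.seed(42)
  for (k in 1:50) {
    h <- hit(sample(20:80, 1), 10^runif(1, -12, 0), runif(1, 0, 100))
    strict <- annotation_filter(rec, h, min_len = 50, max_eval = 5e-4, min_sim = 30)
    relaxed <- annotation_filter(rec, h, min_len = 60, max_eval = 1e-5, min_sim = 50)
    if (strict$keep) expect_true(relaxed$keep)
  }
})

test_that("signal-peptide consensus assigns confidence by cleavage agreement", {
  sp <- function(pos) list(has_sp = TRUE, cleavage_pos = pos)
  none <- list(has_sp = FALSE, cleavage_pos = 0)
  r <- consensus_signal_peptide(sp(22), sp(23))
  expect_equal(r$end, 22); expect_equal(r$confidence, "high")
  r <- consensus_signal_peptide(sp(15), sp(30))
  expect_equal(r$end, 15); expect_equal(r$confidence, "medium")
  r <- consensus_signal_peptide(none, sp(20))
  expect_equal(r$end, 20); expect_equal(r$confidence, "low")
  expect_null(consensus_signal_peptide(none, none))
  expect_error(consensus_signal_peptide(list(has_sp = TRUE, cleavage_pos = 0), sp(20)),
               "positive")
})

test_that("transmembrane consensus intersects methods and bands by length", {
  r <- consensus_transmembrane(rbind(c(10L, 30L)), rbind(c(12L, 32L)))
  expect_equal(unlist(r[1, c("start", "end")], use.names = FALSE), c(12L, 30L))
  expect_equal(r$confidence, "high")  # L = 19
  r <- consensus_transmembrane(rbind(c(1L, 40L)), rbind(c(11L, 45L)))
  expect_equal(r$confidence, "medium")  # L = 30
  r <- consensus_transmembrane(rbind(c(10L, 19L)), rbind(c(10L, 19L)))
  expect_equal(r$confidence, "low")  # L = 10
  # overlapping intervals within one prediction are merged before consensus
  r <- consensus_transmembrane(rbind(c(10L, 20L), c(18L, 30L)), rbind(c(12L, 32L)))
  expect_equal(nrow(r), 1)
  expect_equal(unlist(r[1, c("start", "end")], use.names = FALSE), c(12L, 30L))
  expect_equal(nrow(consensus_transmembrane(rbind(c(1L, 10L)), rbind(c(50L, 60L)))), 0)
})

test_that("region removal trims per confidence policy and conserves residues", {
  rec <- new_sequence_record("precursor208", residues = strrep("A", 208))
  sp <- tibble::tibble(kind = "signal_peptide", start = 1L, end = 52L,
                       confidence = "high")
  out <- apply_region_removal(rec, sp)
  expect_equal(nchar(out$residues), 156)      # residues 53..208
  expect_equal(out$parent_start, 53L)
  expect_equal(out$trim_log$end, 52L)

  # medium-confidence SP is not removed; medium TM is
  expect_equal(nchar(apply_region_removal(rec,
    tibble::tibble(kind = "signal_peptide", start = 1L, end = 52L,
                   confidence = "medium"))$residues), 208)
  expect_lt(nchar(apply_region_removal(rec,
    tibble::tibble(kind = "transmembrane", start = 1L, end = 52L,
                   confidence = "medium"))$residues), 208)

  # internal excision keeps the longest flank, ties toward the C-terminus
  rec100 <- new_sequence_record("q", residues = strrep("A", 100))
  tm <- tibble::tibble(kind = "transmembrane", start = 41L, end = 60L,
                       confidence = "high")
  out <- apply_region_removal(rec100, tm)
  expect_equal(nchar(out$residues), 40)
  expect_equal(out$parent_start, 61L)

  # residue conservation: kept + removed + discarded == input
  kept <- nchar(out$residues)
  removed <- sum(out$trim_log$end - out$trim_log$start + 1)
  discarded <- 40  # the N-terminal flank
  expect_equal(kept + removed + discarded, 100)

  expect_error(apply_region_removal(rec100,
    tibble::tibble(kind = "transmembrane", start = 90L, end = 120L,
                   confidence = "high")), "bounds")

  # no qualifying region: identical record
  expect_identical(apply_region_removal(rec100, rec100$trim_log), rec100)
})

test_that("re-running the cys/length filter after trimming never flips fail to pass", {
  set.seed(9)
  n_checked <- 0
  for (k in 1:20) {
    n <- sample(50:80, 1)
    res <- paste(sample(c("A", "C", "G", "S"), n, replace = TRUE,
                        prob = c(0.5, 0.04, 0.26, 0.2)), collapse = "")
    rec <- new_sequence_record("q", residues = res)
    before <- cys_length_filter(rec)$pass
    e <- sample(10:50, 1)
    trimmed <- apply_region_removal(rec,
      tibble::tibble(kind = "signal_peptide", start = 1L, end = as.integer(e),
                     confidence = "high"))
    after <- cys_length_filter(trimmed)$pass
    expect_false(!before && after)  # fail can never become pass
    if (!before) n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 0)
})
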