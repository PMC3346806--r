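test_that("pair potential is symmetric with a positive unobserved-pair bound", {
  w <- fixture_world()
  pot <- w$potentials
  for (d in c(3, 8, 14)) {
    expect_equal(pot$pair[, , d], t(pot$pair[, , d]))
  }
  # W-W contacts are absent from the toy training set at short range:
  # energy must equal the pseudocount bound for that bin
  counts_bound <- function(total) -log(1 / (total / 210 + 1))
  expect_true(all(pot$pair <= max(counts_bound(1e6)) + 10))  # finite
  expect_true(all(is.finite(pot$pair)))
  expect_true(all(is.finite(pot$burial)))
})

test_that("uniform counts give zero energies, unobserved classes the pseudocount bound", {
  flat <- chemoscan:::counts_to_energy(rep(7, 210), n_classes = 210, pseudocount = 1)
  expect_equal(flat, rep(0, 210), tolerance = 1e-12)
  cts <- c(rep(10, 209), 0)
  e <- chemoscan:::counts_to_energy(cts, n_classes = 210, pseudocount = 1)
  expect_gt(e[210], 0)
  expect_equal(e[210], -log(1 / (sum(cts) / 210 + 1)), tolerance = 1e-12)
})

test_that("potentials serialize losslessly to JSON", {
  w <- fixture_world()
  f <- withr::local_tempfile(fileext = ".json")
  write_potentials(w$potentials, f)
  back <- read_potentials(f)
  expect_equal(back$pair, w$potentials$pair, tolerance = 1e-12)
  expect_equal(back$burial, w$potentials$burial, tolerance = 1e-12)
  expect_equal(back$min_separation, w$potentials$min_separation)
})

test_that("self-alignment covers the whole fold at 100% identity", {
  w <- fixture_world()
  t <- w$set$CKT1
  q <- chemoscan:::native_sequence(t)
  al <- align_sequence_to_structure(q, t, w$potentials)
  expect_equal(al$pl, t$fl)
  expect_equal(al$percent_id, 100)
  expect_equal(nrow(al$gaps), 0)
  expect_equal(percent_identity(al, q, t), 100)
})

test_that("a half-length query cannot reach the fold-coverage band", {
  w <- fixture_world()
  t <- w$set$CKT1
  q <- substr(chemoscan:::native_sequence(t), 1, t$fl %/% 2 - 2)
  al <- align_sequence_to_structure(q, t, w$potentials)
  expect_lte(al$pl, nchar(q))
  expect_gt(al$fl / al$pl, 1.3)
})

test_that("the native sequence outscores its reversal on its own template", {
  w <- fixture_world()
  t <- w$set$CKT1
  q <- chemoscan:::native_sequence(t)
  rev_q <- paste(rev(chemoscan:::aa_chars(q)), collapse = "")
  al_nat <- align_sequence_to_structure(q, t, w$potentials)
  al_rev <- align_sequence_to_structure(rev_q, t, w$potentials)
  expect_gt(al_nat$dp_score, al_rev$dp_score)
  expect_gt(-(al_nat$raw_pair_energy + al_nat$raw_burial_energy),
            -(al_rev$raw_pair_energy + al_rev$raw_burial_energy))
})

test_that("pl never exceeds query length or fold length", {
  w <- fixture_world()
  set.seed(31)
  for (k in 1:10) {
    len <- sample(12:90, 1)
    q <- paste(sample(chemoscan:::AA20, len, replace = TRUE), collapse = "")
    t <- w$set[[sample(length(w$set), 1)]]
    al <- align_sequence_to_structure(q, t, w$potentials)
    expect_lte(al$pl, min(len, t$fl))
  }
})

test_that("z-scores are reproducible under a fixed seed and positive for native", {
  w <- fixture_world()
  t <- w$set$CKT2
  q <- chemoscan:::native_sequence(t)
  a1 <- zscores(q, t, w$potentials, n_shuffles = 40, seed = 5)
  a2 <- zscores(q, t, w$potentials, n_shuffles = 40, seed = 5)
  expect_equal(a1$z_pair, a2$z_pair)
  expect_equal(a1$z_surf, a2$z_surf)
  expect_gt(a1$z_pair, 0)
  expect_false(a1$z_degenerate)
  expect_error(zscores(q, t, w$potentials, seed = NULL), "seed")
})

test_that("degenerate constant-energy potentials yield z = 0 with a flag", {
  w <- fixture_world()
  pot <- w$potentials
  pot$pair[] <- 0
  pot$burial[] <- 0
  t <- w$set$CKT1
  al <- zscores(chemoscan:::native_sequence(t), t, pot, n_shuffles = 20, seed = 1)
  expect_equal(al$z_pair, 0)
  expect_equal(al$z_surf, 0)
  expect_true(al$z_degenerate)
})

test_that("Thx is linear in its weights and zero for zero inputs", {
  al <- structure(list(z_pair = 0, z_surf = 0, seq_similarity = 0, thx = NA),
                  class = "threading_alignment")
  expect_equal(compute_thx(al, 70)$thx, 0)
  al$z_pair <- 1.5; al$z_surf <- 0.5; al$seq_similarity <- 20
  t1 <- compute_thx(al, 70)$thx
  t2 <- compute_thx(al, 70, w_pair = 2, w_surf = 2, w_seq = 2)$thx
  expect_equal(t2, 2 * t1)
  expect_equal(compute_thx(al, 35)$thx, 2 * t1)  # halving length doubles Thx
  expect_error(compute_thx(al, 0), "positive")
})

test_that("percent identity counts identical aligned pairs", {
  w <- fixture_world()
  t <- w$set$CKT1
  q <- chemoscan:::native_sequence(t)
  qaa <- chemoscan:::aa_chars(q)
  # toy 10-pair alignment with exactly 3 matches
  al <- list(pairs = tibble::tibble(qpos = 1:10, tpos = 1:10), pl = 10)
  mism <- qaa
  keep <- c(2, 5, 9)
  for (i in setdiff(1:10, keep)) mism[i] <- setdiff(chemoscan:::AA20, mism[i])[1]
  expect_equal(percent_identity(al, paste(mism, collapse = ""), t), 30)
  none <- qaa
  for (i in 1:10) none[i] <- setdiff(chemoscan:::AA20, none[i])[1]
  expect_equal(percent_identity(al, paste(none, collapse = ""), t), 0)
  expect_error(percent_identity(list(pairs = NULL, pl = 0), q, t), "pl = 0")
})

test_that("template ranking is 1-based, Thx-sorted and order-invariant", {
  w <- fixture_world()
  q <- chemoscan:::native_sequence(w$set$CKT3)
  hits <- rank_templates(q, w$chemokine, w$potentials, seed = 9, n_shuffles = 40)
  expect_equal(hits$rank, seq_len(nrow(hits)))
  expect_true(all(diff(hits$thx) <= 0))
  expect_equal(hits$template[1], "CKT3_A")

  # reorder the library: same scores, same ranking
  lib2 <- w$chemokine
  lib2$templates <- rev(lib2$templates)
  hits2 <- rank_templates(q, lib2, w$potentials, seed = 9, n_shuffles = 40)
  expect_equal(hits2$thx, hits$thx)
  expect_equal(hits2$template, hits$template)

  single <- w$chemokine
  single$templates <- single$templates[1]
  h1 <- rank_templates(q, single, w$potentials, seed = 9, n_shuffles = 10)
  expect_equal(h1$rank, 1L)
})

test_that("cutoff calibration returns the designated homolog's best HC Thx", {
  w <- fixture_world()
  cal <- make_homolog(w$set$CKT2, 25, seed = 999)
  cut <- calibrate_thx_cutoff(cal, w$chemokine, w$potentials, seed = 11,
                              n_shuffles = 40)
  expect_true(is.numeric(cut) && length(cut) == 1 && is.finite(cut))
  hits <- rank_templates(cal, w$chemokine, w$potentials, seed = 11,
                         n_shuffles = 40)
  expect_true(cut %in% hits$thx)
})
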