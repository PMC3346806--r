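fake_alignment <- function(fl, pl, gaps = NULL, tpos = NULL) {
  structure(list(
    pairs = tibble::tibble(qpos = seq_len(pl), tpos = tpos %||% seq_len(pl)),
    pl = pl, fl = fl,
    gaps = gaps %||% tibble::tibble(side = character(), start = integer(),
                                    length = integer())
  ), class = "threading_alignment")
}

bare_template <- function(n, sse = rep("C", n)) {
  ca <- cbind(3.8 * seq_len(n), 0, 0)
  new_template_structure("TPL", "A", rep("A", n), ca, ca + 1, sse = sse)
}

test_that("hit classification applies the coverage, gap and SSE rules inclusively", {
  t <- bare_template(400)
  # fold-coverage band boundaries are HC-eligible
  expect_equal(classify_hit(fake_alignment(69, 62), t)$confidence, "HC")
  expect_true(classify_hit(fake_alignment(60, 100), t)$fcov_ok)   # 0.6 exactly
  expect_true(classify_hit(fake_alignment(130, 100), t)$fcov_ok)  # 1.3 exactly
  expect_false(classify_hit(fake_alignment(59, 100), t)$fcov_ok)
  expect_false(classify_hit(fake_alignment(131, 100), t)$fcov_ok)
  # a 348-residue fold with an 81-residue path is a false positive
  r <- classify_hit(fake_alignment(348, 81), t)
  expect_false(r$fcov_ok); expect_equal(r$confidence, "FP")

  gap10 <- tibble::tibble(side = "query", start = 5L, length = 10L)
  gap11 <- tibble::tibble(side = "query", start = 5L, length = 11L)
  expect_equal(classify_hit(fake_alignment(69, 62, gaps = gap10), t)$confidence, "HC")
  r <- classify_hit(fake_alignment(69, 62, gaps = gap11), t)
  expect_false(r$gap_ok); expect_equal(r$confidence, "FP")
  expect_error(classify_hit(fake_alignment(69, 0), t), "pl = 0")
})

test_that("SSE coverage tolerates one unaligned position per element edge", {
  sse <- c(rep("C", 5), rep("H", 10), rep("C", 55))
  t <- bare_template(70, sse = sse)
  covered <- fake_alignment(70, 70)
  expect_true(classify_hit(covered, t)$sse_covered)
  # drop one residue at the helix edge: still covered
  edge <- fake_alignment(70, 69, tpos = setdiff(1:70, 6))
  expect_true(classify_hit(edge, t)$sse_covered)
  # drop a residue in the helix core: not covered
  core <- fake_alignment(70, 69, tpos = setdiff(1:70, 10))
  expect_false(classify_hit(core, t)$sse_covered)
  expect_equal(classify_hit(core, t)$confidence, "FP")
})

test_that("top-n selection is deterministic with id tie-breaks", {
  sc <- tibble::tibble(query_id = c("b", "a", "c", "d"),
                       best_thx = c(10, 10, 30, 5))
  top <- take_top(sc, n = 2)
  expect_equal(top$query_id, c("c", "a"))
  expect_equal(nrow(take_top(sc, n = 10)), 4)
  expect_error(take_top(sc, n = 0), "positive")
})

test_that("SCOP domain ranking applies coverage and chemokine-rank rules", {
  dom <- function(family, thx, conf, cov) {
    tibble::tibble(family = family, thx = thx, z_pair = 0,
                   confidence = conf, pct_cov = cov, template = family)
  }
  # coverage boundary: 70 kept, 69.9 dropped
  d <- dplyr::bind_rows(dom("d.9.1.1", 50, "HC", 70),
                        dom("a.24.1.1", 40, "HC", 69.9))
  r <- rank_scop_domains(d)
  expect_equal(nrow(r$domains), 1)
  expect_true(r$pass); expect_equal(r$ck_rank, 1L)

  # chemokine at HC rank 2 passes, rank 3 fails
  d <- dplyr::bind_rows(dom("a.24.1.1", 90, "HC", 100),
                        dom("d.9.1.1", 80, "HC", 100),
                        dom("b.1.1.1", 70, "HC", 100))
  expect_true(rank_scop_domains(d)$pass)
  expect_equal(rank_scop_domains(d)$ck_rank, 2L)
  d <- dplyr::bind_rows(dom("a.24.1.1", 90, "HC", 100),
                        dom("b.1.1.1", 85, "HC", 100),
                        dom("d.9.1.1", 80, "HC", 100),
                        dom("c.2.1.1", 70, "HC", 100))
  r <- rank_scop_domains(d)
  expect_false(r$pass); expect_equal(r$ck_rank, 3L)

  # FP entries do not consume high-confidence ranks
  d <- dplyr::bind_rows(dom("a.24.1.1", 90, "FP", 100),
                        dom("b.1.1.1", 85, "FP", 100),
                        dom("d.9.1.1", 80, "HC", 100))
  expect_equal(rank_scop_domains(d)$ck_rank, 1L)

  # best-per-family collapse before ranking
  d <- dplyr::bind_rows(dom("d.9.1.1", 60, "HC", 100),
                        dom("d.9.1.1", 95, "FP", 100),
                        dom("a.24.1.1", 90, "HC", 100))
  r <- rank_scop_domains(d)
  expect_false(r$pass)  # the best d.9 entry is the FP one
  expect_equal(rank_scop_domains(d, top_domains = 1)$reason, "no_hc_hit")

  r <- rank_scop_domains(d[0, ])
  expect_false(r$pass); expect_equal(r$reason, "no_scop_domains")
})

test_that("chemokine profile screen couples the Thx cutoff with the disulfide scaffold", {
  w <- fixture_world()
  hom <- make_homolog(w$set$CKT1, 45, seed = 321)
  scr <- chemokine_profile_screen(hom, w$chemokine, w$potentials,
                                  thx_cutoff = 150, seed = 4, n_shuffles = 40)
  expect_true(scr$pass)
  expect_gte(scr$dismap$bond_count, 1)
  expect_true(all(scr$dis_range >= 0))

  # an impossible cutoff fails with the cutoff reason
  scr2 <- chemokine_profile_screen(hom, w$chemokine, w$potentials,
                                   thx_cutoff = 1e6, seed = 4, n_shuffles = 40)
  expect_false(scr2$pass)
  expect_equal(scr2$reason, "below_thx_cutoff")

  # a cysteine-free query cannot offer a disulfide scaffold
  nocys <- gsub("C", "A", hom)
  scr3 <- chemokine_profile_screen(nocys, w$chemokine, w$potentials,
                                   thx_cutoff = -1e6, seed = 4, n_shuffles = 40)
  expect_false(scr3$pass)
  expect_equal(scr3$reason, "no_disulfide_scaffold")
})

test_that("fold-space screen recovers homologs and is order-invariant", {
  w <- fixture_world()
  hom <- make_homolog(w$set$CKT2, 40, seed = 654)
  r <- foldspace_screen(hom, w$foldspace, w$potentials, seed = 6, n_shuffles = 40)
  expect_true(r$pass)
  expect_lte(r$ck_rank, 2L)

  lib2 <- w$foldspace
  lib2$templates <- rev(lib2$templates)
  r2 <- foldspace_screen(hom, lib2, w$potentials, seed = 6, n_shuffles = 40)
  expect_equal(r2$pass, r$pass)
  expect_equal(r2$ck_rank, r$ck_rank)
})
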