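bio3d_example <- system.file("examples", "1hel.pdb", package = "bio3d")

test_that("virtual C-beta reconstruction is exact for ideal tetrahedral geometry", {
  # independent oracle: place CB by solving the internal-coordinate system
  # (bond 1.53 A, angles N-CA-CB 110.5 deg, C-CA-CB 110.1 deg) directly
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  cc <- ca + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  u1 <- (n - ca) / sqrt(sum((n - ca)^2))
  u2 <- (cc - ca) / sqrt(sum((cc - ca)^2))
  c1 <- cos(110.5 * pi / 180); c2 <- cos(110.1 * pi / 180)
  d12 <- sum(u1 * u2)
  x <- (c1 - c2 * d12) / (1 - d12^2)
  y <- (c2 - c1 * d12) / (1 - d12^2)
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  u3 <- u3 / sqrt(sum(u3^2))
  z2 <- 1 - x^2 - y^2 - 2 * x * y * d12
  cb_oracle <- ca + 1.53 * (x * u1 + y * u2 + sqrt(z2) * u3)
  got <- virtual_cb(n, ca, cc)
  # the two chiral placements: reconstruction must match one branch closely
  cb_oracle2 <- ca + 1.53 * (x * u1 + y * u2 - sqrt(z2) * u3)
  err <- min(sqrt(sum((got - cb_oracle)^2)), sqrt(sum((got - cb_oracle2)^2)))
  expect_lt(err, 0.05)
  expect_equal(sqrt(sum((got - ca)^2)), 1.53, tolerance = 1e-9)
})

test_that("virtual C-beta reconstruction tracks observed C-beta atoms on a real chain", {
  expect_true(nzchar(bio3d_example))
  pdb <- bio3d::read.pdb(bio3d_example, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  errs <- c()
  for (rn in unique(at$resno)) {
    ri <- at[at$resno == rn, ]
    get <- function(a) {
      r <- ri[ri$elety == a, ][1, ]
      if (is.na(r$x)) NULL else c(r$x, r$y, r$z)
    }
    n <- get("N"); ca <- get("CA"); cc <- get("C"); cb <- get("CB")
    if (is.null(n) || is.null(ca) || is.null(cc) || is.null(cb)) next
    errs <- c(errs, sqrt(sum((virtual_cb(n, ca, cc) - cb)^2)))
  }
  expect_gt(length(errs), 50)
  # real side chains deviate from ideal geometry; the bulk must stay tight
  expect_lt(median(errs), 0.2)
  expect_lt(mean(errs), 0.15)
  expect_gt(mean(errs < 0.2), 0.8)
})

test_that("PDB chain parsing round-trips toy templates and flags errors", {
  w <- fixture_world()
  t <- w$set$CKT1
  f <- withr::local_tempfile(fileext = ".pdb")
  write_template_pdb(t, f)
  back <- parse_structure_chain(f, "A")
  expect_equal(back$aa, t$aa)
  expect_equal(back$fl, t$fl)
  expect_lt(max(abs(back$ca - t$ca)), 1e-3)
  expect_lt(max(abs(back$cb - t$cb)), 1e-3)
  expect_error(parse_structure_chain(f, "Z"), "available chains")
})

test_that("missing C-beta atoms are reconstructed and flagged virtual", {
  expect_true(nzchar(bio3d_example))
  t <- parse_structure_chain(bio3d_example, "A")
  gly <- which(t$aa == "G" & t$resolved)
  expect_gt(length(gly), 0)
  expect_true(all(t$cb_virtual[gly]))
  expect_false(any(is.na(t$cb[t$resolved, ])))
  # reconstructed glycine C-beta sits a bond length from C-alpha
  d <- sqrt(rowSums((t$cb[gly, , drop = FALSE] - t$ca[gly, , drop = FALSE])^2))
  expect_equal(d, rep(1.53, length(gly)), tolerance = 1e-6)
})

ideal_helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  k <- seq_len(n) - 1
  cbind(rise * k, radius * cos(k * twist * pi / 180),
        radius * sin(k * twist * pi / 180))
}

test_that("secondary structure assignment labels ideal geometries correctly", {
  n <- 14
  ca <- ideal_helix_ca(n)
  t <- new_template_structure("HLX", "A", rep("A", n), ca, ca + 1.53 / sqrt(3))
  t <- assign_sse(t)
  expect_true(all(t$sse[3:(n - 4)] == "H"))

  # fully extended single chain: extension without a partner is coil, not E
  ca <- cbind(3.3 * (0:19), 0, 0.8 * ((0:19) %% 2))
  t <- assign_sse(new_template_structure("EXT", "A", rep("A", 20), ca, ca + 1))
  expect_false(any(t$sse == "E"))

  # two paired extended chains: now strands appear
  ca2 <- rbind(ca[1:9, ],
               cbind(3.3 * (8:0), 4.8, 0.8 * ((8:0) %% 2)))
  t2 <- assign_sse(new_template_structure("SHT", "A", rep("A", 18), ca2, ca2 + 1))
  expect_true(any(t2$sse == "E"))

  # fewer than 5 resolved residues: all coil
  ca <- ideal_helix_ca(4)
  t <- assign_sse(new_template_structure("TINY", "A", rep("A", 4), ca, ca + 1))
  expect_true(all(t$sse == "C"))
})

test_that("external SSE labels override the built-in assignment", {
  w <- fixture_world()
  t <- w$set$CKT1
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%d\tH", 1:10), f)
  t2 <- assign_sse(t, labels_file = f)
  expect_true(all(t2$sse[1:10] == "H"))
  expect_true(all(t2$sse[11:length(t2$sse)] == "C"))
})

test_that("chemokine library keeps d.9 templates only", {
  w <- fixture_world()
  lib <- w$chemokine
  expect_equal(length(lib$templates), 5)
  expect_true(all(vapply(lib$templates, function(t)
    any(grepl("^d\\.9\\.", t$scop$family)), logical(1))))

  # explicit mapping: d.9.1.1 in, g.3.7.2 out, unmapped warned
  ts <- w$set[c("CKT1", "HBD1", "LHX1")]
  scop <- tibble::tibble(pdb_id = c("CKT1", "HBD1"), chain = "A",
                         family = c("d.9.1.1", "g.3.7.2"),
                         start = 1L, end = 40L)
  expect_warning(lib2 <- build_chemokine_library(ts, scop), "without SCOP")
  expect_equal(vapply(lib2$templates, function(t) t$pdb_id, character(1)),
               "CKT1", ignore_attr = TRUE)

  expect_warning(lib3 <- build_chemokine_library(ts, scop[0, ]), "without SCOP")
  expect_length(lib3$templates, 0)
})

test_that("fold-space redundancy filter is greedy, deterministic and order-invariant", {
  w <- fixture_world()
  a <- w$set$CKT1
  b <- a; b$pdb_id <- "COPY"           # identical chain under another id
  c <- w$set$HBD1                      # unrelated fold
  lib <- build_foldspace_library(list(a, b, c))
  expect_equal(length(lib$templates), 2)

  ids <- function(l) sort(vapply(l$templates, chemoscan:::template_name, character(1)))
  lib_shuffled <- build_foldspace_library(list(c, b, a))
  expect_equal(ids(lib), ids(lib_shuffled))

  lib2 <- build_foldspace_library(list(a, c))
  expect_equal(length(lib2$templates), 2)
})

test_that("SCOP domain coverage is the aligned fraction of the domain", {
  al <- list(pairs = tibble::tibble(qpos = 1:69, tpos = 1:69))
  expect_equal(scop_domain_coverage(al, c(1, 69)), 100)
  al62 <- list(pairs = tibble::tibble(qpos = 1:62, tpos = 1:62))
  expect_equal(scop_domain_coverage(al62, c(1, 69)), 100 * 62 / 69, tolerance = 1e-9)
  al0 <- list(pairs = tibble::tibble(qpos = integer(), tpos = integer()))
  expect_equal(scop_domain_coverage(al0, c(1, 69)), 0)
  expect_error(scop_domain_coverage(al, c(5, 4)), "domain")
})
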