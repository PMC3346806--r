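AA_BACKGROUND <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 0,
                   E = 6.75, Q = 3.93, G = 7.07, H = 2.27, I = 5.96,
                   K = 5.84, L = 9.66, M = 2.42, F = 3.86, P = 4.70,
                   S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)

#' Specify a toy template fixture
#'
#' @param seed integer seed controlling jitter and sequence sampling.
#' @param sse_layout list of c(type, length) pairs, e.g.
#'   `list(c("C", 4), c("E", 6), ...)`; types H/E/C.
#' @param planted_disulfides data frame with columns i, j (template
#'   positions) and logical columns dist_ok, orient_ok giving the intended
#'   verdict of the distance and orientation criteria for that pair (the
#'   separation criterion follows from i and j).
#' @param pdb_id,chain_id identifiers for the emitted template.
#' @param scop_family SCOP family id attached to the full span.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed, sse_layout, planted_disulfides = NULL,
                         pdb_id = "TOY1", chain_id = "A",
                         scop_family = "d.9.1.1") {
  n <- sum(vapply(sse_layout, function(e) as.integer(e[2]), integer(1)))
  if (!is.null(planted_disulfides)) {
    stopifnot(all(planted_disulfides$i >= 1), all(planted_disulfides$j <= n))
  }
  structure(list(seed = as.integer(seed), sse_layout = sse_layout,
                 planted_disulfides = planted_disulfides,
                 pdb_id = pdb_id, chain_id = chain_id,
                 scop_family = scop_family, n_residues = n),
            class = "fixture_spec")
}

# idealized coordinates for one SSE element
element_coords <- function(type, len, origin, direction_sign) {
  ca <- matrix(0, len, 3)
  if (type == "H") {
    # alpha helix: 1.5 A rise, 100 degrees per residue, 2.3 A radius
    for (k in seq_len(len)) {
      ang <- (k - 1) * 100 * pi / 180
      ca[k, ] <- origin + c(direction_sign * 1.5 * (k - 1),
                            2.3 * cos(ang), 2.3 * sin(ang))
    }
  } else {  # strand: 3.3 A rise with alternating 0.8 A pleat
    for (k in seq_len(len)) {
      ca[k, ] <- origin + c(direction_sign * 3.3 * (k - 1), 0,
                            0.8 * (k %% 2))
    }
  }
  ca
}

#' Build a toy template structure from a fixture spec
#'
#' Backbone C-alpha traces are idealized secondary structure elements
#' (strands laid as an antiparallel meander, helices packed against the
#' sheet) connected by interpolated loops; C-beta atoms point away from the
#' local chain axis. Planted cysteine pairs get their C-beta orientations
#' carved to satisfy exactly the intended subset of the disulfide criteria,
#' and the realized geometry is re-checked against the criteria before the
#' template is returned (build error on any mismatch). Deterministic for a
#' given spec and seed.
#'
#' @param spec a [fixture_spec()].
#' @return a `template_structure` with SSE labels as laid out.
#' @export
make_toy_template <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_residues
  ca <- matrix(NA_real_, n, 3)
  sse <- rep("C", n)
  # position elements: strands meander in y, helices sit below the sheet
  strand_i <- 0; helix_i <- 0
  pos <- 1
  elements <- list()
  for (e in spec$sse_layout) {
    type <- e[1]; len <- as.integer(e[2])
    idx <- seq(pos, length.out = len)
    if (type == "E") {
      dirn <- if (strand_i %% 2 == 0) 1 else -1
      org <- c(if (dirn == 1) 0 else 3.3 * (len - 1), strand_i * 4.8, 0)
      ca[idx, ] <- element_coords("E", len, org, dirn)
      sse[idx] <- "E"
      strand_i <- strand_i + 1
      elements[[length(elements) + 1]] <- idx
    } else if (type == "H") {
      dirn <- if (helix_i %% 2 == 0) 1 else -1
      org <- c(if (dirn == 1) -2 else 1.5 * (len - 1) - 2,
               -6 - helix_i * 10, 4.5)
      ca[idx, ] <- element_coords("H", len, org, dirn)
      sse[idx] <- "H"
      helix_i <- helix_i + 1
      elements[[length(elements) + 1]] <- idx
    }
    pos <- pos + len
  }
  # fill coils by interpolation between flanking element endpoints
  filled <- !is.na(ca[, 1])
  runs <- rle(filled)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (k in which(!runs$values)) {
    s <- starts[k]; e <- ends[k]; L <- e - s + 1L
    P <- if (s > 1) ca[s - 1, ] else NULL
    Q <- if (e < n) ca[e + 1, ] else NULL
    if (is.null(P)) {  # N-terminal tail: extend backwards from first element
      d <- ca[e + 1, ] - ca[e + 2, ]
      d <- d / sqrt(sum(d^2))
      for (t in seq_len(L)) ca[e + 1 - t, ] <- ca[e + 1, ] + t * 3.5 * d + c(0, 0, 1.2 * (t %% 2))
    } else if (is.null(Q)) {  # C-terminal tail
      d <- ca[s - 1, ] - ca[s - 2, ]
      d <- d / sqrt(sum(d^2))
      for (t in seq_len(L)) ca[s - 1 + t, ] <- ca[s - 1, ] + t * 3.5 * d + c(0, 0, 1.2 * (t %% 2))
    } else {
      v <- Q - P
      nv <- sqrt(sum(v^2))
      perp <- c(-v[2], v[1], 0)
      if (sqrt(sum(perp^2)) < 1e-6) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      bump <- max(2.5, (3.5 * (L + 1) - nv) / 2)
      for (t in seq_len(L)) {
        f <- t / (L + 1)
        ca[s - 1 + t, ] <- P + f * v + bump * sin(pi * f) * perp + c(0, 0, 0.6 * (t %% 2))
      }
    }
  }
  ca <- ca + matrix(runif(3 * n, -0.12, 0.12), n, 3)  # seeded jitter

  # default C-beta: away from the local chain direction
  cb <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- if (i > 1) ca[i - 1, ] else ca[i, ]
    b <- if (i < n) ca[i + 1, ] else ca[i, ]
    v <- b - a
    u <- c(v[2], -v[1], 0.5)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) u <- c(0, 0, 1) else u <- u / nu
    if (sse[i] == "E") u <- u * (if (i %% 2 == 0) 1 else -1)
    cb[i, ] <- ca[i, ] + 1.53 * u
  }

  # sequence: background-sampled, cysteines only at planted positions
  aa <- sample(names(AA_BACKGROUND), n, replace = TRUE,
               prob = AA_BACKGROUND / sum(AA_BACKGROUND))
  pd <- spec$planted_disulfides
  if (!is.null(pd) && nrow(pd) > 0) {
    cys_pos <- unique(c(pd$i, pd$j))
    aa[cys_pos] <- "C"
    for (k in seq_len(nrow(pd))) {
      i <- pd$i[k]; j <- pd$j[k]
      d_ca <- pt_dist(ca[i, ], ca[j, ])
      u_ij <- (ca[j, ] - ca[i, ]) / d_ca
      want_dist <- isTRUE(pd$dist_ok[k]); want_orient <- isTRUE(pd$orient_ok[k])
      if (want_dist && want_orient) {
        if (d_ca > 10) stop_scan("pair (%d,%d): d_ca %.1f > 10, distance pass unrealizable", i, j, d_ca)
        cb[i, ] <- ca[i, ] + 1.53 * u_ij
        cb[j, ] <- ca[j, ] - 1.53 * u_ij
      } else if (want_dist && !want_orient) {
        # point apart: d_cb = d_ca + 3.06; distance still passes iff d_cb <= 9
        if (d_ca + 3.06 > 9) stop_scan("pair (%d,%d): d_ca %.1f too large for orientation-only failure", i, j, d_ca)
        cb[i, ] <- ca[i, ] - 1.53 * u_ij
        cb[j, ] <- ca[j, ] + 1.53 * u_ij
      } else if (!want_dist && want_orient) {
        if (d_ca <= 10) stop_scan("pair (%d,%d): d_ca %.1f <= 10, distance failure with good orientation unrealizable here", i, j, d_ca)
        cb[i, ] <- ca[i, ] + 1.53 * u_ij
        cb[j, ] <- ca[j, ] - 1.53 * u_ij
      } else {
        cb[i, ] <- ca[i, ] - 1.53 * u_ij
        cb[j, ] <- ca[j, ] + 1.53 * u_ij
        if (d_ca + 3.06 <= 9) stop_scan("pair (%d,%d): d_ca %.1f too small to fail the distance criterion", i, j, d_ca)
      }
    }
  }

  t <- new_template_structure(spec$pdb_id, spec$chain_id, aa, ca, cb,
                              sse = sse,
                              scop = tibble(family = spec$scop_family,
                                            start = 1L, end = as.integer(n)))

  # build-time oracle: recompute the criteria directly and compare
  if (!is.null(pd) && nrow(pd) > 0) {
    for (k in seq_len(nrow(pd))) {
      i <- pd$i[k]; j <- pd$j[k]
      d_ca <- pt_dist(ca[i, ], ca[j, ]); d_cb <- pt_dist(cb[i, ], cb[j, ])
      got_dist <- d_ca <= 10 && d_cb <= 9
      got_orient <- (d_cb - d_ca) <= 1
      if (got_dist != isTRUE(pd$dist_ok[k]) || got_orient != isTRUE(pd$orient_ok[k]))
        stop_scan("pair (%d,%d): realized geometry contradicts the intended verdicts", i, j)
    }
  }
  t
}

#' The standard chemokine-like toy layout
#'
#' Three antiparallel strands packed against a C-terminal helix with three
#' all-criteria-compatible cysteine pairs planted across the fold, the
#' topology the IL8-like fold descriptor screens for.
#'
#' @param seed integer seed.
#' @param pdb_id,chain_id identifiers.
#' @return a [fixture_spec()].
#' @export
chemokine_fixture_spec <- function(seed, pdb_id = "CKT1", chain_id = "A") {
  # 70 residues, 6 cysteines: the size of a mature chemokine domain
  layout <- list(c("C", 8), c("E", 8), c("C", 4), c("E", 8), c("C", 5),
                 c("E", 8), c("C", 5), c("H", 15), c("C", 9))
  # strand 1: 9..16, strand 2: 21..28, strand 3: 34..41, helix: 47..61;
  # pairs span N-tail/helix, strand1/helix and strand2/strand3 contacts
  planted <- tibble(i = c(8L, 13L, 24L), j = c(47L, 57L, 38L),
                    dist_ok = TRUE, orient_ok = TRUE)
  fixture_spec(seed, layout, planted, pdb_id = pdb_id, chain_id = chain_id,
               scop_family = "d.9.1.1")
}

#' A small library of geometrically distinct toy folds
#'
#' Five chemokine-like templates (jitter and sequence variants) plus four
#' non-chemokine folds (helix bundle, beta meander, long helix, alpha/beta
#' mix), each carrying a SCOP family id; the raw material for the chemokine
#' descriptor library and the fold-space control library.
#'
#' @param seed integer seed.
#' @return named list of `template_structure`.
#' @export
make_fixture_fold_set <- function(seed) {
  sets <- list()
  for (k in 1:5) {
    sp <- chemokine_fixture_spec(seed + k, pdb_id = sprintf("CKT%d", k))
    sets[[sp$pdb_id]] <- make_toy_template(sp)
  }
  bundle <- fixture_spec(seed + 11,
                         list(c("C", 3), c("H", 12), c("C", 4), c("H", 12),
                              c("C", 4), c("H", 12), c("C", 3)),
                         pdb_id = "HBD1", scop_family = "a.24.1.1")
  sets$HBD1 <- make_toy_template(bundle)
  meander <- fixture_spec(seed + 12,
                          list(c("C", 3), c("E", 7), c("C", 3), c("E", 7),
                               c("C", 3), c("E", 7), c("C", 3), c("E", 7),
                               c("C", 3)),
                          pdb_id = "BMD1", scop_family = "b.1.1.1")
  sets$BMD1 <- make_toy_template(meander)
  longhx <- fixture_spec(seed + 13, list(c("C", 3), c("H", 30), c("C", 3)),
                         pdb_id = "LHX1", scop_family = "a.1.1.1")
  sets$LHX1 <- make_toy_template(longhx)
  abmix <- fixture_spec(seed + 14,
                        list(c("C", 3), c("E", 6), c("C", 3), c("H", 10),
                             c("C", 3), c("E", 6), c("C", 3), c("H", 10),
                             c("C", 3)),
                        pdb_id = "ABM1", scop_family = "c.2.1.1")
  sets$ABM1 <- make_toy_template(abmix)
  sets
}

#' Mutate a template's native sequence to a target identity
#'
#' Non-cysteine positions are substituted (substitution-matrix-weighted
#' sampling, never to the same residue, never to cysteine when cysteines are
#' preserved) until the realized identity is within 2 points of the target.
#'
#' @param template a `template_structure`.
#' @param target_identity percent identity in (0, 100].
#' @param preserve_cys keep cysteine positions untouched (default TRUE).
#' @param seed integer seed.
#' @return character residue string.
#' @export
make_homolog <- function(template, target_identity, preserve_cys = TRUE,
                         seed) {
  if (target_identity <= 0 || target_identity > 100)
    stop_scan("target_identity must be in (0, 100]")
  set.seed(seed)
  aa <- template$aa[template$resolved]
  n <- length(aa)
  n_mut <- round((1 - target_identity / 100) * n)
  mutable <- if (preserve_cys) which(aa != "C") else seq_len(n)
  if (n_mut > length(mutable))
    stop_scan("target identity %.0f%% unreachable with %d preserved cysteines",
              target_identity, sum(aa == "C"))
  if (n_mut > 0) {
    sites <- sample(mutable, n_mut)
    B <- substitution_matrix()
    targets <- if (preserve_cys) setdiff(AA20, "C") else AA20
    for (s in sites) {
      opts <- setdiff(targets, aa[s])
      w <- exp(B[aa[s], opts] / 2)
      aa[s] <- sample(opts, 1, prob = w / sum(w))
    }
  }
  paste(aa, collapse = "")
}

#' Generate a decoy cohort with companion predictor and hit fixtures
#'
#' Random protein sequences under UniProt-style "hypothetical protein"
#' headers, with seeded fractions of planted signal peptides, transmembrane
#' segments and homology-annotated records, written in exactly the formats
#' the pre-filter consumes. Optional extra sequences (e.g. planted homologs)
#' are appended with clean predictor rows.
#'
#' @param n number of decoys.
#' @param length_range inclusive range of sequence lengths (default 55-120).
#' @param cys_lambda Poisson mean of the cysteine count (default 3).
#' @param sp_fraction,tm_fraction,annotated_fraction planted fractions.
#' @param extra named character vector of extra sequences to append.
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return list of paths (fasta, hits, sp_a, sp_b, tm_a, tm_b) plus a tibble
#'   `truth` of planted features per record.
#' @export
make_decoy_cohort <- function(n, length_range = c(55, 120), cys_lambda = 3,
                              sp_fraction = 0.2, tm_fraction = 0.15,
                              annotated_fraction = 0.2, extra = NULL,
                              dir = tempfile("cohort"), seed) {
  if (n < 1) stop_scan("n must be >= 1")
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("DEC%04d_HUMAN", seq_len(n))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  has_sp <- runif(n) < sp_fraction
  has_tm <- runif(n) < tm_fraction
  annotated <- runif(n) < annotated_fraction
  seqs <- character(n)
  for (k in seq_len(n)) {
    body <- sample(names(AA_BACKGROUND), lens[k], replace = TRUE,
                   prob = AA_BACKGROUND / sum(AA_BACKGROUND))
    ncys <- min(stats::rpois(1, cys_lambda), lens[k] %/% 4)
    if (ncys > 0) body[sample(lens[k], ncys)] <- "C"
    if (has_sp[k]) {
      # hydrophobic leader so the trim is meaningful
      body[1:18] <- sample(c("L", "A", "V", "F", "I"), 18, replace = TRUE)
    }
    seqs[k] <- paste(body, collapse = "")
  }
  fasta <- file.path(dir, "cohort.fasta")
  accs <- sub("_HUMAN$", "", ids)
  lines <- unlist(lapply(seq_len(n), function(k)
    c(sprintf(">tr|%s|%s hypothetical protein", accs[k], ids[k]), seqs[k])))
  extra_ids <- if (is.null(extra)) character() else paste0(names(extra), "_HUMAN")
  if (!is.null(extra)) {
    lines <- c(lines, unlist(lapply(seq_along(extra), function(k)
      c(sprintf(">tr|%s|%s hypothetical protein", names(extra)[k], extra_ids[k]),
        extra[[k]]))))
  }
  writeLines(lines, fasta)
  sp_row <- function(id, planted, jitter) {
    pos <- if (planted) 20L + jitter else 0L
    sprintf("%s\t%d\t%.2f", id, pos, if (planted) 0.9 else 0.1)
  }
  sp_a <- file.path(dir, "sp_a.tsv"); sp_b <- file.path(dir, "sp_b.tsv")
  writeLines(c(vapply(seq_len(n), function(k) sp_row(ids[k], has_sp[k], 0L), character(1)),
               vapply(extra_ids, function(nm) sp_row(nm, FALSE, 0L), character(1))),
             sp_a)
  writeLines(c(vapply(seq_len(n), function(k) sp_row(ids[k], has_sp[k], 1L), character(1)),
               vapply(extra_ids, function(nm) sp_row(nm, FALSE, 1L), character(1))),
             sp_b)
  tm_row <- function(id, planted, shift) {
    if (planted) sprintf("%s\t%d-%d\t0.9", id, 30L + shift, 50L + shift)
    else sprintf("%s\t-\t0.1", id)
  }
  tm_a <- file.path(dir, "tm_a.tsv"); tm_b <- file.path(dir, "tm_b.tsv")
  writeLines(c(vapply(seq_len(n), function(k) tm_row(ids[k], has_tm[k] & lens[k] >= 55, 0L), character(1)),
               vapply(extra_ids, function(nm) tm_row(nm, FALSE, 0L), character(1))),
             tm_a)
  writeLines(c(vapply(seq_len(n), function(k) tm_row(ids[k], has_tm[k] & lens[k] >= 55, 1L), character(1)),
               vapply(extra_ids, function(nm) tm_row(nm, FALSE, 1L), character(1))),
             tm_b)
  hits <- file.path(dir, "hits.tsv")
  hit_lines <- vapply(which(annotated), function(k) {
    sprintf("%s\tPDB|1XYZ|A\t%.1f\t%d\t10\t1\t1\t%d\t1\t%d\t%.1e\t120.0",
            ids[k], 45 + runif(1, 0, 30), 80L, 80L, 80L, 1e-20)
  }, character(1))
  writeLines(hit_lines, hits)

  list(fasta = fasta, hits = hits, sp_a = sp_a, sp_b = sp_b,
       tm_a = tm_a, tm_b = tm_b, dir = dir,
       truth = tibble(id = ids, length = lens, has_sp = has_sp,
                      has_tm = has_tm, annotated = annotated))
}
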