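.chemoscan_env <- new.env(parent = emptyenv())

#' The substitution matrix used for sequence-similarity scoring
#'
#' BLOSUM62 from Biostrings by default; any 20x20 (or larger) log-odds matrix
#' with one-letter row/column names can be supplied to the scoring functions.
#'
#' @return numeric matrix.
#' @export
substitution_matrix <- function() {
  if (is.null(.chemoscan_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .chemoscan_env$blosum62 <- e$BLOSUM62
  }
  .chemoscan_env$blosum62
}

subst_score <- function(a, b, mat) {
  ok <- a %in% rownames(mat) & b %in% colnames(mat)
  s <- numeric(length(a))
  if (any(ok)) s[ok] <- mat[cbind(a[ok], b[ok])]
  sum(s)
}

# deterministic per-template seed derived from run seed and template name,
# so that scores are invariant to library ordering
template_seed <- function(seed, tname) {
  h <- sum(utf8ToInt(tname) * (seq_along(utf8ToInt(tname)) * 31)) %% 1000003L
  (as.integer(seed) %% 1000003L) * 1009L %% 2147483629L + h
}

#' Align a query sequence onto a template structure
#'
#' Frozen-approximation threading: template position j scores residue a by
#' its burial energy plus the sum of pair energies against the template's
#' native contact partners. The alignment is computed by affine-gap dynamic
#' programming, global in the template and semi-global in the query (full
#' fold coverage is preferred because it is required downstream); ties are
#' broken deterministically toward diagonal > up > left.
#'
#' @param query residue string (>= 10 residues) or a `sequence_record`.
#' @param template a `template_structure`.
#' @param potentials a `contact_potentials`.
#' @param gap_open,gap_extend affine gap penalties (defaults 4.0 / 0.4).
#' @param profile optional precomputed [template_profile()] to reuse.
#' @return object of class `threading_alignment`: pairs tibble
#'   (qpos, tpos in template residue indices), `pl`, `fl`, `gaps` tibble,
#'   raw pair/burial energies, sequence similarity, percent identity.
#'   z-scores and Thx are filled by [zscores()] / [compute_thx()].
#' @export
align_sequence_to_structure <- function(query, template, potentials,
                                        gap_open = 4.0, gap_extend = 0.4,
                                        profile = NULL) {
  qres <- if (inherits(query, "sequence_record")) query$residues else query
  if (nchar(qres) == 0) stop_scan("empty query")
  if (nchar(qres) < 10) stop_scan("query shorter than 10 residues")
  qaa <- aa_chars(qres)
  prof <- profile %||% template_profile(template, potentials)
  S <- score_matrix(prof, qaa)
  # S is n_resolved x n_query; DP wants query rows x template cols
  res <- cs_align_cpp(t(S), gap_open, gap_extend)
  build_alignment(res, qaa, prof, template)
}

# DP score matrix: negated energies standardized over the template's full
# 20-residue profile, so gap penalties are expressed in profile-SD units and
# stay meaningful whatever the absolute scale of the potentials
score_matrix <- function(prof, qaa) {
  full <- -(prof$pair + prof$surf)
  mu <- mean(full[, AA20]); sdev <- sd(as.vector(full[, AA20]))
  S <- full[, qaa, drop = FALSE]
  if (!is.na(sdev) && sdev > 0) S <- (S - mu) / sdev
  S
}

build_alignment <- function(res, qaa, prof, template) {
  qpos <- res$qpos
  tres <- res$tpos                   # indices into resolved subset
  tpos <- prof$tidx[tres]            # template residue indices
  pl <- length(qpos)
  acol <- match(qaa, colnames(prof$pair))
  e_pair <- if (pl) sum(prof$pair[cbind(tres, acol[qpos])]) else 0
  e_surf <- if (pl) sum(prof$surf[cbind(tres, acol[qpos])]) else 0
  sim <- if (pl) subst_score(qaa[qpos], prof$aa[tres], substitution_matrix()) else 0
  pid <- if (pl) 100 * sum(qaa[qpos] == prof$aa[tres]) / pl else 0
  structure(list(
    pairs = tibble(qpos = qpos, tpos = tpos),
    pl = pl, fl = template$fl,
    gaps = alignment_gaps(qpos, tres, length(prof$tidx)),
    raw_pair_energy = e_pair, raw_burial_energy = e_surf,
    seq_similarity = sim, percent_id = pid,
    z_pair = NA_real_, z_surf = NA_real_, z_degenerate = FALSE,
    thx = NA_real_, dp_score = res$score,
    template = template_name(template)
  ), class = "threading_alignment")
}

# internal gap runs on both sides; template end-gaps count (global side),
# query end-overhangs do not (semi-global side)
alignment_gaps <- function(qpos, tres, n_template) {
  gaps <- tibble(side = character(), start = integer(), length = integer())
  if (length(qpos) == 0) {
    if (n_template > 0)
      gaps <- tibble(side = "template", start = 1L, length = n_template)
    return(gaps)
  }
  tm <- rep(TRUE, n_template)
  tm[tres] <- FALSE
  r <- rle(tm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    gaps <- bind_rows(gaps, tibble(side = "template", start = starts[k],
                                   length = r$lengths[k]))
  }
  qr <- seq(min(qpos), max(qpos))
  qm <- !(qr %in% qpos)
  r <- rle(qm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    gaps <- bind_rows(gaps, tibble(side = "query",
                                   start = qr[1] + starts[k] - 1L,
                                   length = r$lengths[k]))
  }
  gaps
}

#' @export
print.threading_alignment <- function(x, ...) {
  cat(sprintf("<threading_alignment> vs %s: pl %d / fl %d, %%ID %.1f, Thx %s\n",
              x$template, x$pl, x$fl, x$percent_id,
              ifelse(is.na(x$thx), "(not scored)", sprintf("%.2f", x$thx))))
  invisible(x)
}

#' Interaction z-scores against shuffled-query decoy alignments
#'
#' The query sequence is permuted `n_shuffles` times, each permutation is
#' realigned to the template, and z = (mean(E_shuffled) - E_native) /
#' sd(E_shuffled) for the pair and burial energies separately, so that
#' better-than-random is positive. A zero-variance shuffle distribution is
#' reported as z = 0 with a degenerate flag.
#'
#' @param query residue string or `sequence_record`.
#' @param template a `template_structure`.
#' @param potentials a `contact_potentials`.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed required integer seed (reproducibility contract).
#' @param gap_open,gap_extend passed to the aligner.
#' @param alignment optional precomputed native alignment to reuse.
#' @param profile optional precomputed template profile.
#' @return the native `threading_alignment` with z_pair, z_surf and
#'   z_degenerate filled.
#' @export
zscores <- function(query, template, potentials, n_shuffles = 100, seed,
                    gap_open = 4.0, gap_extend = 0.4,
                    alignment = NULL, profile = NULL) {
  if (missing(seed) || is.null(seed)) stop_scan("zscores() requires a seed")
  qres <- if (inherits(query, "sequence_record")) query$residues else query
  qaa <- aa_chars(qres)
  prof <- profile %||% template_profile(template, potentials)
  native <- alignment %||% align_sequence_to_structure(
    qres, template, potentials, gap_open, gap_extend, profile = prof)
  set.seed(template_seed(seed, template_name(template)))
  ep <- es <- numeric(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    perm <- sample(length(qaa))
    saa <- qaa[perm]
    S <- score_matrix(prof, saa)
    r <- cs_align_cpp(t(S), gap_open, gap_extend)
    if (length(r$qpos)) {
      scol <- match(saa, colnames(prof$pair))
      ep[k] <- sum(prof$pair[cbind(r$tpos, scol[r$qpos])])
      es[k] <- sum(prof$surf[cbind(r$tpos, scol[r$qpos])])
    }
  }
  zp_sd <- sd(ep); zs_sd <- sd(es)
  degen <- FALSE
  if (is.na(zp_sd) || zp_sd == 0) { native$z_pair <- 0; degen <- TRUE }
  else native$z_pair <- (mean(ep) - native$raw_pair_energy) / zp_sd
  if (is.na(zs_sd) || zs_sd == 0) { native$z_surf <- 0; degen <- TRUE }
  else native$z_surf <- (mean(es) - native$raw_burial_energy) / zs_sd
  native$z_degenerate <- degen
  native
}

#' Composite threading index (Thx)
#'
#' Thx = scale * (w_pair * z_pair + w_surf * z_surf + w_seq * S_seq) /
#' query_length, where S_seq is the substitution-matrix similarity score
#' summed over aligned pairs. The absolute scale is a property of this
#' engine's configuration; family cutoffs are re-derived by
#' [calibrate_thx_cutoff()] rather than carried over from other engines.
#'
#' @param alignment a `threading_alignment` with z-scores filled.
#' @param query_length query length in residues (> 0).
#' @param w_pair,w_surf,w_seq weights (default 1).
#' @param scale overall scale (default 100).
#' @return the alignment with `thx` filled.
#' @export
compute_thx <- function(alignment, query_length, w_pair = 1, w_surf = 1,
                        w_seq = 1, scale = 100) {
  if (query_length <= 0) stop_scan("query_length must be positive")
  if (is.na(alignment$z_pair) || is.na(alignment$z_surf))
    stop_scan("z-scores must be computed before Thx")
  alignment$thx <- scale * (w_pair * alignment$z_pair +
                              w_surf * alignment$z_surf +
                              w_seq * alignment$seq_similarity) / query_length
  alignment
}

#' Percent sequence identity of an alignment
#'
#' @param alignment a `threading_alignment`.
#' @param query residue string or `sequence_record`.
#' @param template a `template_structure`.
#' @return 100 * identical aligned pairs / pl.
#' @export
percent_identity <- function(alignment, query, template) {
  if (alignment$pl == 0) stop_scan("empty alignment (pl = 0)")
  qres <- if (inherits(query, "sequence_record")) query$residues else query
  qaa <- aa_chars(qres)
  100 * sum(qaa[alignment$pairs$qpos] ==
              template$aa[alignment$pairs$tpos]) / alignment$pl
}

#' Thread a query against every template of a fold library and rank hits
#'
#' Hits are sorted by Thx descending, ties by z_pair then template id; ranks
#' are 1-based. Per-template shuffle seeds are derived from `seed` and the
#' template name, so scores are invariant to library ordering.
#'
#' @param query residue string or `sequence_record`.
#' @param library a `fold_library`.
#' @param potentials a `contact_potentials`.
#' @param seed integer seed for the shuffle decoys.
#' @param n_shuffles shuffles per template (default 100).
#' @param gap_open,gap_extend,w_pair,w_surf,w_seq,scale scoring parameters.
#' @return tibble with template, rank, thx, z_pair, z_surf, percent_id, pl,
#'   fl, seq_similarity and an `alignment` list-column.
#' @export
rank_templates <- function(query, library, potentials, seed,
                           n_shuffles = 100, gap_open = 4.0, gap_extend = 0.4,
                           w_pair = 1, w_surf = 1, w_seq = 1, scale = 100) {
  if (length(library$templates) == 0) stop_scan("empty fold library")
  qres <- if (inherits(query, "sequence_record")) query$residues else query
  qlen <- nchar(qres)
  rows <- lapply(library$templates, function(t) {
    prof <- template_profile(t, potentials)
    al <- align_sequence_to_structure(qres, t, potentials, gap_open,
                                      gap_extend, profile = prof)
    al <- zscores(qres, t, potentials, n_shuffles = n_shuffles, seed = seed,
                  gap_open = gap_open, gap_extend = gap_extend,
                  alignment = al, profile = prof)
    al <- compute_thx(al, qlen, w_pair, w_surf, w_seq, scale)
    tibble(template = template_name(t), thx = al$thx, z_pair = al$z_pair,
           z_surf = al$z_surf, percent_id = al$percent_id, pl = al$pl,
           fl = al$fl, seq_similarity = al$seq_similarity,
           alignment = list(al))
  })
  hits <- bind_rows(rows)
  hits <- arrange(hits, desc(.data$thx), desc(.data$z_pair), .data$template)
  hits$rank <- seq_len(nrow(hits))
  hits[, c("template", "rank", "thx", "z_pair", "z_surf", "percent_id",
           "pl", "fl", "seq_similarity", "alignment")]
}

#' Derive the family Thx cutoff from a designated remote homolog
#'
#' Mirrors calibration on a known remote family member: the cutoff is the Thx
#' of the homolog's best high-confidence hit against the family library.
#'
#' @param query the designated remote homolog (string or `sequence_record`).
#' @param library the family `fold_library`.
#' @param potentials a `contact_potentials`.
#' @param seed integer seed.
#' @param ... passed to [rank_templates()] and [classify_hit()].
#' @return numeric cutoff.
#' @export
calibrate_thx_cutoff <- function(query, library, potentials, seed, ...) {
  hits <- rank_templates(query, library, potentials, seed, ...)
  lib_templates <- setNames(library$templates,
                            vapply(library$templates, template_name, character(1)))
  conf <- vapply(seq_len(nrow(hits)), function(i)
    classify_hit(hits$alignment[[i]],
                 lib_templates[[hits$template[i]]])$confidence, character(1))
  hc <- which(conf == "HC")
  if (length(hc) == 0) stop_scan("calibration query has no high-confidence hit")
  hits$thx[hc[1]]
}
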