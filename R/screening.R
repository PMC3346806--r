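#' Classify a threading hit as high-confidence (HC) or false positive (FP)
#'
#' Three rules, all required for HC: fold coverage `ratio_lo <= fl/pl <=
#' ratio_hi` (inclusive); no alignment gap longer than `max_gap` residues on
#' either side; and every template secondary structure element of length >= 3
#' covered by the alignment, allowing at most `edge_slack` unaligned
#' positions at each element edge.
#'
#' @param alignment a `threading_alignment`.
#' @param template the `template_structure` it was computed against.
#' @param ratio_lo,ratio_hi fl/pl band (defaults 0.6 / 1.3).
#' @param max_gap maximal tolerated gap length (default 10).
#' @param edge_slack unaligned positions tolerated per element edge (default 1).
#' @return list(confidence = "HC"/"FP", fcov_ok, gap_ok, sse_covered, ratio).
#' @export
classify_hit <- function(alignment, template, ratio_lo = 0.6, ratio_hi = 1.3,
                         max_gap = 10, edge_slack = 1) {
  if (alignment$pl == 0) stop_scan("cannot classify an empty alignment (pl = 0)")
  ratio <- alignment$fl / alignment$pl
  fcov_ok <- ratio >= ratio_lo && ratio <= ratio_hi
  gap_ok <- nrow(alignment$gaps) == 0 || all(alignment$gaps$length <= max_gap)
  elements <- sse_elements(template)
  sse_covered <- TRUE
  if (nrow(elements) > 0) {
    aligned_t <- alignment$pairs$tpos
    for (k in seq_len(nrow(elements))) {
      posn <- seq(elements$start[k], elements$end[k])
      cov <- posn %in% aligned_t
      core <- cov
      if (edge_slack > 0 && length(cov) > 2 * edge_slack) {
        core <- cov[(1 + edge_slack):(length(cov) - edge_slack)]
      }
      if (!all(core)) { sse_covered <- FALSE; break }
    }
  }
  list(confidence = if (fcov_ok && gap_ok && sse_covered) "HC" else "FP",
       fcov_ok = fcov_ok, gap_ok = gap_ok, sse_covered = sse_covered,
       ratio = ratio)
}

classify_hits_tbl <- function(hits, library) {
  templates <- setNames(library$templates,
                        vapply(library$templates, template_name, character(1)))
  cls <- lapply(seq_len(nrow(hits)), function(i)
    classify_hit(hits$alignment[[i]], templates[[hits$template[i]]]))
  hits$confidence <- vapply(cls, `[[`, character(1), "confidence")
  hits$fcov_ok <- vapply(cls, `[[`, logical(1), "fcov_ok")
  hits$gap_ok <- vapply(cls, `[[`, logical(1), "gap_ok")
  hits$sse_covered <- vapply(cls, `[[`, logical(1), "sse_covered")
  hits
}

#' Chemokine 3D-profile screen of one query
#'
#' Ranks the query against the chemokine fold library; the query passes iff
#' its best high-confidence hit reaches the family Thx cutoff AND at least
#' `min_bonds` disulfide bonds can be mapped onto that scaffold.
#'
#' @param query residue string or `sequence_record`.
#' @param chemokine_library a `fold_library` of kind "chemokine".
#' @param potentials a `contact_potentials`.
#' @param thx_cutoff family cutoff (from [calibrate_thx_cutoff()]).
#' @param min_bonds minimal mappable disulfide bonds (default 1).
#' @param seed integer seed.
#' @param dis_top_hits number of top HC hits over which the reported diS
#'   range (min-max of per-template bond counts) is taken (default 2).
#' @param ... scoring parameters passed to [rank_templates()].
#' @return list(pass, best_hit (one-row tibble or NULL), dismap, best_thx,
#'   dis_range, reason).
#' @export
chemokine_profile_screen <- function(query, chemokine_library, potentials,
                                     thx_cutoff, min_bonds = 1, seed,
                                     dis_top_hits = 2, ...) {
  if (length(chemokine_library$templates) == 0) stop_scan("empty chemokine library")
  hits <- rank_templates(query, chemokine_library, potentials, seed, ...)
  hits <- classify_hits_tbl(hits, chemokine_library)
  hc <- hits[hits$confidence == "HC", , drop = FALSE]
  if (nrow(hc) == 0) {
    return(list(pass = FALSE, best_hit = NULL, dismap = NULL,
                best_thx = NA_real_, dis_range = c(NA_integer_, NA_integer_),
                reason = "no_hc_hit", hits = hits))
  }
  templates <- setNames(chemokine_library$templates,
                        vapply(chemokine_library$templates, template_name, character(1)))
  top <- hc[seq_len(min(dis_top_hits, nrow(hc))), , drop = FALSE]
  bonds <- vapply(seq_len(nrow(top)), function(k) {
    map_disulfides(query, templates[[top$template[k]]], top$alignment[[k]])$bond_count
  }, integer(1))
  best <- hc[1, , drop = FALSE]
  dismap <- map_disulfides(query, templates[[best$template]], best$alignment[[1]])
  thx_ok <- best$thx >= thx_cutoff
  bonds_ok <- dismap$bond_count >= min_bonds
  reason <- if (!thx_ok) "below_thx_cutoff" else if (!bonds_ok) "no_disulfide_scaffold" else ""
  list(pass = thx_ok && bonds_ok, best_hit = best, dismap = dismap,
       best_thx = best$thx, dis_range = range(bonds), reason = reason,
       hits = hits)
}

#' Keep the top-n scored queries
#'
#' @param scores tibble with columns `query_id` and a score column.
#' @param n number to retain (default 70).
#' @param key score column name (default "best_thx").
#' @return the top `n` rows by `key` descending, ties broken by query id.
#' @export
take_top <- function(scores, n = 70, key = "best_thx") {
  if (n <= 0) stop_scan("n must be positive")
  ord <- order(-scores[[key]], scores$query_id)
  scores[ord[seq_len(min(n, nrow(scores)))], , drop = FALSE]
}

#' Fold-space control screen of one query
#'
#' Ranks the query across a redundancy-reduced all-fold library, expands hits
#' to SCOP domains, discards domains with coverage below `min_cov` percent,
#' collapses to the best hit per SCOP family, and passes the query iff a
#' chemokine (d.9) domain is ranked first or second among the high-confidence
#' entries within the top `top_domains` domains.
#'
#' @param query residue string or `sequence_record`.
#' @param foldspace_library a `fold_library` of kind "fold_space" with SCOP
#'   annotations attached.
#' @param potentials a `contact_potentials`.
#' @param seed integer seed.
#' @param min_cov SCOP domain coverage threshold in percent (default 70).
#' @param top_domains domains considered (default 20).
#' @param max_ck_rank maximal accepted chemokine rank (default 2).
#' @param ... scoring parameters passed to [rank_templates()].
#' @return list(pass, ck_rank, domains (ranked tibble), reason).
#' @export
foldspace_screen <- function(query, foldspace_library, potentials, seed,
                             min_cov = 70, top_domains = 20, max_ck_rank = 2,
                             ...) {
  hits <- rank_templates(query, foldspace_library, potentials, seed, ...)
  hits <- classify_hits_tbl(hits, foldspace_library)
  templates <- setNames(foldspace_library$templates,
                        vapply(foldspace_library$templates, template_name, character(1)))
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    t <- templates[[hits$template[k]]]
    if (nrow(t$scop) == 0) next
    for (d in seq_len(nrow(t$scop))) {
      cov <- scop_domain_coverage(hits$alignment[[k]],
                                  c(t$scop$start[d], t$scop$end[d]))
      rows[[length(rows) + 1]] <- tibble(
        template = hits$template[k], family = t$scop$family[d],
        thx = hits$thx[k], z_pair = hits$z_pair[k],
        confidence = hits$confidence[k], pct_cov = cov)
    }
  }
  if (length(rows) == 0) {
    return(c(list(hits = hits),
             rank_scop_domains(tibble(), min_cov, top_domains, max_ck_rank)))
  }
  c(list(hits = hits),
    rank_scop_domains(bind_rows(rows), min_cov, top_domains, max_ck_rank))
}

#' Plot a threading hit ranking
#'
#' Thx by template, ordered by rank, coloured by HC/FP classification when
#' present.
#'
#' @param hits tibble from [rank_templates()] (optionally after
#'   classification by the screens).
#' @param cutoff optional Thx cutoff drawn as a dashed line.
#' @return a ggplot object.
#' @export
plot_hits <- function(hits, cutoff = NULL) {
  hits$template <- factor(hits$template, levels = rev(hits$template[order(hits$rank)]))
  fill <- if ("confidence" %in% names(hits)) hits$confidence else NULL
  p <- ggplot2::ggplot(hits, ggplot2::aes(x = .data$thx, y = .data$template)) +
    ggplot2::labs(x = "Thx", y = NULL) +
    ggplot2::theme_minimal()
  p <- if (is.null(fill)) {
    p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$confidence)) +
      ggplot2::scale_fill_manual(values = c(HC = "steelblue", FP = "grey70"))
  }
  if (!is.null(cutoff)) p <- p + ggplot2::geom_vline(xintercept = cutoff,
                                                     linetype = "dashed")
  p
}

#' Rank SCOP domains of a hit list and decide the chemokine verdict
#'
#' The pure selection rule behind [foldspace_screen()]: discard domains with
#' coverage below `min_cov` percent, keep the best hit per SCOP family,
#' restrict to the top `top_domains` domains, rank the high-confidence
#' entries, and pass iff a chemokine (d.9) domain ranks at or above
#' `max_ck_rank`.
#'
#' @param domains tibble with columns family, thx, z_pair, confidence,
#'   pct_cov, template (one row per hit x domain).
#' @param min_cov,top_domains,max_ck_rank see [foldspace_screen()].
#' @return list(pass, ck_rank, domains (with hc_rank), reason).
#' @export
rank_scop_domains <- function(domains, min_cov = 70, top_domains = 20,
                              max_ck_rank = 2) {
  if (nrow(domains) == 0) {
    return(list(pass = FALSE, ck_rank = NA_integer_, domains = domains,
                reason = "no_scop_domains"))
  }
  dom <- domains[domains$pct_cov >= min_cov, , drop = FALSE]
  if (nrow(dom) == 0) {
    return(list(pass = FALSE, ck_rank = NA_integer_, domains = dom,
                reason = "all_domains_undercovered"))
  }
  # best hit per SCOP family, then rank
  dom <- arrange(dom, desc(.data$thx), desc(.data$z_pair), .data$template)
  dom <- dom[!duplicated(dom$family), , drop = FALSE]
  dom <- dom[seq_len(min(top_domains, nrow(dom))), , drop = FALSE]
  hc <- dom[dom$confidence == "HC", , drop = FALSE]
  if (nrow(hc) == 0) {
    dom$hc_rank <- NA_integer_
    return(list(pass = FALSE, ck_rank = NA_integer_, domains = dom,
                reason = "no_hc_hit"))
  }
  hc$hc_rank <- seq_len(nrow(hc))
  dom <- left_join(dom, hc[, c("family", "hc_rank")], by = "family")
  ck <- hc[grepl("^d\\.9(\\.|$)", hc$family), , drop = FALSE]
  ck_rank <- if (nrow(ck) == 0) NA_integer_ else min(ck$hc_rank)
  pass <- !is.na(ck_rank) && ck_rank <= max_ck_rank
  list(pass = pass, ck_rank = ck_rank, domains = dom,
       reason = if (pass) "" else "chemokine_rank_too_low")
}
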