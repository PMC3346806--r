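#' Anchor query cysteines onto template positions
#'
#' A cysteine aligned to a resolved template residue anchors there. A
#' cysteine aligned to a gap (or an unresolved residue) yields up to two
#' candidate anchors: the nearest resolved template positions left and right
#' of the gap, both flagged as neighbor substitutions. A cysteine with no
#' resolved neighbor on either side is unanchorable and excluded with a
#' warning.
#'
#' @param alignment a `threading_alignment`.
#' @param template a `template_structure`.
#' @param query residue string or `sequence_record`.
#' @return tibble(cys_pos, anchors (list of integer template indices),
#'   substituted (logical)).
#' @export
anchor_cysteines <- function(alignment, template, query) {
  qres <- if (inherits(query, "sequence_record")) query$residues else query
  qaa <- aa_chars(qres)
  cys <- which(qaa == "C")
  pairs <- alignment$pairs
  aligned_ok <- pairs[template$resolved[pairs$tpos], , drop = FALSE]
  rows <- lapply(cys, function(qc) {
    hit <- aligned_ok$tpos[aligned_ok$qpos == qc]
    if (length(hit) == 1) {
      return(tibble(cys_pos = qc, anchors = list(hit), substituted = FALSE))
    }
    left <- aligned_ok$tpos[aligned_ok$qpos < qc]
    right <- aligned_ok$tpos[aligned_ok$qpos > qc]
    anchors <- c(if (length(left)) max(left),
                 if (length(right)) min(right))
    if (length(anchors) == 0) {
      warning(sprintf("cysteine at query position %d has no resolved template neighbor; excluded", qc),
              call. = FALSE)
      return(NULL)
    }
    tibble(cys_pos = qc, anchors = list(unique(anchors)), substituted = TRUE)
  })
  bind_rows(rows)
}

#' Geometric disulfide feasibility of one cysteine pair
#'
#' The three scaffold criteria: (i) d(C-alpha) <= `d_ca_max` and d(C-beta) <=
#' `d_cb_max`; (ii) d(C-beta) - d(C-alpha) <= `d_diff_max` (side chains must
#' not point apart); (iii) sequence separation j - i >= `min_sep`. All bounds
#' inclusive. With multiple candidate anchors per cysteine, the pair passes
#' if any anchor combination passes (`mode = "any"`, the default) or only if
#' all combinations pass (`mode = "all"`); recorded distances are those of
#' the best (minimum d_cb) passing combination, else of the minimum-d_cb
#' combination.
#'
#' @param anchorsA,anchorsB integer vectors of template anchor positions.
#' @param i,j 1-based query positions of the two cysteines (i < j).
#' @param template a `template_structure`.
#' @param d_ca_max,d_cb_max,d_diff_max,min_sep thresholds (defaults 10, 9, 1, 3).
#' @param mode "any" (permissive) or "all" (strict) over anchor combinations.
#' @return one-row tibble(i, j, anchor_i, anchor_j, d_ca, d_cb,
#'   crit_distance, crit_orientation, crit_separation, possible).
#' @export
check_pair <- function(anchorsA, anchorsB, i, j, template,
                       d_ca_max = 10, d_cb_max = 9, d_diff_max = 1,
                       min_sep = 3, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (i > j) { tmp <- i; i <- j; j <- tmp
               tmp <- anchorsA; anchorsA <- anchorsB; anchorsB <- tmp }
  sep_ok <- (j - i) >= min_sep
  combos <- expand.grid(a = anchorsA, b = anchorsB)
  combos <- combos[combos$a != combos$b, , drop = FALSE]
  if (nrow(combos) == 0) {
    # both cysteines collapse onto one template residue (e.g. a shared
    # terminal neighbor): no scaffold geometry to measure, bond infeasible
    return(tibble(i = i, j = j, anchor_i = anchorsA[1], anchor_j = anchorsB[1],
                  d_ca = 0, d_cb = 0, crit_distance = FALSE,
                  crit_orientation = FALSE, crit_separation = sep_ok,
                  possible = FALSE))
  }
  res <- lapply(seq_len(nrow(combos)), function(k) {
    a <- combos$a[k]; b <- combos$b[k]
    if (!template$resolved[a] || !template$resolved[b] ||
        any(is.na(template$ca[a, ])) || any(is.na(template$cb[a, ])) ||
        any(is.na(template$ca[b, ])) || any(is.na(template$cb[b, ])))
      stop_scan("missing coordinates at template anchor %d or %d", a, b)
    d_ca <- pt_dist(template$ca[a, ], template$ca[b, ])
    d_cb <- pt_dist(template$cb[a, ], template$cb[b, ])
    list(a = a, b = b, d_ca = d_ca, d_cb = d_cb,
         dist_ok = d_ca <= d_ca_max && d_cb <= d_cb_max,
         orient_ok = (d_cb - d_ca) <= d_diff_max)
  })
  geom_pass <- vapply(res, function(r) r$dist_ok && r$orient_ok, logical(1))
  geom_ok <- if (mode == "any") any(geom_pass) else all(geom_pass)
  pool <- if (any(geom_pass) && mode == "any") res[geom_pass] else res
  best <- pool[[which.min(vapply(pool, function(r) r$d_cb, numeric(1)))]]
  tibble(i = i, j = j, anchor_i = best$a, anchor_j = best$b,
         d_ca = best$d_ca, d_cb = best$d_cb,
         crit_distance = if (mode == "any") any(vapply(res, function(r) r$dist_ok, logical(1)))
                         else all(vapply(res, function(r) r$dist_ok, logical(1))),
         crit_orientation = if (mode == "any") any(vapply(res, function(r) r$orient_ok, logical(1)))
                            else all(vapply(res, function(r) r$orient_ok, logical(1))),
         crit_separation = sep_ok,
         possible = geom_ok && sep_ok)
}

# Exact maximum-cardinality matching on a general graph.
# Size by memoized recursion on the set of available vertices; the chosen
# pairing is then built greedily over lexicographically ordered edges, keeping
# an edge iff a maximum matching through it still exists. This makes the
# chosen pairing the lexicographically smallest maximum matching.
max_matching_exact <- function(vertices, edges) {
  empty <- matrix(integer(), ncol = 2)
  if (nrow(edges) == 0) return(list(size = 0L, pairing = empty))
  memo <- new.env(parent = emptyenv())
  msize <- function(avail) {
    if (length(avail) < 2) return(0L)
    key <- paste(avail, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sub <- edges[edges[, 1] %in% avail & edges[, 2] %in% avail, , drop = FALSE]
    if (nrow(sub) == 0) { memo[[key]] <- 0L; return(0L) }
    v <- min(sub[, 1])
    best <- msize(setdiff(avail, v))  # leave v unmatched
    for (e in which(sub[, 1] == v)) {
      cand <- 1L + msize(setdiff(avail, sub[e, ]))
      if (cand > best) best <- cand
    }
    memo[[key]] <- best
    best
  }
  total <- msize(vertices)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  avail <- vertices
  chosen <- empty
  need <- total
  for (e in seq_len(nrow(edges))) {
    if (need == 0L) break
    a <- edges[e, 1]; b <- edges[e, 2]
    if (!(a %in% avail) || !(b %in% avail)) next
    rest <- setdiff(avail, c(a, b))
    if (1L + msize(rest) == need) {
      chosen <- rbind(chosen, edges[e, , drop = FALSE])
      avail <- rest
      need <- need - 1L
    }
  }
  list(size = as.integer(total), pairing = chosen)
}

#' Maximum disjoint disulfide pairing from pair assessments
#'
#' Cysteines are vertices, feasible pairs are edges; the bond count (diS) is
#' the size of a maximum-cardinality matching, found by exact search
#' (guarded to `max_cys` cysteines). The chosen pairing is the
#' lexicographically smallest maximum matching, so results are deterministic.
#'
#' @param assessments tibble of [check_pair()] rows covering all pairs.
#' @param max_cys guard on the number of distinct cysteines (default 20).
#' @return object of class `disulfide_map`: assessments (with
#'   `in_chosen_pairing`), `bond_count`, `chosen_pairing` tibble.
#' @export
enumerate_bonds <- function(assessments, max_cys = 20) {
  cys <- sort(unique(c(assessments$i, assessments$j)))
  if (length(cys) > max_cys)
    stop_scan("%d cysteines exceeds the exact-search guard (%d); raise max_cys",
              length(cys), max_cys)
  edges <- as.matrix(assessments[assessments$possible, c("i", "j"), drop = FALSE])
  storage.mode(edges) <- "integer"
  m <- max_matching_exact(cys, edges)
  chosen <- if (m$size > 0) {
    tibble(i = m$pairing[, 1], j = m$pairing[, 2])
  } else tibble(i = integer(), j = integer())
  assessments$in_chosen_pairing <-
    paste(assessments$i, assessments$j) %in% paste(chosen$i, chosen$j)
  structure(list(assessments = assessments, bond_count = m$size,
                 chosen_pairing = chosen),
            class = "disulfide_map")
}

#' @export
print.disulfide_map <- function(x, ...) {
  cat(sprintf("<disulfide_map> %d assessed pair(s), diS = %d\n",
              nrow(x$assessments), x$bond_count))
  invisible(x)
}

#' Scaffold-based disulfide mapping of a query onto a template
#'
#' Composes [anchor_cysteines()], [check_pair()] over all cysteine pairs and
#' [enumerate_bonds()].
#'
#' @param query residue string or `sequence_record`.
#' @param template a `template_structure`.
#' @param alignment a `threading_alignment` of query onto template.
#' @param d_ca_max,d_cb_max,d_diff_max,min_sep,mode,max_cys see [check_pair()]
#'   and [enumerate_bonds()].
#' @return a `disulfide_map`; queries with fewer than two anchorable
#'   cysteines give bond_count 0.
#' @export
map_disulfides <- function(query, template, alignment,
                           d_ca_max = 10, d_cb_max = 9, d_diff_max = 1,
                           min_sep = 3, mode = "any", max_cys = 20) {
  anchors <- anchor_cysteines(alignment, template, query)
  empty <- tibble(i = integer(), j = integer(), anchor_i = integer(),
                  anchor_j = integer(), d_ca = numeric(), d_cb = numeric(),
                  crit_distance = logical(), crit_orientation = logical(),
                  crit_separation = logical(), possible = logical())
  if (is.null(anchors) || nrow(anchors) < 2) return(enumerate_bonds(empty, max_cys))
  combos <- utils::combn(nrow(anchors), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    check_pair(anchors$anchors[[a]], anchors$anchors[[b]],
               anchors$cys_pos[a], anchors$cys_pos[b], template,
               d_ca_max, d_cb_max, d_diff_max, min_sep, mode)
  })
  enumerate_bonds(bind_rows(rows), max_cys)
}

#' Write a disulfide report as TSV plus a one-line summary
#'
#' @param map a `disulfide_map`.
#' @param query_id,template_id identifiers for the report.
#' @param path output TSV path (summary goes to `<path>.summary`).
#' @export
write_disulfide_report <- function(map, query_id, template_id, path) {
  d <- map$assessments
  d$query <- query_id; d$template <- template_id
  d <- d[, c("query", "template", "i", "j", "d_ca", "d_cb", "crit_distance",
             "crit_orientation", "crit_separation", "possible",
             "in_chosen_pairing")]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%s\tdiS=%d", query_id, template_id, map$bond_count),
             paste0(path, ".summary"))
  invisible(path)
}
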