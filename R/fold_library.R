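#' Read a SCOP domain mapping from TSV
#'
#' @param path TSV with columns pdb_id, chain, scop_family, start, end
#'   (no header). Residue ranges are chain residue indices.
#' @return tibble(pdb_id, chain, family, start, end).
#' @export
read_scop_map <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("pdb_id", "chain", "family", "start", "end"),
                  colClasses = c("character", "character", "character",
                                 "integer", "integer"))
  as_tibble(d)
}

#' Load template structures listed in a manifest
#'
#' @param path TSV with columns file path, chain id (no header). Relative
#'   paths are resolved against the manifest's directory.
#' @return list of `template_structure`.
#' @export
read_template_manifest <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("file", "chain"),
                  colClasses = c("character", "character"))
  base <- dirname(path)
  lapply(seq_len(nrow(d)), function(k) {
    f <- d$file[k]
    if (!file.exists(f)) f <- file.path(base, d$file[k])
    parse_structure_chain(f, d$chain[k])
  })
}

#' Attach SCOP domains from a mapping to a list of templates
#' @keywords internal
attach_scop <- function(templates, scop_map) {
  lapply(templates, function(t) {
    m <- scop_map[scop_map$pdb_id == t$pdb_id & scop_map$chain == t$chain_id, ]
    t$scop <- tibble(family = m$family, start = m$start, end = m$end)
    t
  })
}

new_fold_library <- function(name, kind, templates, provenance = list()) {
  ids <- vapply(templates, template_name, character(1))
  if (anyDuplicated(ids)) stop_scan("duplicate (pdb_id, chain) in fold library")
  structure(list(name = name, kind = kind, templates = templates,
                 provenance = provenance),
            class = "fold_library")
}

#' @export
print.fold_library <- function(x, ...) {
  cat(sprintf("<fold_library> %s (%s): %d templates\n",
              x$name, x$kind, length(x$templates)))
  invisible(x)
}

#' Is any SCOP family of a template under the IL8-like chemokine fold (d.9)?
#' @keywords internal
has_chemokine_domain <- function(scop_families) {
  any(grepl("^d\\.9(\\.|$)", scop_families))
}

#' Build the chemokine-only fold descriptor library
#'
#' Keeps templates carrying at least one SCOP domain under the IL8-like
#' chemokine fold (d.9). Templates without a SCOP mapping are excluded with a
#' warning.
#'
#' @param templates list of `template_structure`.
#' @param scop_map tibble from [read_scop_map()] (or NULL to use domains
#'   already attached to the templates).
#' @param name library name.
#' @return a `fold_library` of kind "chemokine".
#' @export
build_chemokine_library <- function(templates, scop_map = NULL,
                                    name = "chemokine") {
  if (!is.null(scop_map)) templates <- attach_scop(templates, scop_map)
  unmapped <- vapply(templates, function(t) nrow(t$scop) == 0, logical(1))
  if (any(unmapped)) {
    warning(sprintf("%d template(s) without SCOP mapping excluded from chemokine library",
                    sum(unmapped)), call. = FALSE)
  }
  keep <- vapply(templates, function(t)
    nrow(t$scop) > 0 && has_chemokine_domain(t$scop$family), logical(1))
  new_fold_library(name, "chemokine", templates[keep],
                   provenance = list(n_input = length(templates),
                                     n_unmapped = sum(unmapped)))
}

#' Global pairwise sequence identity of two templates
#'
#' Needleman-Wunsch global alignment (match 1 / mismatch 0, zero gap
#' penalties beyond affine defaults); identity = matches / alignment columns
#' excluding terminal gaps.
#'
#' @keywords internal
global_identity <- function(seq_a, seq_b) {
  letters <- c(AA20, "X")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- 0  # ambiguity codes never count as matches
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global",
    substitutionMatrix = m, gapOpening = 1, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | ps == "-"
  # trim terminal gap columns
  inner <- which(!gap)
  if (length(inner) == 0) return(0)
  cols <- seq(min(inner), max(inner))
  100 * sum(pa[cols] == ps[cols] & pa[cols] != "-") / length(cols)
}

#' Build a redundancy-reduced all-fold library
#'
#' Greedy representative selection: templates are sorted by fold length
#' descending (ties by (pdb_id, chain) lexicographic) and admitted iff their
#' global identity to every already-admitted template is below
#' `identity_cutoff` percent. Deterministic and invariant to input order.
#'
#' @param templates list of `template_structure`.
#' @param identity_cutoff percent identity cutoff (default 95).
#' @param scop_map optional SCOP mapping to attach.
#' @param name library name.
#' @return a `fold_library` of kind "fold_space".
#' @export
build_foldspace_library <- function(templates, identity_cutoff = 95,
                                    scop_map = NULL, name = "fold_space") {
  if (length(templates) < 1) stop_scan("need at least one template")
  if (!is.null(scop_map)) templates <- attach_scop(templates, scop_map)
  fls <- vapply(templates, function(t) t$fl, numeric(1))
  ids <- vapply(templates, template_name, character(1))
  ord <- order(-fls, ids)
  admitted <- list()
  admitted_seqs <- character()
  for (k in ord) {
    s <- native_sequence(templates[[k]])
    ok <- all(vapply(admitted_seqs, function(a)
      global_identity(s, a) < identity_cutoff, logical(1)))
    if (ok) {
      admitted[[length(admitted) + 1]] <- templates[[k]]
      admitted_seqs <- c(admitted_seqs, s)
    }
  }
  new_fold_library(name, "fold_space", admitted,
                   provenance = list(n_input = length(templates),
                                     identity_cutoff = identity_cutoff))
}

#' SCOP domain coverage of an alignment
#'
#' Percentage of a SCOP domain's positions that are aligned to a query
#' residue.
#'
#' @param alignment a `threading_alignment` (or any list with a `pairs`
#'   tibble holding `tpos`).
#' @param domain_range integer vector c(start, end) in template residue
#'   indices.
#' @return coverage percentage in 0..100.
#' @export
scop_domain_coverage <- function(alignment, domain_range) {
  start <- domain_range[1]; end <- domain_range[2]
  if (is.na(start) || is.na(end) || end < start)
    stop_scan("empty or invalid SCOP domain range")
  dom <- seq(start, end)
  100 * sum(alignment$pairs$tpos %in% dom) / length(dom)
}
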