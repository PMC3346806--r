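BURIAL_BANDS <- list(c(0, 2), c(3, 5), c(6, 8), c(9, Inf))

burial_band <- function(count) {
  if (count <= 2) 1L else if (count <= 5) 2L else if (count <= 8) 3L else 4L
}

#' Count-to-energy conversion for a potential of mean force
#'
#' `E = -ln((N + pc) / (N_ref + pc))` with N_ref the per-class mean count in
#' the stratum, so that uniform counts give zero energy everywhere and
#' unobserved classes hit the positive pseudocount bound.
#'
#' @keywords internal
counts_to_energy <- function(counts, n_classes, pseudocount) {
  total <- sum(counts)
  ref <- total / n_classes
  -log((counts + pseudocount) / (ref + pseudocount))
}

#' Derive pair and burial potentials of mean force from training structures
#'
#' Pair energies are indexed by (residue type, residue type, C-beta distance
#' bin) with counts taken over residue pairs at sequence separation >=
#' `min_separation`; the reference state is the per-pair-type mean count in
#' each distance bin, with pseudocount regularization. Burial energies are
#' indexed by (residue type, C-beta neighbor-count band) with neighbors
#' counted within `burial_radius`.
#'
#' @param training_templates list of `template_structure`.
#' @param bin_edges distance bin edges in Angstrom (default 0..15 step 1).
#' @param min_separation minimum |i - j| for pair counting (default 4).
#' @param pseudocount regularizer (default 1).
#' @param burial_radius neighbor radius in Angstrom (default 10).
#' @return object of class `contact_potentials` with `pair` (20 x 20 x nbins
#'   array, symmetric) and `burial` (20 x 4 matrix) energy tables.
#' @export
derive_potentials <- function(training_templates, bin_edges = 0:15,
                              min_separation = 4, pseudocount = 1,
                              burial_radius = 10) {
  nb <- length(bin_edges) - 1
  pair_counts <- array(0, dim = c(20, 20, nb), dimnames = list(AA20, AA20, NULL))
  burial_counts <- matrix(0, 20, 4, dimnames = list(AA20, NULL))
  n_contacts <- 0
  for (t in training_templates) {
    idx <- which(t$resolved & t$aa %in% AA20)
    if (length(idx) < 2) next
    cb <- t$cb[idx, , drop = FALSE]
    dm <- as.matrix(dist(cb))
    aa <- t$aa[idx]
    for (a in seq_along(idx)) {
      nb_count <- sum(dm[a, ] <= burial_radius) - 1L
      burial_counts[aa[a], burial_band(nb_count)] <-
        burial_counts[aa[a], burial_band(nb_count)] + 1
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (abs(idx[b] - idx[a]) < min_separation) next
        d <- dm[a, b]
        if (d >= max(bin_edges)) next
        bin <- findInterval(d, bin_edges, rightmost.closed = TRUE)
        # unordered pair counted once into both orderings to keep symmetry
        pair_counts[aa[a], aa[b], bin] <- pair_counts[aa[a], aa[b], bin] + 1
        if (aa[a] != aa[b])
          pair_counts[aa[b], aa[a], bin] <- pair_counts[aa[b], aa[a], bin] + 1
        n_contacts <- n_contacts + 1
      }
    }
  }
  if (n_contacts == 0) stop_scan("no contacts found in training set")

  pair_energy <- array(0, dim = dim(pair_counts), dimnames = dimnames(pair_counts))
  for (d in seq_len(nb)) {
    cts <- pair_counts[, , d]
    # unordered classes: upper triangle incl. diagonal, 210 types
    ut <- upper.tri(cts, diag = TRUE)
    e_ut <- counts_to_energy(cts[ut], n_classes = sum(ut), pseudocount = pseudocount)
    e <- matrix(0, 20, 20, dimnames = dimnames(cts))
    e[ut] <- e_ut
    e <- e + t(e) - diag(diag(e))  # mirror to full symmetric matrix
    pair_energy[, , d] <- e
  }
  burial_energy <- burial_counts
  for (band in 1:4) {
    burial_energy[, band] <- counts_to_energy(burial_counts[, band],
                                              n_classes = 20,
                                              pseudocount = pseudocount)
  }
  structure(list(
    pair = pair_energy, burial = burial_energy,
    bin_edges = bin_edges, min_separation = min_separation,
    pseudocount = pseudocount, burial_radius = burial_radius,
    reference = "per-class mean count within stratum",
    n_contacts = n_contacts
  ), class = "contact_potentials")
}

#' @export
print.contact_potentials <- function(x, ...) {
  cat(sprintf("<contact_potentials> %d distance bins (%g-%g A), min separation %d, %d training contacts\n",
              length(x$bin_edges) - 1, min(x$bin_edges), max(x$bin_edges),
              x$min_separation, x$n_contacts))
  invisible(x)
}

#' Serialize potentials to a JSON file
#' @param potentials a `contact_potentials`.
#' @param path output file.
#' @export
write_potentials <- function(potentials, path) {
  obj <- list(pair = potentials$pair, burial = potentials$burial,
              bin_edges = potentials$bin_edges,
              min_separation = potentials$min_separation,
              pseudocount = potentials$pseudocount,
              burial_radius = potentials$burial_radius,
              reference = potentials$reference,
              n_contacts = potentials$n_contacts)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read potentials from a JSON file written by [write_potentials()]
#' @param path JSON file.
#' @export
read_potentials <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pair <- array(unlist(obj$pair), dim = c(20, 20, length(obj$bin_edges) - 1),
                dimnames = list(AA20, AA20, NULL))
  burial <- matrix(unlist(obj$burial), 20, 4, dimnames = list(AA20, NULL))
  structure(list(pair = pair, burial = burial,
                 bin_edges = obj$bin_edges,
                 min_separation = obj$min_separation,
                 pseudocount = obj$pseudocount,
                 burial_radius = obj$burial_radius,
                 reference = obj$reference,
                 n_contacts = obj$n_contacts),
            class = "contact_potentials")
}

#' Frozen-approximation scoring profile of a template
#'
#' For each resolved template position j and each residue type a, the pair
#' profile is the sum of pair energies of a against the template's native
#' residues at j's contact partners, and the burial profile is the burial
#' energy of a in j's neighbor-count band.
#'
#' @param template a `template_structure`.
#' @param potentials a `contact_potentials`.
#' @return list with `tidx` (template residue indices of the resolved
#'   positions), `pair` and `surf` (n_resolved x 21 matrices; column X is 0).
#' @keywords internal
template_profile <- function(template, potentials) {
  idx <- which(template$resolved)
  cb <- template$cb[idx, , drop = FALSE]
  dm <- as.matrix(dist(cb))
  aa <- template$aa[idx]
  nres <- length(idx)
  letters21 <- c(AA20, "X")
  ppair <- matrix(0, nres, 21, dimnames = list(NULL, letters21))
  psurf <- matrix(0, nres, 21, dimnames = list(NULL, letters21))
  maxd <- max(potentials$bin_edges)
  for (j in seq_len(nres)) {
    nb_count <- sum(dm[j, ] <= potentials$burial_radius) - 1L
    psurf[j, AA20] <- potentials$burial[, burial_band(nb_count)]
    partners <- which(abs(idx - idx[j]) >= potentials$min_separation &
                        dm[j, ] < maxd & aa %in% AA20)
    for (p in partners) {
      bin <- findInterval(dm[j, p], potentials$bin_edges, rightmost.closed = TRUE)
      ppair[j, AA20] <- ppair[j, AA20] + potentials$pair[, aa[p], bin]
    }
  }
  list(tidx = idx, pair = ppair, surf = psurf, aa = aa)
}
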