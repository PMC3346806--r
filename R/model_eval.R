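#' Per-residue contact energy profile of a structure
#'
#' Energy of residue i is half the sum of pair energies over partners j with
#' d(C-beta_i, C-beta_j) <= `cutoff` and |i - j| >= `min_sep`, so that the
#' profile sums to the total contact energy.
#'
#' @param structure a `template_structure` (models are read with
#'   [parse_structure_chain()]).
#' @param pair_potential a `contact_potentials` (its pair table is used).
#' @param cutoff contact distance in Angstrom (default 10).
#' @param min_sep minimum sequence separation (default 4).
#' @return numeric vector over resolved residues, with attribute
#'   `residue_index` (template residue indices).
#' @export
contact_energy_profile <- function(structure, pair_potential, cutoff = 10,
                                   min_sep = 4) {
  idx <- which(structure$resolved)
  aa <- structure$aa[idx]
  cb <- structure$cb[idx, , drop = FALSE]
  dm <- as.matrix(dist(cb))
  prof <- numeric(length(idx))
  edges <- pair_potential$bin_edges
  for (a in seq_along(idx)) {
    if (!aa[a] %in% AA20) next
    partners <- which(dm[a, ] <= cutoff & abs(idx - idx[a]) >= min_sep &
                        aa %in% AA20)
    for (b in partners) {
      bin <- findInterval(min(dm[a, b], max(edges) - 1e-9), edges,
                          rightmost.closed = TRUE)
      prof[a] <- prof[a] + 0.5 * pair_potential$pair[aa[a], aa[b], bin]
    }
  }
  attr(prof, "residue_index") <- idx
  prof
}

kabsch <- function(A, B) {
  # rotation + translation minimizing RMSD of A onto B (n x 3 each)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, tA = ca, tB = cb)
}

apply_kabsch <- function(X, k) sweep(sweep(X, 2, k$tA) %*% t(k$R), 2, k$tB, `+`)

# initial correspondence from SSE elements: pair same-type elements in order
# (longest common subsequence over element type strings), then pair residues
# from the element starts
sse_seed_correspondence <- function(sa, sb) {
  ea <- sse_elements(sa); eb <- sse_elements(sb)
  if (nrow(ea) == 0 || nrow(eb) == 0) return(NULL)
  na <- nrow(ea); nb <- nrow(eb)
  L <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    L[i + 1, j + 1] <- if (ea$type[i] == eb$type[j]) L[i, j] + 1L
                       else max(L[i, j + 1], L[i + 1, j])
  }
  if (L[na + 1, nb + 1] == 0) return(NULL)
  pairs <- list(); i <- na; j <- nb
  while (i > 0 && j > 0) {
    if (ea$type[i] == eb$type[j] && L[i + 1, j + 1] == L[i, j] + 1L) {
      pairs[[length(pairs) + 1]] <- c(i, j); i <- i - 1; j <- j - 1
    } else if (L[i, j + 1] >= L[i + 1, j]) i <- i - 1 else j <- j - 1
  }
  out <- list()
  for (p in rev(pairs)) {
    len <- min(ea$end[p[1]] - ea$start[p[1]], eb$end[p[2]] - eb$start[p[2]]) + 1L
    out[[length(out) + 1]] <- cbind(seq(ea$start[p[1]], length.out = len),
                                    seq(eb$start[p[2]], length.out = len))
  }
  do.call(rbind, out)
}

# longest strictly increasing (both sides) chain of nearest-neighbor pairs
monotone_pairs <- function(cand) {
  # cand: matrix (ia, ib, d), already unique in ia; pick LIS over ib weighted
  # by count (maximize number of pairs)
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  n <- nrow(cand)
  best <- rep(1L, n); prev <- rep(0L, n)
  for (k in seq_len(n)) {
    for (m in seq_len(k - 1)) {
      if (cand[m, 2] < cand[k, 2] && best[m] + 1L > best[k]) {
        best[k] <- best[m] + 1L; prev[k] <- m
      }
    }
  }
  k <- which.max(best)
  chain <- integer()
  while (k > 0) { chain <- c(k, chain); k <- prev[k] }
  cand[chain, , drop = FALSE]
}

#' Rigid-body superposition with iterative correspondence refinement
#'
#' Starting from an SSE-guided element pairing, a least-squares rigid
#' superposition on C-alpha atoms is computed (Kabsch), positions are then
#' re-paired by spatial proximity (within `pair_cutoff`, kept sequence-
#' monotone), and the two steps are iterated to convergence.
#'
#' @param structA,structB `template_structure`s with >= 20 resolved residues.
#' @param pair_cutoff re-pairing distance in Angstrom (default 5).
#' @param max_iter,tol iteration controls (50 / 1e-4 Angstrom RMSD change).
#' @return object of class `correspondence`: pairs tibble(pos_a, pos_b) in
#'   resolved-residue indices, `rmsd` (Angstrom), `n_iter`.
#' @export
superpose <- function(structA, structB, pair_cutoff = 5, max_iter = 50,
                      tol = 1e-4) {
  ia <- which(structA$resolved); ib <- which(structB$resolved)
  if (length(ia) < 20 || length(ib) < 20)
    stop_scan("both structures need >= 20 resolved residues")
  A <- structA$ca[ia, , drop = FALSE]; B <- structB$ca[ib, , drop = FALSE]
  # seeds in resolved-subset indexing
  map_a <- match(seq_along(structA$resolved), ia)
  map_b <- match(seq_along(structB$resolved), ib)
  seed <- sse_seed_correspondence(structA, structB)
  if (is.null(seed))
    stop_scan("no initial SSE element pairing; supply a manual correspondence")
  seed <- cbind(map_a[seed[, 1]], map_b[seed[, 2]])
  seed <- seed[stats::complete.cases(seed), , drop = FALSE]
  if (nrow(seed) < 3) stop_scan("SSE seed correspondence too small")
  corr <- seed
  rmsd_prev <- Inf; rmsd <- Inf; it <- 0
  for (it in seq_len(max_iter)) {
    k <- kabsch(A[corr[, 1], , drop = FALSE], B[corr[, 2], , drop = FALSE])
    A_fit <- apply_kabsch(A, k)
    dmat <- outer(rowSums(A_fit^2), rowSums(B^2), `+`) - 2 * A_fit %*% t(B)
    dmat[dmat < 0] <- 0
    dmat <- sqrt(dmat)
    nn <- apply(dmat, 1, which.min)
    nd <- dmat[cbind(seq_len(nrow(dmat)), nn)]
    cand <- cbind(seq_len(nrow(A)), nn, nd)[nd <= pair_cutoff, , drop = FALSE]
    cand <- monotone_pairs(cand)
    if (nrow(cand) < 3) break
    corr <- cand[, 1:2, drop = FALSE]
    rmsd <- sqrt(mean(dmat[corr]^2))
    if (abs(rmsd_prev - rmsd) < tol) break
    rmsd_prev <- rmsd
  }
  k <- kabsch(A[corr[, 1], , drop = FALSE], B[corr[, 2], , drop = FALSE])
  A_fit <- apply_kabsch(A[corr[, 1], , drop = FALSE], k)
  rmsd <- sqrt(mean(rowSums((A_fit - B[corr[, 2], , drop = FALSE])^2)))
  structure(list(pairs = tibble(pos_a = corr[, 1], pos_b = corr[, 2]),
                 rmsd = rmsd, n_iter = it),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("<correspondence> %d pairs, RMSD %.3f A (%d iterations)\n",
              nrow(x$pairs), x$rmsd, x$n_iter))
  invisible(x)
}

#' Contact-energy coefficient of determination between two profiles
#'
#' Squared Pearson correlation of the energy values of structurally
#' corresponding residues; gap positions do not enter.
#'
#' @param profileA,profileB numeric energy profiles (resolved-residue
#'   indexed, as from [contact_energy_profile()]).
#' @param correspondence a `correspondence` from [superpose()].
#' @return R-squared in 0..1.
#' @export
contact_energy_r2 <- function(profileA, profileB, correspondence) {
  p <- correspondence$pairs
  if (nrow(p) < 3) stop_scan("need at least 3 corresponding pairs for R^2")
  a <- profileA[p$pos_a]; b <- profileB[p$pos_b]
  if (sd(a) == 0 || sd(b) == 0) stop_scan("zero variance in a contact energy profile")
  cor(a, b)^2
}

#' Secondary structure fractions of a structure
#'
#' Helix and strand from the SSE labels; turns are 4-residue coil segments
#' whose C-alpha(i)-C-alpha(i+3) distance is below `turn_dist`; the rest is
#' unordered. Fractions are percentages of resolved residues and sum to 100
#' up to rounding.
#'
#' @param structure a `template_structure` with SSE labels.
#' @param turn_dist turn closure distance in Angstrom (default 7).
#' @return tibble(class, n_residues, percent) for helix/strand/turn/unordered.
#' @export
sse_fractions <- function(structure, turn_dist = 7) {
  idx <- which(structure$resolved)
  sse <- structure$sse[idx]
  ca <- structure$ca[idx, , drop = FALSE]
  n <- length(idx)
  turn <- rep(FALSE, n)
  if (n >= 4) {
    for (i in seq_len(n - 3)) {
      win <- i:(i + 3)
      if (all(sse[win] == "C") && pt_dist(ca[i, ], ca[i + 3, ]) < turn_dist)
        turn[win] <- TRUE
    }
  }
  cls <- ifelse(sse == "H", "helix",
                ifelse(sse == "E", "strand",
                       ifelse(turn, "turn", "unordered")))
  out <- tibble(class = c("helix", "strand", "turn", "unordered"))
  out$n_residues <- vapply(out$class, function(k) sum(cls == k), integer(1),
                           USE.NAMES = FALSE)
  out$percent <- 100 * out$n_residues / n
  out
}
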