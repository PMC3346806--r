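# Shared fixture world, built once per test run. Seed 100 defines the toy
# study conditions: 5 chemokine-like folds, 4 distinct control folds,
# potentials trained on all 9.
fixture_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set <- make_fixture_fold_set(100)
      cache <<- list(
        set = set,
        chemokine = build_chemokine_library(set[1:5]),
        foldspace = build_foldspace_library(set),
        potentials = derive_potentials(set)
      )
    }
    cache
  }
})

# Minimal hand-built template: explicit CA/CB coordinates, no SSE.
mini_template <- function(ca, cb, aa = NULL, sse = NULL) {
  n <- nrow(ca)
  new_template_structure("MINI", "A",
                         aa %||% rep("A", n), ca, cb, sse = sse)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force re-check of the three disulfide criteria for a
# single anchor combination (used as the oracle against check_pair).
brute_pair_check <- function(ca1, cb1, ca2, cb2, i, j,
                             d_ca_max = 10, d_cb_max = 9, d_diff_max = 1,
                             min_sep = 3) {
  d_ca <- sqrt(sum((ca1 - ca2)^2))
  d_cb <- sqrt(sum((cb1 - cb2)^2))
  (d_ca <= d_ca_max) && (d_cb <= d_cb_max) &&
    ((d_cb - d_ca) <= d_diff_max) && (abs(j - i) >= min_sep)
}

# Exhaustive enumeration of all matchings on an edge list (independent
# oracle for enumerate_bonds): returns the maximum matching size.
brute_max_matching <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  best <- 0L
  recurse <- function(k, used, size) {
    if (k > nrow(edges)) {
      best <<- max(best, size)
      return(invisible())
    }
    recurse(k + 1L, used, size)  # skip edge k
    a <- edges[k, 1]; b <- edges[k, 2]
    if (!(a %in% used) && !(b %in% used)) {
      recurse(k + 1L, c(used, a, b), size + 1L)
    }
  }
  recurse(1L, integer(), 0L)
  best
}

ideal_helix_ca_eval <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  k <- seq_len(n) - 1
  cbind(rise * k, radius * cos(k * twist * pi / 180),
        radius * sin(k * twist * pi / 180))
}

# All-pairs disulfide mapping over a random cysteine geometry; returns the
# bond count (thresholds forwarded to check_pair).
map_disulfides_on <- function(g, ...) {
  n <- nrow(g$template$ca)
  combos <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    check_pair(a, b, i = g$qpos[a], j = g$qpos[b], template = g$template, ...)
  })
  enumerate_bonds(dplyr::bind_rows(rows))$bond_count
}

# A random toy geometry of n cysteines with coordinates in a box, returning
# a template plus the cysteine positions (used by the oracle suites).
random_cys_geometry <- function(n_cys, seed, spread = 12) {
  set.seed(seed)
  n <- n_cys
  ca <- matrix(runif(3 * n, 0, spread), n, 3)
  cb <- ca + matrix(stats::rnorm(3 * n, 0, 1.2), n, 3)
  # cysteine query positions with random spacing >= 1
  qpos <- cumsum(sample(1:5, n, replace = TRUE))
  list(template = mini_template(ca, cb, aa = rep("C", n)), qpos = qpos)
}
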