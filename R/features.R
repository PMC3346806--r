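# Monoisotopic atomic masses (IUPAC/CODATA) and isotope distributions.
MONO_MASS <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
MASS_H2O <- 18.0105646863
MASS_H <- 1.0078250319

# residue (= amino acid minus water) elemental compositions, C/H/N/O/S
RESIDUE_FORMULA <- list(
  A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0)
)
ELEMENTS <- c("C", "H", "N", "O", "S")

# isotope mass/abundance tables per element (lightest first)
ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548378), abund = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017780), abund = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984), abund = c(0.99632, 0.00368)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abund = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
           abund = c(0.9493, 0.0076, 0.0429, 0.0002))
)

peptide_formula <- function(sequence, n_disulfides = 0) {
  chars <- aa_chars(toupper(sequence))
  if (any(chars == "X")) {
    stop_scan("sequence contains ambiguous residue X at position(s) %s",
              paste(which(chars == "X"), collapse = ", "))
  }
  bad <- setdiff(unique(chars), names(RESIDUE_FORMULA))
  if (length(bad) > 0) stop_scan("non-standard residue(s): %s", paste(bad, collapse = ", "))
  counts <- Reduce(`+`, lapply(chars, function(a) RESIDUE_FORMULA[[a]]))
  names(counts) <- ELEMENTS
  counts["H"] <- counts["H"] + 2  # free, unmodified termini: + H2O
  counts["O"] <- counts["O"] + 1
  counts["H"] <- counts["H"] - 2 * n_disulfides
  counts
}

#' Theoretical monoisotopic mass of a peptide with disulfide bonds
#'
#' Sum of residue monoisotopic masses plus water (free, unmodified termini),
#' minus two hydrogens per disulfide bond.
#'
#' @param sequence one-letter amino-acid string (standard residues only; X
#'   raises an error listing the positions).
#' @param n_disulfides number of disulfide bonds (needs >= 2 cysteines each).
#' @param experimental_mass optional measured monoisotopic mass (Da) for a
#'   delta-mass report.
#' @return object of class `mass_result`: `mass` (Da), `formula` (element
#'   counts), `n_disulfides`, `delta` (experimental - theoretical, Da or NA).
#' @export
monoisotopic_mass <- function(sequence, n_disulfides = 0,
                              experimental_mass = NULL) {
  chars <- aa_chars(toupper(sequence))
  ncys <- sum(chars == "C")
  if (ncys < 2 * n_disulfides) {
    stop_scan("%d disulfide bond(s) need %d cysteines; sequence has %d",
              n_disulfides, 2 * n_disulfides, ncys)
  }
  f <- peptide_formula(sequence, n_disulfides)
  mass <- sum(f * MONO_MASS[ELEMENTS])
  structure(list(mass = mass, formula = f, n_disulfides = n_disulfides,
                 delta = if (is.null(experimental_mass)) NA_real_
                         else experimental_mass - mass),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("<mass_result> %.4f Da (%s), %d disulfide bond(s)%s\n",
              x$mass,
              paste0(ELEMENTS, x$formula, collapse = ""),
              x$n_disulfides,
              if (is.na(x$delta)) "" else sprintf(", delta-m %+.4f Da", x$delta)))
  invisible(x)
}

# convolution of two isotope patterns indexed by nominal neutron offset;
# each bin keeps an abundance-weighted mean mass
convolve_pattern <- function(p1, p2, prune = 1e-12) {
  n1 <- length(p1$abund); n2 <- length(p2$abund)
  nout <- n1 + n2 - 1
  abund <- numeric(nout); msum <- numeric(nout)
  for (i in seq_len(n1)) {
    a <- p1$abund[i] * p2$abund
    k <- i + seq_len(n2) - 1
    abund[k] <- abund[k] + a
    msum[k] <- msum[k] + a * (p1$mass[i] + p2$mass)
  }
  keep <- abund > prune
  keep[1] <- TRUE
  last <- max(which(keep))
  idx <- seq_len(last)
  list(mass = ifelse(abund[idx] > 0, msum[idx] / pmax(abund[idx], 1e-300), 0),
       abund = abund[idx])
}

element_pattern <- function(element, count) {
  iso <- ISOTOPES[[element]]
  # spread isotopes onto nominal-offset grid
  offs <- round(iso$mass - iso$mass[1])
  base <- list(mass = numeric(max(offs) + 1), abund = numeric(max(offs) + 1))
  for (k in seq_along(offs)) {
    base$abund[offs[k] + 1] <- base$abund[offs[k] + 1] + iso$abund[k]
    base$mass[offs[k] + 1] <- iso$mass[k]
  }
  # exponentiation by squaring
  result <- list(mass = 0, abund = 1)
  sq <- base
  while (count > 0) {
    if (count %% 2 == 1) result <- convolve_pattern(result, sq)
    count <- count %/% 2
    if (count > 0) sq <- convolve_pattern(sq, sq)
  }
  result
}

#' Theoretical isotope envelope of a peptide
#'
#' Elemental composition accumulated per residue, then iterative polynomial
#' convolution of the elemental isotope distributions. The first peak mass
#' equals the monoisotopic mass, and abundances are normalized to a maximum
#' of 1.
#'
#' @inheritParams monoisotopic_mass
#' @param min_abundance peaks below this relative abundance are dropped
#'   (default 1e-4).
#' @return tibble(mass, abundance), masses strictly increasing.
#' @export
isotope_pattern <- function(sequence, n_disulfides = 0, min_abundance = 1e-4) {
  mres <- monoisotopic_mass(sequence, n_disulfides)
  f <- mres$formula
  pat <- list(mass = 0, abund = 1)
  for (el in ELEMENTS) {
    if (f[[el]] > 0) pat <- convolve_pattern(pat, element_pattern(el, f[[el]]))
  }
  pat$mass[1] <- mres$mass  # exact monoisotopic for the all-lightest peak
  ab <- pat$abund / max(pat$abund)
  keep <- ab >= min_abundance
  keep[1] <- TRUE
  tibble(mass = pat$mass[keep], abundance = ab[keep])
}

DEFAULT_MOTIFS <- c(
  gag_attachment = "[RK]?SG[GSA]",
  rgd = "RGD",
  n_glycosylation = "N[^P][ST]"
)

#' Scan a sequence for chemokine-relevant linear motifs
#'
#' Defaults: a glycosaminoglycan (GAG) attachment consensus (serine-glycine
#' core with optional basic flank), the RGD integrin-binding motif, and the
#' N-glycosylation sequon `N[^P][ST]`. Matches per motif are non-overlapping,
#' leftmost-first.
#'
#' @param sequence one-letter amino-acid string.
#' @param motif_set named character vector of regular expressions.
#' @return tibble(motif, pattern, start, end, matched).
#' @export
scan_motifs <- function(sequence, motif_set = DEFAULT_MOTIFS) {
  sequence <- toupper(sequence)
  rows <- lapply(names(motif_set), function(nm) {
    m <- gregexpr(motif_set[[nm]], sequence, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    tibble(motif = nm, pattern = unname(motif_set[[nm]]),
           start = starts, end = starts + lens - 1L,
           matched = substring(sequence, starts, starts + lens - 1L))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(motif = character(), pattern = character(),
                  start = integer(), end = integer(), matched = character())
  }
  out
}

#' Cysteine count, positions and pairwise separations
#'
#' @param sequence one-letter amino-acid string (X never counts).
#' @return list(count, positions (1-based), separations tibble(i, j, sep)).
#' @export
cysteine_stats <- function(sequence) {
  chars <- aa_chars(toupper(sequence))
  pos <- which(chars == "C")
  seps <- if (length(pos) >= 2) {
    cmb <- utils::combn(pos, 2)
    tibble(i = cmb[1, ], j = cmb[2, ], sep = cmb[2, ] - cmb[1, ])
  } else tibble(i = integer(), j = integer(), sep = integer())
  list(count = length(pos), positions = pos, separations = seps)
}
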