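AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "C", PYL = "K")

#' Construct a template structure
#'
#' One polymer chain with per-residue identity, C-alpha/C-beta coordinates and
#' secondary structure labels; the basic unit of a fold library.
#'
#' @param pdb_id,chain_id identifiers.
#' @param aa character vector of one-letter codes (length n).
#' @param ca n x 3 matrix of C-alpha coordinates (Angstrom); NA rows for
#'   unresolved residues.
#' @param cb n x 3 matrix of C-beta coordinates; reconstructed ones flagged in
#'   `cb_virtual`.
#' @param cb_virtual logical vector.
#' @param sse character vector of H/E/C labels (assigned later if NULL).
#' @param scop tibble(family, start, end) of SCOP domain annotations in
#'   residue indices of this chain.
#' @return object of class `template_structure` with `resolved` flags and
#'   fold length `fl` (count of resolved residues).
#' @export
new_template_structure <- function(pdb_id, chain_id, aa, ca, cb,
                                   cb_virtual = NULL, sse = NULL,
                                   scop = NULL) {
  n <- length(aa)
  stopifnot(nrow(ca) == n, nrow(cb) == n)
  resolved <- !is.na(ca[, 1])
  if (!any(resolved)) stop_scan("template %s_%s has no resolved residues", pdb_id, chain_id)
  structure(list(
    pdb_id = pdb_id, chain_id = chain_id, aa = aa,
    ca = ca, cb = cb,
    cb_virtual = cb_virtual %||% rep(FALSE, n),
    resolved = resolved,
    sse = sse %||% rep("C", n),
    scop = scop %||% tibble(family = character(), start = integer(), end = integer()),
    fl = sum(resolved)
  ), class = "template_structure")
}

#' @export
print.template_structure <- function(x, ...) {
  cat(sprintf("<template_structure> %s_%s: %d residues (%d resolved), SSE %s\n",
              x$pdb_id, x$chain_id, length(x$aa), x$fl,
              paste(rle(x$sse)$values, collapse = "")))
  invisible(x)
}

template_name <- function(t) paste0(t$pdb_id, "_", t$chain_id)

native_sequence <- function(t) paste(t$aa[t$resolved], collapse = "")

#' Reconstruct a virtual C-beta from backbone N, CA, C
#'
#' Ideal tetrahedral geometry with a 1.53 Angstrom CA-CB bond, using the
#' standard fixed linear combination of the backbone frame vectors.
#'
#' @param n,ca,c numeric length-3 coordinates.
#' @return length-3 C-beta coordinate.
#' @export
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  v <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  ca + 1.53 * v / sqrt(sum(v^2))
}

#' Parse one chain of a PDB file into a template structure
#'
#' Altloc conflicts are resolved to the highest-occupancy conformer. Missing
#' C-beta atoms (including glycine) are reconstructed from N, CA, C with
#' [virtual_cb()] and flagged; residues lacking a C-alpha are marked
#' unresolved. Only PDB-format files are supported by this reader.
#'
#' @param path PDB file.
#' @param chain_id chain identifier.
#' @param scop optional tibble(family, start, end) of SCOP domains.
#' @return a `template_structure`.
#' @export
parse_structure_chain <- function(path, chain_id, scop = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain[at$type == "ATOM"])
  if (!chain_id %in% chains) {
    stop_scan("chain '%s' not found in %s; available chains: %s",
              chain_id, path, paste(chains, collapse = ", "))
  }
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  # highest-occupancy altloc per (residue, atom name), residues in numeric order
  ins <- ifelse(is.na(at$insert), "", at$insert)
  at <- at[order(at$resno, ins, at$elety, -replace(at$o, is.na(at$o), 1)), ,
           drop = FALSE]
  at <- at[!duplicated(paste(at$resno, ins, at$elety)), , drop = FALSE]

  ins <- ifelse(is.na(at$insert), "", at$insert)
  rkey <- paste(at$resno, ins)
  resids <- unique(rkey)
  n <- length(resids)
  aa <- character(n)
  ca <- matrix(NA_real_, n, 3)
  cb <- matrix(NA_real_, n, 3)
  cbv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ri <- at[rkey == resids[i], , drop = FALSE]
    aa[i] <- unname(AA3TO1[ri$resid[1]] %||% "X")
    if (is.na(aa[i])) aa[i] <- "X"
    getxyz <- function(name) {
      r <- ri[ri$elety == name, , drop = FALSE]
      if (nrow(r) == 0) return(NULL)
      c(r$x[1], r$y[1], r$z[1])
    }
    pca <- getxyz("CA")
    if (is.null(pca)) next  # unresolved
    ca[i, ] <- pca
    pcb <- getxyz("CB")
    if (!is.null(pcb)) {
      cb[i, ] <- pcb
    } else {
      pn <- getxyz("N"); pc <- getxyz("C")
      if (!is.null(pn) && !is.null(pc)) {
        cb[i, ] <- virtual_cb(pn, pca, pc)
        cbv[i] <- TRUE
      } else {
        cb[i, ] <- pca  # CA fallback when backbone incomplete
        cbv[i] <- TRUE
      }
    }
  }
  pdb_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  t <- new_template_structure(pdb_id, chain_id, aa, ca, cb, cbv, scop = scop)
  assign_sse(t)
}

#' Assign secondary structure from C-alpha geometry
#'
#' Helix (H) by the i,i+3 / i,i+4 C-alpha distance signature of an alpha
#' helix; strand (E) by local chain extension plus spatial proximity to a
#' partner extended segment (no strand without pairing). Elements shorter
#' than `min_len` are relabelled coil. An external per-residue label file
#' (TSV: index, label) overrides the built-in assignment.
#'
#' @param template a `template_structure`.
#' @param labels_file optional TSV with columns residue index, label (H/E/C).
#' @param min_len minimum element length (default 3).
#' @return the template with the `sse` field filled.
#' @export
assign_sse <- function(template, labels_file = NULL, min_len = 3) {
  n <- length(template$aa)
  if (!is.null(labels_file)) {
    d <- read.table(labels_file, sep = "\t", header = FALSE,
                    col.names = c("idx", "label"),
                    colClasses = c("integer", "character"))
    sse <- rep("C", n)
    sse[d$idx] <- toupper(d$label)
    template$sse <- sse
    return(template)
  }
  idx <- which(template$resolved)
  sse <- rep("C", n)
  if (length(idx) < 5) {
    template$sse <- sse
    return(template)
  }
  ca <- template$ca
  d_seq <- function(i, k) {
    j <- i + k
    if (j > n || !template$resolved[i] || !template$resolved[j]) return(NA_real_)
    pt_dist(ca[i, ], ca[j, ])
  }
  helix <- rep(FALSE, n)
  for (i in seq_len(n - 4)) {
    d3 <- d_seq(i, 3); d4 <- d_seq(i, 4)
    if (!is.na(d3) && !is.na(d4) &&
        d3 >= 4.5 && d3 <= 6.1 && d4 >= 5.0 && d4 <= 7.0) {
      helix[i:(i + 4)] <- TRUE
    }
  }
  # extension: local CA(i-1),CA(i+1) span typical of beta conformation
  extended <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (helix[i]) next
    d2 <- if (template$resolved[i - 1] && template$resolved[i + 1])
      pt_dist(ca[i - 1, ], ca[i + 1, ]) else NA_real_
    if (!is.na(d2) && d2 >= 6.0) extended[i] <- TRUE
  }
  # pairing: an extended residue needs a non-local extended partner within 5.5 A
  ext_idx <- which(extended)
  strand <- rep(FALSE, n)
  if (length(ext_idx) >= 2) {
    dm <- as.matrix(dist(ca[ext_idx, , drop = FALSE]))
    for (a in seq_along(ext_idx)) {
      partners <- abs(ext_idx[a] - ext_idx) >= 3 & dm[a, ] <= 5.5
      if (any(partners)) strand[ext_idx[a]] <- TRUE
    }
  }
  sse[helix] <- "H"
  sse[strand & !helix] <- "E"
  # enforce minimum element length
  r <- rle(sse)
  r$values[r$values != "C" & r$lengths < min_len] <- "C"
  sse <- inverse.rle(r)
  template$sse <- sse
  template
}

#' Secondary structure elements of a template
#'
#' @param template a `template_structure`.
#' @param min_len minimum element length to report (default 3).
#' @return tibble(type, start, end) for H/E runs.
#' @export
sse_elements <- function(template, min_len = 3) {
  r <- rle(template$sse)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "C" & r$lengths >= min_len
  tibble(type = r$values[keep], start = starts[keep], end = ends[keep])
}

#' Write a template structure to a minimal PDB file
#'
#' Emits CA and CB ATOM records (the atoms the screening engine consumes);
#' unresolved residues are omitted, which round-trips through
#' [parse_structure_chain()].
#'
#' @param template a `template_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_template_pdb <- function(template, path) {
  aa1to3 <- setNames(names(AA3TO1)[1:20], unname(AA3TO1[1:20]))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_along(template$aa)) {
    if (!template$resolved[i]) next
    res3 <- aa1to3[template$aa[i]] %||% "UNK"
    if (is.na(res3)) res3 <- "UNK"
    for (atom in c("CA", "CB")) {
      xyz <- if (atom == "CA") template$ca[i, ] else template$cb[i, ]
      if (any(is.na(xyz))) next
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, atom, res3, template$chain_id, i, xyz[1], xyz[2], xyz[3]), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
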