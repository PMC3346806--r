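#' Read candidate protein sequences from a FASTA file
#'
#' Parses UniProt-style headers (`sp|ACC|NAME` or `tr|ACC|NAME`); for other
#' headers the first whitespace-separated token becomes the id and the
#' accession is left empty. Residues are sanitized under the package policy
#' (U to C, O to K, ambiguity codes to X).
#'
#' @param path FASTA file.
#' @return list of `sequence_record` objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_scan("FASTA file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(list())
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    hdr <- headers[[i]]
    tok <- strsplit(hdr, "\\s+")[[1]][1]
    acc <- ""
    id <- tok
    m <- regmatches(tok, regexec("^(?:sp|tr)\\|([^|]+)\\|(\\S*)", tok))[[1]]
    if (length(m) == 3) {
      acc <- m[2]
      id <- if (nzchar(m[3])) m[3] else m[2]
    }
    desc <- sub("^\\S+\\s*", "", hdr)
    new_sequence_record(id = id, accession = acc, description = desc,
                        residues = as.character(set[[i]]))
  })
}

#' Construct a sequence record
#'
#' @param id record identifier.
#' @param accession UniProt-style accession, possibly empty.
#' @param description free-text description (used by [keyword_filter()]).
#' @param residues one-letter amino-acid string.
#' @param parent_start 1-based position of residue 1 in the untrimmed parent.
#' @param trim_log tibble of removed regions (kind, start, end, confidence),
#'   in parent coordinates.
#' @return object of class `sequence_record`.
#' @export
new_sequence_record <- function(id, accession = "", description = "",
                                residues, parent_start = 1L,
                                trim_log = NULL) {
  s <- sanitize_residues(residues)
  if (parent_start < 1) stop_scan("parent_start must be >= 1")
  structure(list(
    id = id, accession = accession, description = description,
    residues = s$residues, n_nonstandard = s$n_nonstandard,
    parent_start = as.integer(parent_start),
    trim_log = trim_log %||% tibble(kind = character(), start = integer(),
                                    end = integer(), confidence = character())
  ), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s%s (%d aa, %d Cys, parent_start %d)\n",
              x$id, if (nzchar(x$accession)) paste0(" [", x$accession, "]") else "",
              nchar(x$residues), cys_count(x$residues), x$parent_start))
  invisible(x)
}

cys_count <- function(residues) sum(aa_chars(residues) == "C")

#' Keep records whose description carries an "uncharacterized" keyword
#'
#' Whole-word, case-insensitive match against the description, mirroring the
#' selection of proteins labelled unknown/orf/hypothetical/uncharacterized/
#' putative in sequence databases.
#'
#' @param records list of `sequence_record`.
#' @param keywords character vector of keywords.
#' @return the subset of `records` (order preserved) with >= 1 keyword.
#' @export
keyword_filter <- function(records,
                           keywords = c("unknown", "orf", "hypothetical",
                                        "uncharacterized", "putative")) {
  pat <- paste0("\\b(", paste(keywords, collapse = "|"), ")\\b")
  keep <- vapply(records, function(r)
    grepl(pat, r$description, ignore.case = TRUE, perl = TRUE), logical(1))
  records[keep]
}

#' Cysteine-content and length filter
#'
#' A functional IL8-like chemokine fold needs disulfide bonds, hence at least
#' two cysteines, and a minimal sequence length. X residues (ambiguity codes)
#' do not count as cysteines.
#'
#' @param record a `sequence_record`.
#' @param min_cys minimum number of cysteines (default 2).
#' @param min_len minimum sequence length in residues (default 55).
#' @return list(pass = logical, reason = character): reason names the failing
#'   criterion ("length" / "cysteines"), or "" on pass.
#' @export
cys_length_filter <- function(record, min_cys = 2, min_len = 55) {
  len <- nchar(record$residues)
  ncys <- cys_count(record$residues)
  if (len < min_len) return(list(pass = FALSE, reason = "length"))
  if (ncys < min_cys) return(list(pass = FALSE, reason = "cysteines"))
  list(pass = TRUE, reason = "")
}

HITS_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Parse a 12-column tabular homology hit file (outfmt-6 dialect)
#'
#' @param path tab-separated file with columns qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore, no header.
#' @param similarity_col column used as the similarity measure (default
#'   "pident"; the standard tabular format reports percent identity).
#' @return tibble with query_id, subject_id, percent_similarity,
#'   alignment_length, evalue.
#' @export
parse_homology_hits <- function(path, similarity_col = "pident") {
  if (!file.exists(path)) stop_scan("hit file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_similarity = numeric(), alignment_length = integer(),
                  evalue = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop_scan("hit file %s: line %d has %d columns, expected 12",
              path, which(nf != 12)[1], nf[nf != 12][1])
  }
  m <- do.call(rbind, fields)
  colnames(m) <- HITS_COLS
  tibble(
    query_id = m[, "qseqid"],
    subject_id = m[, "sseqid"],
    percent_similarity = as.numeric(m[, similarity_col]),
    alignment_length = as.integer(m[, "length"]),
    evalue = as.numeric(m[, "evalue"])
  )
}

#' Discard records already annotated by homology
#'
#' A record is considered structurally annotated (and discarded) if any hit
#' is longer than `min_len` residues with e-value <= `max_eval` and
#' similarity > `min_sim` percent.
#'
#' @param record a `sequence_record`.
#' @param hits tibble as returned by [parse_homology_hits()], already
#'   restricted to this record's query id.
#' @param min_len alignment length threshold (strictly greater; default 50).
#' @param max_eval e-value ceiling (inclusive; default 0.0005).
#' @param min_sim similarity threshold in percent (strictly greater; default 30).
#' @return list(keep = logical, hit = one-row tibble of the triggering hit or NULL).
#' @export
annotation_filter <- function(record, hits, min_len = 50, max_eval = 5e-4,
                              min_sim = 30) {
  if (is.null(hits) || nrow(hits) == 0) return(list(keep = TRUE, hit = NULL))
  trig <- hits$alignment_length > min_len &
    hits$evalue <= max_eval &
    hits$percent_similarity > min_sim
  if (!any(trig)) return(list(keep = TRUE, hit = NULL))
  list(keep = FALSE, hit = hits[which(trig)[1], , drop = FALSE])
}

#' Read per-sequence signal-peptide predictions from a 3-column TSV
#'
#' Columns: id, cleavage position (last residue of the signal peptide; 0 or
#' "-" when no signal peptide is predicted), score.
#'
#' @param path TSV file, no header.
#' @return tibble(id, has_sp, cleavage_pos, score).
#' @export
read_sp_predictions <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("id", "pos", "score"),
                  colClasses = c("character", "character", "numeric"))
  pos <- suppressWarnings(as.integer(d$pos))
  pos[is.na(pos)] <- 0L
  tibble(id = d$id, has_sp = pos > 0L, cleavage_pos = pos, score = d$score)
}

#' Read per-sequence transmembrane predictions from a 3-column TSV
#'
#' Columns: id, comma-separated intervals like "10-30,45-67" ("-" for none),
#' score.
#'
#' @param path TSV file, no header.
#' @return tibble(id, intervals (list of 2-column matrices), score).
#' @export
read_tm_predictions <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("id", "pos", "score"),
                  colClasses = c("character", "character", "numeric"))
  iv <- lapply(d$pos, function(p) {
    p <- trimws(p)
    if (!nzchar(p) || p == "-" || p == "0") {
      return(matrix(integer(), ncol = 2))
    }
    parts <- strsplit(p, ",", fixed = TRUE)[[1]]
    se <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE),
                                function(x) as.integer(x[1:2])))
    se
  })
  tibble(id = d$id, intervals = iv, score = d$score)
}

#' Consensus signal-peptide call from two predictors
#'
#' Confidence grouping: `high` when both methods predict a signal peptide and
#' their cleavage positions agree within 3 residues (the region ends at the
#' smaller cleavage position); `medium` when both predict but disagree by more
#' than 3; `low` when exactly one predicts.
#'
#' @param predA,predB lists with `has_sp` (logical), `cleavage_pos` (1-based
#'   last signal-peptide residue) and optionally `score`.
#' @param max_disagree maximal cleavage-site disagreement for high confidence.
#' @return one-row tibble(kind, start, end, confidence) or NULL when neither
#'   method predicts a signal peptide.
#' @export
consensus_signal_peptide <- function(predA, predB, max_disagree = 3) {
  chk <- function(p) {
    if (isTRUE(p$has_sp) && (is.na(p$cleavage_pos) || p$cleavage_pos <= 0))
      stop_scan("cleavage_pos must be positive when a signal peptide is predicted")
  }
  chk(predA); chk(predB)
  a <- isTRUE(predA$has_sp); b <- isTRUE(predB$has_sp)
  if (!a && !b) return(NULL)
  if (a && b) {
    conf <- if (abs(predA$cleavage_pos - predB$cleavage_pos) <= max_disagree)
      "high" else "medium"
    end <- min(predA$cleavage_pos, predB$cleavage_pos)
  } else {
    conf <- "low"
    end <- if (a) predA$cleavage_pos else predB$cleavage_pos
  }
  tibble(kind = "signal_peptide", start = 1L, end = as.integer(end),
         confidence = conf)
}

merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(integer(), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

#' Consensus transmembrane regions from two predictors
#'
#' Each method's intervals are merged internally, then the consensus is the
#' intersection of the two methods' predictions. Confidence follows the
#' consensus length L: most genuine TM helices are 17-25 residues long, so
#' `high` for 17 <= L <= 25, `medium` for 12 <= L < 17 or 25 < L <= 35, `low`
#' otherwise.
#'
#' @param predA,predB integer matrices with columns start, end (1-based
#'   inclusive), one row per predicted TM segment.
#' @return tibble(kind, start, end, confidence), possibly empty.
#' @export
consensus_transmembrane <- function(predA, predB) {
  a <- merge_intervals(predA)
  b <- merge_intervals(predB)
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- max(a[i, 1], b[j, 1])
      e <- min(a[i, 2], b[j, 2])
      if (s <= e) out[[length(out) + 1]] <- c(s, e)
    }
  }
  if (length(out) == 0) {
    return(tibble(kind = character(), start = integer(), end = integer(),
                  confidence = character()))
  }
  m <- merge_intervals(do.call(rbind, out))
  L <- m[, 2] - m[, 1] + 1L
  conf <- ifelse(L >= 17 & L <= 25, "high",
                 ifelse((L >= 12 & L < 17) | (L > 25 & L <= 35),
                        "medium", "low"))
  tibble(kind = "transmembrane", start = as.integer(m[, 1]),
         end = as.integer(m[, 2]), confidence = conf)
}

#' Excise signal-peptide and transmembrane regions from a record
#'
#' Signal peptides are removed only at high confidence; transmembrane regions
#' at high or medium confidence. After excision the longest remaining
#' contiguous segment becomes the new record (ties broken toward the
#' C-terminal segment, where chemokine domains typically sit); `parent_start`
#' is updated and all removed regions are appended to the trim log in parent
#' coordinates.
#'
#' @param record a `sequence_record`.
#' @param regions tibble(kind, start, end, confidence) in current record
#'   coordinates, e.g. from [consensus_signal_peptide()] and
#'   [consensus_transmembrane()].
#' @return trimmed `sequence_record` (identical record if nothing qualifies).
#' @export
apply_region_removal <- function(record, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(record)
  len <- nchar(record$residues)
  if (any(regions$start < 1 | regions$end > len | regions$start > regions$end))
    stop_scan("region outside sequence bounds (length %d)", len)
  qual <- (regions$kind == "signal_peptide" & regions$confidence == "high") |
    (regions$kind == "transmembrane" & regions$confidence %in% c("high", "medium"))
  regions <- regions[qual, , drop = FALSE]
  if (nrow(regions) == 0) return(record)

  removed <- logical(len)
  for (k in seq_len(nrow(regions))) removed[regions$start[k]:regions$end[k]] <- TRUE

  # longest kept contiguous segment; ties toward the C-terminal one
  r <- rle(removed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kept <- which(!r$values)
  if (length(kept) == 0) stop_scan("region removal would leave an empty sequence")
  best <- kept[max(which(r$lengths[kept] == max(r$lengths[kept])))]
  s <- starts[best]; e <- ends[best]

  chars <- aa_chars(record$residues)
  off <- record$parent_start - 1L
  new_log <- tibble(kind = regions$kind,
                    start = as.integer(regions$start + off),
                    end = as.integer(regions$end + off),
                    confidence = regions$confidence)
  rec <- new_sequence_record(
    id = record$id, accession = record$accession,
    description = record$description,
    residues = paste(chars[s:e], collapse = ""),
    parent_start = record$parent_start + s - 1L,
    trim_log = bind_rows(record$trim_log, new_log)
  )
  rec
}
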