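#' @useDynLib chemoscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows desc filter group_by mutate n slice
#'   summarise ungroup left_join row_number
#' @importFrom purrr map map_dbl map_chr map_lgl map_int
#' @importFrom rlang .data
#' @importFrom stats sd cor setNames dist runif
#' @importFrom utils head read.table write.table
NULL

# The 20 standard one-letter codes, alphabetical by letter.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Sanitize a raw amino-acid string
#'
#' Non-standard codes are mapped to the policy used throughout the package:
#' selenocysteine (U) to C, pyrrolysine (O) to K; the ambiguity codes B, Z, J
#' and X are kept as X and excluded from cysteine counts and mass computation.
#'
#' @param x character scalar of one-letter residue codes.
#' @return list with `residues` (cleaned string) and `n_nonstandard`.
#' @keywords internal
sanitize_residues <- function(x) {
  x <- toupper(gsub("[\\s*]", "", x, perl = TRUE))
  chars <- strsplit(x, "")[[1]]
  chars[chars == "U"] <- "C"
  chars[chars == "O"] <- "K"
  nonstd <- !(chars %in% AA20)
  chars[nonstd] <- "X"
  list(residues = paste(chars, collapse = ""), n_nonstandard = sum(nonstd))
}

aa_chars <- function(x) strsplit(x, "")[[1]]

#' Euclidean distance between two 3D points
#' @keywords internal
pt_dist <- function(a, b) sqrt(sum((a - b)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scan <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
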