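#' @useDynLib nullomeR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Alphabet registry.  DNA words live over {A,C,G,T} with N the invalid
# marker; peptide words live over the 20 standard amino acids with X the
# nonstandard marker (B, J, O, U, Z, * and friends are all mapped to X at
# ingestion).  Caps keep the dense presence bitmap within a few hundred MB.
DNA_LETTERS <- "ACGT"
AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWY"

alpha_info <- function(alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    list(alphabet = "dna", letters = DNA_LETTERS, size = 4L, invalid = "N",
         max_k = 15L)
  } else {
    list(alphabet = "protein", letters = AA_LETTERS, size = 20L, invalid = "X",
         max_k = 7L)
  }
}

alpha_chars <- function(alphabet) strsplit(alpha_info(alphabet)$letters, "")[[1]]

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# run `code` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream"
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

`%chin%` <- data.table::`%chin%`
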