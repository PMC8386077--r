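#' Scan sequences into a dense k-mer presence map
#'
#' Marks every k-mer occurring as a window of valid residues in any input
#' sequence.  Windows never span sequence boundaries and windows containing
#' an invalid residue (N for DNA, X for protein) are skipped.  In
#' `strand_mode = "both"` (DNA only) a word is marked present when it or its
#' reverse complement occurs, so the presence set is closed under reverse
#' complementation.
#'
#' The map addresses the full word space of size `4^k` (DNA, k <= 15) or
#' `20^k` (protein, k <= 7) as a packed bitmap; at the caps this costs
#' 128 MB and 160 MB respectively.
#'
#' @param sequences character vector of sequences (a `contig_set` or a
#'   `compartment_extract` is also accepted).
#' @param k word length; at most 15 for DNA, 7 for protein.
#' @param alphabet `"dna"` or `"protein"`.
#' @param strand_mode `"both"` (default for DNA) or `"forward"`.  Protein
#'   maps are always forward.
#' @return an object of class `presence_map` with fields `k`, `alphabet`,
#'   `strand_mode`, `n_words`, `n_present` and the packed `bitmap`.
#' @export
scan_presence <- function(sequences, k, alphabet = c("dna", "protein"),
                          strand_mode = c("both", "forward")) {
  ai <- alpha_info(match.arg(alphabet))
  strand_mode <- match.arg(strand_mode)
  sequences <- as_sequences(sequences)
  if (ai$alphabet == "protein") strand_mode <- "forward"
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > ai$max_k)
    stop("k must be a single integer in [1, ", ai$max_k, "] for ",
         ai$alphabet, " scans")
  bitmap <- cpp_scan_presence(sequences, k, ai$letters,
                              strand_mode == "both")
  n_words <- ai$size^k
  structure(
    list(k = k, alphabet = ai$alphabet, strand_mode = strand_mode,
         n_words = n_words,
         n_present = cpp_presence_count(bitmap, n_words),
         bitmap = bitmap),
    class = "presence_map")
}

#' @export
print.presence_map <- function(x, ...) {
  cat(sprintf("presence_map: %s, k=%d, strand=%s\n", x$alphabet, x$k,
              x$strand_mode))
  cat(sprintf("  %s / %s words present (%.4g%% absent)\n",
              format(x$n_present, big.mark = ","),
              format(x$n_words, big.mark = ","),
              100 * (1 - x$n_present / x$n_words)))
  invisible(x)
}

#' Number of absent words in a presence map
#' @param pmap a `presence_map`.
#' @return numeric count `|alphabet|^k - n_present`.
#' @export
nullomer_count <- function(pmap) {
  stopifnot(inherits(pmap, "presence_map"))
  pmap$n_words - pmap$n_present
}

#' Test membership of words in a presence map
#' @param pmap a `presence_map`.
#' @param words character vector of words of length `pmap$k`.
#' @return logical vector.
#' @export
is_present <- function(pmap, words) {
  stopifnot(inherits(pmap, "presence_map"))
  ai <- alpha_info(pmap$alphabet)
  cpp_is_present(pmap$bitmap, words, pmap$k, ai$letters)
}

#' Extract the nullomers (absent words) of a presence map
#'
#' Returns exactly the words never marked present, so that
#' `nrow(result) + n_present == |alphabet|^k`.  In both-strand mode the set
#' is closed under reverse complementation.
#'
#' @param pmap a `presence_map`.
#' @param compartment label recorded with each record (e.g. `"genome"`,
#'   `"promoter"`).
#' @param max_words refuse to materialize more than this many words
#'   (the count is still available through [nullomer_count()]).
#' @return data.frame with columns `word`, `k`, `compartment`, `order`
#'   (`NA` until [classify_order()] is applied).
#' @export
find_nullomers <- function(pmap, compartment = "genome", max_words = 2e6) {
  stopifnot(inherits(pmap, "presence_map"))
  ai <- alpha_info(pmap$alphabet)
  words <- cpp_absent_words(pmap$bitmap, pmap$k, ai$letters, max_words)
  data.frame(word = words,
             k = rep.int(pmap$k, length(words)),
             compartment = rep.int(compartment, length(words)),
             order = rep.int(NA_integer_, length(words)),
             stringsAsFactors = FALSE)
}

#' Count overlapping occurrences of target words
#'
#' In both-strand mode a window is credited to a target when it matches the
#' target or its reverse complement; a palindromic match is counted once per
#' window.  Absent targets get a count of 0.
#'
#' @param sequences character vector of sequences.
#' @param target_words character vector of same-length words.
#' @param strand_mode `"both"` or `"forward"`.
#' @param alphabet `"dna"` or `"protein"`.
#' @return named numeric vector of counts, one per target.
#' @export
count_occurrences <- function(sequences, target_words,
                              strand_mode = c("both", "forward"),
                              alphabet = c("dna", "protein")) {
  ai <- alpha_info(match.arg(alphabet))
  strand_mode <- match.arg(strand_mode)
  if (ai$alphabet == "protein") strand_mode <- "forward"
  sequences <- as_sequences(sequences)
  if (length(target_words) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (length(unique(nchar(target_words))) != 1L)
    stop("target words must all have the same length")
  cpp_count_occurrences(sequences, target_words, ai$letters,
                        strand_mode == "both")
}

#' Single-substitution Hamming neighbours of a word
#'
#' @param word a single word.
#' @param alphabet `"dna"` or `"protein"`.
#' @return character vector of the `(|alphabet|-1) * nchar(word)` distinct
#'   words differing from `word` at exactly one position.
#' @export
hamming_neighbors <- function(word, alphabet = c("dna", "protein")) {
  ai <- alpha_info(match.arg(alphabet))
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  letters <- alpha_chars(ai$alphabet)
  out <- character(0)
  for (i in seq_along(chars)) {
    for (l in letters[letters != chars[i]]) {
      w <- chars
      w[i] <- l
      out <- c(out, paste(w, collapse = ""))
    }
  }
  out
}

# all words within substitution-Hamming distance exactly d (BFS frontier)
hamming_ball_frontier <- function(words, alphabet) {
  unique(unlist(lapply(words, hamming_neighbors, alphabet = alphabet)))
}

#' Classify the order of nullomers
#'
#' The order of an absent word is the largest `i <= max_order` such that
#' every word within substitution-Hamming distance `i` is also absent: a
#' plain nullomer with at least one present neighbour has order 0; a
#' first-order nullomer needs more than one substitution before a present
#' word is reached.
#'
#' @param words character vector of absent words.
#' @param pmap the `presence_map` the words are absent from.
#' @param max_order cap on the classification depth (neighbourhood size
#'   grows combinatorially with distance).
#' @return integer vector of orders in `[0, max_order]`.
#' @export
classify_order <- function(words, pmap, max_order = 2L) {
  stopifnot(inherits(pmap, "presence_map"))
  if (length(words) == 0L) return(integer(0))
  if (any(is_present(pmap, words)))
    stop("classify_order() called on a word present in the map")
  vapply(words, function(w) {
    frontier <- w
    seen <- w
    for (d in seq_len(max_order)) {
      frontier <- setdiff(hamming_ball_frontier(frontier, pmap$alphabet), seen)
      if (length(frontier) == 0L) return(as.integer(max_order))
      if (any(is_present(pmap, frontier))) return(d - 1L)
      seen <- c(seen, frontier)
    }
    as.integer(max_order)
  }, integer(1), USE.NAMES = FALSE)
}

# normalize the various sequence containers to a plain character vector
as_sequences <- function(x) {
  if (inherits(x, "compartment_extract")) x <- x$sequences
  if (inherits(x, "contig_set")) x <- unclass(x)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be a character vector")
  x
}
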