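# shared helpers: random sequences, canonical event frames, k-let counting

rand_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# order-independent canonical form of a mutation-event frame
canon_events <- function(d) {
  d <- as.data.frame(d)
  d$mat <- vapply(d$materialized, function(w) paste(sort(w), collapse = ","),
                  character(1))
  d <- d[order(d$contig, d$pos, d$mclass, d$ref, d$alt),
         c("contig", "pos", "ref", "alt", "mclass", "mat")]
  rownames(d) <- NULL
  d
}

# forward-strand k-let count vector (sorted by word), via the compiled
# counter so conservation checks stay fast
klet_vec <- function(x, k, letters = "ACGT") {
  l <- nullomeR:::cpp_klet_counts(x, k, letters)
  v <- stats::setNames(l$count, l$word)
  v[order(names(v))]
}

# brute-force nullomer order from an explicit absent-word set
order_bruteforce <- function(word, absent_set, max_order = 2L,
                             alphabet = "dna") {
  frontier <- word
  seen <- word
  for (d in seq_len(max_order)) {
    frontier <- setdiff(
      unique(unlist(lapply(frontier, hamming_neighbors, alphabet = alphabet))),
      seen)
    if (length(frontier) == 0L) return(max_order)
    if (!all(frontier %in% absent_set)) return(d - 1L)
    seen <- c(seen, frontier)
  }
  max_order
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
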