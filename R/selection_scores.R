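# Negative-selection scoring of absent words.
#
# phi1: mean occurrence count of the (|alphabet|-1)*k single-substitution
#       neighbours of an absent word over the search space.
# phi2: mean occurrence count over R Monte Carlo k-let preserving shuffles
#       of the compartment.
# phi3: fraction of non-reference species whose compartment contains the
#       word.
# phiN: sum of the per-metric ascending min-ranks (ties share a rank).

#' Substitution-neighbour occurrence score (phi1)
#'
#' The mean number of occurrences, over the search space, of all words one
#' substitution away from an absent word.  phi1 is zero exactly when the
#' word is a first-order (or higher) nullomer.
#'
#' @param word an absent word.
#' @param occurrence_counts named numeric vector covering every
#'   substitution neighbour of `word` (see [count_occurrences()]).
#' @param alphabet `"dna"` or `"protein"`.
#' @return list of class `phi1_score` with `word`, `k`, `value`, and the
#'   per-neighbour `counts`.
#' @export
phi1 <- function(word, occurrence_counts, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  nb <- hamming_neighbors(word, alphabet)
  missing <- setdiff(nb, names(occurrence_counts))
  if (length(missing))
    stop("occurrence_counts is missing ", length(missing),
         " neighbour(s) of ", word, " (e.g. ", missing[1], ")")
  counts <- occurrence_counts[nb]
  structure(list(word = word, k = nchar(word),
                 value = sum(counts) / length(nb), counts = counts),
            class = "phi1_score")
}

#' phi1 for many words against a sequence set
#'
#' Convenience wrapper: counts all substitution neighbours of `words` in
#' `sequences` and returns one phi1 value per word.
#'
#' @inheritParams count_occurrences
#' @param words absent words to score.
#' @return named numeric vector of phi1 values.
#' @export
phi1_scores <- function(words, sequences, strand_mode = c("both", "forward"),
                        alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  strand_mode <- match.arg(strand_mode)
  nb <- lapply(words, hamming_neighbors, alphabet = alphabet)
  counts <- count_occurrences(sequences, unique(unlist(nb)), strand_mode,
                              alphabet)
  vapply(seq_along(words),
         function(i) sum(counts[nb[[i]]]) / length(nb[[i]]),
         numeric(1)) |> stats::setNames(words)
}

#' Distinct permutations of a word's letter multiset
#' @param word a word.
#' @return character vector of distinct rearrangements (identity included).
#' @export
word_permutations <- function(word) {
  chars <- sort(strsplit(word, "", fixed = TRUE)[[1]])
  perms <- function(ch) {
    if (length(ch) <= 1L) return(paste(ch, collapse = ""))
    out <- character(0)
    for (u in unique(ch)) {
      rest <- ch[-match(u, ch)]
      out <- c(out, paste0(u, perms(rest)))
    }
    out
  }
  perms(chars)
}

#' Permutation-occurrence score for nullpeptides
#'
#' The peptide analogue of phi1: because amino-acid frequencies are highly
#' uneven, a nullpeptide is scored by the occurrence counts of all distinct
#' permutations of its letters (identity included, contributing 0 for an
#' absent word) rather than by substitution neighbours.
#'
#' @param word an absent peptide word.
#' @param proteome_counts named numeric vector of occurrence counts covering
#'   the permutations of `word`; alternatively pass `sequences` to count on
#'   the fly.
#' @param sequences optional proteome sequences used when
#'   `proteome_counts` is missing.
#' @return list of class `permutation_score` with `word`, `n_permutations`,
#'   `mean`, `min`, `max`, `median` and the per-permutation `counts`.
#' @export
phi1_peptide <- function(word, proteome_counts = NULL, sequences = NULL) {
  perms <- word_permutations(word)
  if (is.null(proteome_counts)) {
    if (is.null(sequences))
      stop("provide proteome_counts or sequences")
    proteome_counts <- count_occurrences(sequences, perms, "forward", "protein")
  }
  missing <- setdiff(perms, names(proteome_counts))
  if (length(missing))
    stop("proteome_counts is missing ", length(missing), " permutation(s)")
  counts <- proteome_counts[perms]
  structure(list(word = word, n_permutations = length(perms),
                 mean = mean(counts), min = min(counts), max = max(counts),
                 median = stats::median(counts), counts = counts),
            class = "permutation_score")
}

# --- k-let preserving shuffle ---------------------------------------------

#' Shuffle a sequence preserving its k-let counts
#'
#' `klet = 1` is a uniform permutation of the letters.  `klet = 2` or `3`
#' performs an Euler-path shuffle on the de Bruijn multigraph of
#' `(klet-1)`-mers, producing a uniform random sequence with exactly the
#' input's k-let count vector; the first and last `(klet-1)`-mer are
#' preserved.  Runs of invalid residues (N / X) are kept in place and the
#' valid segments between them are shuffled independently, so the geography
#' of assembly gaps is fixed.
#'
#' @param sequence a single sequence string.
#' @param klet 1, 2 or 3.
#' @param seed optional seed for reproducibility (the caller's RNG stream is
#'   left untouched when a seed is given).
#' @param alphabet `"dna"` or `"protein"`.
#' @return the shuffled sequence string.
#' @export
shuffle_klet <- function(sequence, klet = 2L, seed = NULL,
                         alphabet = c("dna", "protein")) {
  klet <- as.integer(klet)
  if (!klet %in% 1:3) stop("klet must be 1, 2 or 3")
  alphabet <- match.arg(alphabet)
  if (nchar(sequence) < klet)
    stop("sequence shorter than klet")
  with_seed_or_not(seed, {
    ai <- alpha_info(alphabet)
    pat <- sprintf("[^%s]+", ai$letters)
    bad <- gregexpr(pat, sequence)[[1]]
    if (bad[1] == -1L) return(shuffle_segment(sequence, klet))
    # split into valid / invalid runs, shuffle valid runs independently
    starts <- as.integer(bad)
    lens <- attr(bad, "match.length")
    pieces <- character(0)
    cursor <- 1L
    for (i in seq_along(starts)) {
      if (starts[i] > cursor)
        pieces <- c(pieces, shuffle_piece(substring(sequence, cursor,
                                                    starts[i] - 1L), klet))
      pieces <- c(pieces, substring(sequence, starts[i],
                                    starts[i] + lens[i] - 1L))
      cursor <- starts[i] + lens[i]
    }
    if (cursor <= nchar(sequence))
      pieces <- c(pieces, shuffle_piece(substring(sequence, cursor,
                                                  nchar(sequence)), klet))
    paste(pieces, collapse = "")
  })
}

shuffle_piece <- function(piece, klet) {
  if (nchar(piece) < klet) piece else shuffle_segment(piece, klet)
}

# Euler-path shuffle of one fully-valid segment (Altschul-Erickson /
# uShuffle scheme): pick a random last-exit edge per vertex forming an
# arborescence toward the terminal (klet-1)-mer, permute the remaining
# out-edges uniformly, then walk the forced Euler path.
shuffle_segment <- function(segment, klet) {
  n <- nchar(segment)
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  if (klet == 1L) return(paste(sample(chars), collapse = ""))
  m <- klet - 1L
  if (n <= klet) return(segment)
  vstr <- substring(segment, 1:(n - m + 1L), m:n)
  uv <- unique(vstr)
  vid <- match(vstr, uv)
  nv <- length(uv)
  ne <- n - m
  from <- vid[1:ne]
  to <- vid[2:(ne + 1L)]
  ech <- chars[(m + 1L):n]
  last <- vid[ne + 1L]
  edges_of <- split(seq_len(ne), factor(from, levels = seq_len(nv)))

  need <- setdiff(which(lengths(edges_of) > 0L), last)
  last_edge <- rep(NA_integer_, nv)
  ok <- length(need) == 0L
  for (attempt in seq_len(5000L)) {
    if (ok) break
    for (v in need) {
      ev <- edges_of[[v]]
      last_edge[v] <- if (length(ev) == 1L) ev else sample(ev, 1L)
    }
    ok <- arborescence_ok(last_edge, to, last, nv)
  }
  if (!ok) stop("Euler shuffle failed to find an arborescence (pathological input)")

  ord_target <- integer(ne)
  ord_char <- character(ne)
  off <- integer(nv + 1L)
  cursor <- 0L
  for (v in seq_len(nv)) {
    off[v] <- cursor
    ev <- edges_of[[v]]
    if (length(ev)) {
      rest <- if (is.na(last_edge[v])) ev else ev[ev != last_edge[v]]
      if (length(rest) > 1L) rest <- sample(rest)
      ev_ord <- c(rest, if (!is.na(last_edge[v])) last_edge[v])
      ord_target[cursor + seq_along(ev_ord)] <- to[ev_ord] - 1L
      ord_char[cursor + seq_along(ev_ord)] <- ech[ev_ord]
      cursor <- cursor + length(ev_ord)
    }
  }
  off[nv + 1L] <- cursor
  cpp_euler_walk(off, ord_target, paste(ord_char, collapse = ""),
                 vid[1] - 1L, substring(segment, 1L, m))
}

# does following each vertex's chosen last edge always reach `last`?
arborescence_ok <- function(last_edge, to, last, nv) {
  status <- integer(nv)          # 0 unknown, 1 reaches last, 2 on stack
  status[last] <- 1L
  for (v in seq_len(nv)) {
    if (status[v] != 0L) next
    path <- integer(0)
    u <- v
    while (!is.na(u) && status[u] == 0L) {
      status[u] <- 2L
      path <- c(path, u)
      u <- if (is.na(last_edge[u])) NA_integer_ else to[last_edge[u]]
    }
    good <- !is.na(u) && status[u] == 1L
    status[path] <- if (good) 1L else 3L
    if (!good) return(FALSE)
  }
  TRUE
}

#' Monte Carlo shuffle simulation (phi2) and compartment enrichment
#'
#' Shuffles every compartment sequence independently in each of `R`
#' replicates (k-let preserving, see [shuffle_klet()]), counts the
#' occurrences of the requested words per replicate, and compares the
#' observed nullomer count at length `k` with the replicate mean.
#'
#' @param sequences compartment sequences.
#' @param k word length for the nullomer-count enrichment.
#' @param words optional words to score (phi2 = mean occurrences across
#'   replicates); typically the compartment's nullomers.
#' @param klet 1, 2 or 3 (mono-/di-/tri-nucleotide or -peptide content
#'   preserved).
#' @param R number of replicates (the reference analysis uses 100).
#' @param seed master seed; per-replicate shuffles consume the seeded RNG
#'   stream sequentially.
#' @param strand_mode,alphabet as in [scan_presence()].
#' @param label compartment label for the enrichment record.
#' @return list of class `phi2_result` with `scores` (data.frame: `word`,
#'   `phi2`, `phi2_sd`, plus a `replicate_counts` matrix attribute) and
#'   `enrichment` (list: `label`, `k`, `klet`, `R`, `observed`,
#'   `expected`, `sd`, `enrichment = observed / expected`).
#' @export
phi2_simulate <- function(sequences, k, words = NULL, klet = 3L, R = 100L,
                          seed = NULL, strand_mode = c("both", "forward"),
                          alphabet = c("dna", "protein"),
                          label = "compartment") {
  if (R < 1L) stop("R must be >= 1")
  alphabet <- match.arg(alphabet)
  strand_mode <- match.arg(strand_mode)
  if (alphabet == "protein") strand_mode <- "forward"
  sequences <- as_sequences(sequences)
  observed <- nullomer_count(scan_presence(sequences, k, alphabet, strand_mode))
  nw <- length(words)
  word_counts <- matrix(0, nrow = R, ncol = nw,
                        dimnames = list(NULL, words))
  null_counts <- numeric(R)
  with_seed_or_not(seed, {
    for (r in seq_len(R)) {
      shuf <- vapply(sequences, shuffle_klet, character(1), klet = klet,
                     alphabet = alphabet, USE.NAMES = FALSE)
      null_counts[r] <- nullomer_count(
        scan_presence(shuf, k, alphabet, strand_mode))
      if (nw > 0L)
        word_counts[r, ] <- count_occurrences(shuf, words, strand_mode,
                                              alphabet)
    }
  })
  scores <- data.frame(word = words %||% character(0),
                       phi2 = if (nw) colMeans(word_counts) else numeric(0),
                       phi2_sd = if (nw) apply(word_counts, 2, stats::sd)
                                 else numeric(0),
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  attr(scores, "replicate_counts") <- word_counts
  structure(list(
    scores = scores,
    enrichment = list(label = label, k = k, klet = klet, R = R,
                      observed = observed,
                      expected = mean(null_counts),
                      sd = stats::sd(null_counts),
                      replicate_nullomer_counts = null_counts,
                      enrichment = observed / mean(null_counts))),
    class = "phi2_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-species absence ratio (phi3)
#'
#' @param species_presence_flags logical vector: does each non-reference
#'   species' compartment contain the word?
#' @param n number of non-reference species examined (defaults to the
#'   number of flags).
#' @return phi3 = M / n where M is the number of species containing the word.
#' @export
phi3 <- function(species_presence_flags, n = length(species_presence_flags)) {
  if (n == 0L) stop("phi3 needs at least one species")
  sum(species_presence_flags) / n
}

#' Aggregate rank score (phiN)
#'
#' Each metric is ranked ascending with ties sharing the minimal
#' ("competition") rank; phiN is the sum of the three ranks, so the
#' strongest negative-selection candidates have the smallest phiN.  The
#' ordering is invariant under any strictly monotone transform of the
#' individual scores.
#'
#' @param words character vector.
#' @param phi1_values,phi2_values,phi3_values numeric vectors aligned with
#'   `words` (no missing values).
#' @return data.frame sorted ascending by `phiN` with columns `word`,
#'   `phi1`, `phi2`, `phi3`, `rank1`, `rank2`, `rank3`, `phiN`.
#' @export
phiN_rank <- function(words, phi1_values, phi2_values, phi3_values) {
  stopifnot(length(words) == length(phi1_values),
            length(words) == length(phi2_values),
            length(words) == length(phi3_values))
  if (anyNA(phi1_values) || anyNA(phi2_values) || anyNA(phi3_values))
    stop("all three scores must be present for every word")
  r1 <- rank(phi1_values, ties.method = "min")
  r2 <- rank(phi2_values, ties.method = "min")
  r3 <- rank(phi3_values, ties.method = "min")
  out <- data.frame(word = words, phi1 = phi1_values, phi2 = phi2_values,
                    phi3 = phi3_values, rank1 = r1, rank2 = r2, rank3 = r3,
                    phiN = r1 + r2 + r3, stringsAsFactors = FALSE)
  out <- out[order(out$phiN, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop words that resurface through common population variants
#'
#' Words whose aggregate resurfacing probability exceeds the threshold are
#' removed from a [phiN_rank()] table before final ordering; words without
#' a profile are treated as probability 0 and retained.
#'
#' @param ranking data.frame from [phiN_rank()].
#' @param resurfacing_profiles data.frame with `word` and
#'   `aggregate_probability` (see [resurfacing_profiles()]).
#' @param probability_threshold exclusion threshold (default 0.05).
#' @return the filtered ranking.
#' @export
finalize_ranking <- function(ranking, resurfacing_profiles,
                             probability_threshold = 0.05) {
  p <- resurfacing_profiles$aggregate_probability[
    match(ranking$word, resurfacing_profiles$word)]
  p[is.na(p)] <- 0
  out <- ranking[p <= probability_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
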