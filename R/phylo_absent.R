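# Absence-based phylogenetics: Jaccard similarity over per-species
# nullomer / nullpeptide sets, Ward clustering, and clade partitions.

#' Species absence profile
#'
#' @param species species name.
#' @param words the species' nullomer or nullpeptide set (all same length).
#' @param group optional group label (e.g. "primate", "mammal").
#' @return object of class `species_profile`.
#' @export
species_profile <- function(species, words, group = NA_character_) {
  if (length(words) && length(unique(nchar(words))) != 1L)
    stop("profile words must all have the same length")
  structure(list(species = species, group = group, words = unique(words)),
            class = "species_profile")
}

profile_words <- function(x) if (inherits(x, "species_profile")) x$words else x

#' Jaccard index of two word sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 with a warning.
#'
#' @param setA,setB character vectors of equal-length words.
#' @return the Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(setA, setB) {
  setA <- unique(profile_words(setA)); setB <- unique(profile_words(setB))
  if (length(setA) && length(setB) &&
      nchar(setA[1]) != nchar(setB[1]))
    stop("word length mismatch between sets")
  u <- length(unique(c(setA, setB)))
  if (u == 0L) {
    warning("both sets empty; Jaccard defined as 0")
    return(0)
  }
  i <- sum(setA %chin% setB)
  i / u
}

#' Pairwise Jaccard matrix over species profiles
#'
#' @param profiles named list of word sets (or `species_profile` objects;
#'   their `species` fields name the rows).
#' @return symmetric matrix of Jaccard indices with unit diagonal for
#'   non-empty sets.
#' @export
pairwise_jaccard_matrix <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  nms <- names(profiles)
  sp <- vapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (inherits(p, "species_profile")) p$species
    else if (!is.null(nms) && nzchar(nms[i])) nms[i]
    else stop("profiles must be named")
  }, character(1))
  if (anyDuplicated(sp)) stop("duplicate species names")
  n <- length(profiles)
  J <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) {
    wi <- profile_words(profiles[[i]])
    J[i, i] <- if (length(wi)) 1 else 0
    for (j in seq_len(i - 1L)) {
      v <- jaccard_index(wi, profile_words(profiles[[j]]))
      J[i, j] <- v
      J[j, i] <- v
    }
  }
  J
}

#' Hierarchical absence tree from a Jaccard matrix
#'
#' Agglomerative clustering with Ward's criterion on the distance
#' `1 - J` (the `ward.D2` linkage, matching scipy's `ward`).  Species are
#' pre-sorted lexicographically so equidistant merges break ties
#' reproducibly.
#'
#' @param jaccard_matrix symmetric similarity matrix from
#'   [pairwise_jaccard_matrix()].
#' @return object of class `absence_tree`: list with the `hclust` fit and
#'   the `ape::phylo` tree.
#' @export
build_tree <- function(jaccard_matrix) {
  if (!isSymmetric(unname(jaccard_matrix)))
    stop("Jaccard matrix must be symmetric")
  ord <- order(rownames(jaccard_matrix))
  J <- jaccard_matrix[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - J), method = "ward.D2")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc)),
            class = "absence_tree")
}

#' @export
print.absence_tree <- function(x, ...) {
  cat("absence_tree over", length(x$hclust$labels), "species\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Serialize an absence tree to Newick
#'
#' @param tree an `absence_tree`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "absence_tree"))
  if (is.null(path)) ape::write.tree(tree$phylo)
  else invisible(ape::write.tree(tree$phylo, file = path))
}

#' Partition words by the species sharing them
#'
#' Given per-species absence profiles, reports (i) `primes`: words absent
#' from every species (in every profile); (ii) `species_specific`: words
#' absent from exactly one species; (iii) `group_specific`: for each group
#' with at least two members, words absent from all members but present in
#' at least one non-member; and (iv) the sharing histogram (number of words
#' absent from exactly m species, m = 1..n).
#'
#' @param profiles named list of word sets or `species_profile` objects.
#' @param group_map optional named character vector mapping species to a
#'   single group each (defaults to `species_profile` group fields).
#' @return list of class `clade_partition`.
#' @export
clade_partition <- function(profiles, group_map = NULL) {
  if (length(profiles) == 0L) stop("empty profiles")
  words <- lapply(profiles, profile_words)
  nms <- names(profiles)
  sp <- vapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (inherits(p, "species_profile")) p$species else nms[i]
  }, character(1))
  names(words) <- sp
  if (is.null(group_map)) {
    grp <- vapply(profiles, function(p)
      if (inherits(p, "species_profile")) p$group else NA_character_,
      character(1))
    group_map <- stats::setNames(grp, sp)
  }
  universe <- unique(unlist(words, use.names = FALSE))
  m <- vapply(words, function(w) universe %chin% w, logical(length(universe)))
  if (length(universe) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, sp))
  shared_by <- rowSums(m)
  n <- length(words)
  primes <- universe[shared_by == n]
  species_specific <- lapply(stats::setNames(seq_len(n), sp), function(i)
    universe[shared_by == 1L & m[, i]])
  groups <- split(sp, group_map[sp])
  groups <- groups[lengths(groups) >= 2L]
  group_specific <- lapply(groups, function(members) {
    inside <- rowSums(m[, members, drop = FALSE]) == length(members)
    universe[inside & shared_by < n]
  })
  hist <- table(factor(shared_by, levels = seq_len(n)))
  structure(list(n_species = n, primes = primes,
                 species_specific = species_specific,
                 group_specific = group_specific,
                 sharing_histogram = hist),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("clade_partition over", x$n_species, "species:",
      length(x$primes), "prime(s);",
      sum(lengths(x$species_specific)), "species-specific word(s)\n")
  invisible(x)
}

#' Streaming prime detection across many sequence collections
#'
#' Accumulates presence over any number of FASTA files (or in-memory
#' sequence sets) into one shared presence map; words never present
#' anywhere are primes with respect to that universe.
#'
#' @param inputs character vector of FASTA paths, or list of sequence
#'   vectors.
#' @param k word length.
#' @param alphabet,strand_mode as in [scan_presence()].
#' @param max_words reporting cap passed to [find_nullomers()].
#' @return data.frame of prime words (compartment label `"primes"`).
#' @export
find_primes <- function(inputs, k, alphabet = c("dna", "protein"),
                        strand_mode = c("both", "forward"), max_words = 2e6) {
  alphabet <- match.arg(alphabet)
  strand_mode <- match.arg(strand_mode)
  if (alphabet == "protein") strand_mode <- "forward"
  ai <- alpha_info(alphabet)
  pmap <- NULL
  for (inp in inputs) {
    seqs <- if (is.character(inp) && length(inp) == 1L && file.exists(inp))
      as_sequences(read_fasta(inp, alphabet)) else as_sequences(inp)
    pm <- scan_presence(seqs, k, alphabet, strand_mode)
    if (is.null(pmap)) pmap <- pm
    else pmap$bitmap <- pmap$bitmap | pm$bitmap
  }
  pmap$n_present <- cpp_presence_count(pmap$bitmap, pmap$n_words)
  find_nullomers(pmap, compartment = "primes", max_words = max_words)
}
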