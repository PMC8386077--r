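# Intersection of observed population variants with the map of potential
# nullomer-materializing edits, and allele-frequency based resurfacing.

# words newly present after applying one edit to a local window; mirrors
# the convention of cpp_scan_materializing (INS keyed to the gap before pos)
materialized_by_edit <- function(seqstr, type, pos, base, pmap) {
  k <- pmap$k
  n <- nchar(seqstr)
  local <- switch(type,
    SUB = {
      lo <- max(1L, pos - (k - 1L))
      s <- substring(seqstr, lo, min(n, pos + (k - 1L)))
      substr(s, pos - lo + 1L, pos - lo + 1L) <- base
      s
    },
    DEL = paste0(substring(seqstr, max(1L, pos - (k - 1L)), pos - 1L),
                 substring(seqstr, pos + 1L, min(n, pos + k - 1L))),
    INS = paste0(substring(seqstr, max(1L, pos - (k - 1L)), pos - 1L), base,
                 substring(seqstr, pos, min(n, pos + k - 2L))),
    stop("unknown edit type ", type))
  len <- nchar(local)
  if (len < k) return(character(0))
  wins <- substring(local, 1:(len - k + 1L), k:len)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (length(wins) == 0L) return(character(0))
  mat <- unique(wins[!is_present(pmap, wins)])
  if (pmap$strand_mode == "both" && length(mat))
    mat <- unique(c(mat, revcomp(mat)))
  sort(mat)
}

#' Nullomers materialized by observed variants
#'
#' Applies each variant independently to the reference and collects the
#' absent words that become present in a window overlapping the edit.
#' Variants whose REF does not match the genome are skipped (their number
#' is reported in the `n_ref_mismatch` attribute, with a warning).
#'
#' @param genome a `contig_set` or named character vector (DNA).
#' @param variants data.frame from [read_vcf_records()].
#' @param pmap `presence_map` of the genome.
#' @param k word length; must equal `pmap$k`.
#' @return named list mapping each variant-associated word to the
#'   data.frame of its supporting variant records.
#' @export
variant_materialized_nullomers <- function(genome, variants, pmap, k = pmap$k) {
  stopifnot(inherits(pmap, "presence_map"))
  if (k != pmap$k) stop("k does not match the presence map")
  genome <- as_sequences(genome)
  assoc <- list()
  n_mismatch <- 0L
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]
    if (!ctg %in% names(genome)) { n_mismatch <- n_mismatch + 1L; next }
    seqstr <- genome[[ctg]]
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    if (substring(seqstr, pos, pos + nchar(ref) - 1L) != ref) {
      n_mismatch <- n_mismatch + 1L
      next
    }
    edit <- vcf_to_edit(pos, ref, alt)
    if (is.null(edit)) next
    words <- materialized_by_edit(seqstr, edit$type, edit$pos, edit$base, pmap)
    for (w in words) {
      assoc[[w]] <- rbind(assoc[[w]], variants[i, , drop = FALSE])
    }
  }
  if (n_mismatch > 0L)
    warning(n_mismatch, " variant(s) skipped (REF mismatch or unknown contig)")
  attr(assoc, "n_ref_mismatch") <- n_mismatch
  attr(assoc, "k") <- k
  assoc
}

# translate a VCF (pos, ref, alt) into the package's edit convention
vcf_to_edit <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L)
    return(list(type = "SUB", pos = pos, base = alt))
  if (nr == 1L && na == 2L) {
    if (substring(alt, 1L, 1L) == ref)       # insert after pos
      return(list(type = "INS", pos = pos + 1L, base = substring(alt, 2L, 2L)))
    if (substring(alt, 2L, 2L) == ref)       # insert before pos
      return(list(type = "INS", pos = pos, base = substring(alt, 1L, 1L)))
    return(NULL)
  }
  if (nr == 2L && na == 1L && substring(ref, 1L, 1L) == alt)
    return(list(type = "DEL", pos = pos + 1L, base = ""))
  NULL
}

#' Aggregate resurfacing probability of a word
#'
#' Under an independent-sites approximation the probability that at least
#' one of the supporting variants is carried is
#' `P = 1 - prod(1 - AF)`; a `"sum"` alternative (sum of AFs capped at 1)
#' is provided as a switch.  The probability is invariant to variant order
#' and monotone non-decreasing as variants are added; no variants gives 0.
#'
#' @param afs numeric vector of allele frequencies in `[0, 1]` (one per
#'   supporting variant; `NA` treated as absent and dropped).
#' @param method `"product"` (default) or `"sum"`.
#' @return the aggregate probability in `[0, 1]`.
#' @export
aggregate_resurfacing_probability <- function(afs, method = c("product", "sum")) {
  method <- match.arg(method)
  afs <- afs[!is.na(afs)]
  if (length(afs) == 0L) return(0)
  if (any(afs < 0 | afs > 1)) stop("allele frequencies must be in [0, 1]")
  if (method == "product") 1 - prod(1 - afs) else min(1, sum(afs))
}

#' Resurfacing profiles for variant-associated words
#'
#' @param assoc named list from [variant_materialized_nullomers()].
#' @param populations population suffixes for per-population probabilities
#'   (missing per-population AFs count as 0 there).
#' @param method passed to [aggregate_resurfacing_probability()].
#' @return data.frame with `word`, `n_variants`, `aggregate_probability`
#'   and one `p_<pop>` column per population.
#' @export
resurfacing_profiles <- function(assoc, populations = GNOMAD_POPULATIONS,
                                 method = "product") {
  words <- names(assoc)
  rows <- lapply(words, function(w) {
    v <- assoc[[w]]
    row <- data.frame(word = w, n_variants = nrow(v),
                      aggregate_probability =
                        aggregate_resurfacing_probability(v$af_global, method),
                      stringsAsFactors = FALSE)
    for (p in populations) {
      cn <- paste0("af_", p)
      af <- if (cn %in% names(v)) v[[cn]] else numeric(0)
      af[is.na(af)] <- 0
      row[[paste0("p_", p)]] <- aggregate_resurfacing_probability(af, method)
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else {
           z <- data.frame(word = character(0), n_variants = integer(0),
                           aggregate_probability = numeric(0))
           for (p in populations) z[[paste0("p_", p)]] <- numeric(0)
           z
         }
  rownames(out) <- NULL
  out
}

#' Population-specific nullomer calls
#'
#' A word is called for population `p` when its per-population aggregate
#' resurfacing probability exceeds `common` in `p` and is below `rare` in
#' every other population (missing frequencies count as 0).  Calls are
#' mutually exclusive per word.
#'
#' @param profiles data.frame from [resurfacing_profiles()] with `p_<pop>`
#'   columns.
#' @param common,rare thresholds (defaults 0.05 / 0.01).
#' @return data.frame with `word`, `carrier_population`, `carrier_p`,
#'   `max_other_p`.
#' @export
population_specific_nullomers <- function(profiles, common = 0.05, rare = 0.01) {
  pcols <- grep("^p_", names(profiles), value = TRUE)
  if (length(pcols) < 2L) stop("need at least 2 populations")
  pmat <- as.matrix(profiles[, pcols, drop = FALSE])
  pmat[is.na(pmat)] <- 0
  rows <- list()
  for (i in seq_len(nrow(pmat))) {
    p <- pmat[i, ]
    carrier <- which(p > common)
    if (length(carrier) != 1L) next
    others <- p[-carrier]
    if (any(others >= rare)) next
    rows[[length(rows) + 1L]] <- data.frame(
      word = profiles$word[i],
      carrier_population = sub("^p_", "", pcols[carrier]),
      carrier_p = unname(p[carrier]),
      max_other_p = if (length(others)) max(others) else 0,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(word = character(0), carrier_population = character(0),
                         carrier_p = numeric(0), max_other_p = numeric(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of a nullomer set that does not resurface
#'
#' @param nullomer_set character vector of absent words.
#' @param profiles data.frame from [resurfacing_profiles()]; words without
#'   a profile count as non-resurfacing.
#' @param threshold aggregate-probability threshold (default 0.05).
#' @return fraction of set members with aggregate probability `<= threshold`.
#' @export
non_resurfacing_fraction <- function(nullomer_set, profiles, threshold = 0.05) {
  if (length(nullomer_set) == 0L) stop("empty nullomer set")
  p <- profiles$aggregate_probability[match(nullomer_set, profiles$word)]
  p[is.na(p)] <- 0
  mean(p <= threshold)
}
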