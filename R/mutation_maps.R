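# Genome-wide maps of single-base edits that would materialize absent words.

#' Expected mutation-class counts for a k-mer
#'
#' The single-base edits that disrupt (equivalently, whose inverses create)
#' one occurrence of a k-mer: k deletions, 3k substitutions, and 4(k-1)
#' insertions -- insertions at the two ends are excluded because inserting
#' outside the word leaves the occurrence intact.  For k = 13 this gives
#' 13 / 39 / 48 edits, i.e. 13% / 39% / 48% of the 8k-4 total.
#'
#' @param k word length (>= 2).
#' @return list of class `mutation_class_expectation` with counts,
#'   `total = 8k - 4`, and `fractions` summing to 1.
#' @export
expected_class_counts <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("expected_class_counts() needs k >= 2")
  counts <- c(DEL = k, SUB = 3L * k, INS = 4L * (k - 1L))
  structure(list(k = k, deletions = counts[["DEL"]],
                 substitutions = counts[["SUB"]],
                 insertions = counts[["INS"]],
                 total = sum(counts), fractions = counts / sum(counts)),
            class = "mutation_class_expectation")
}

#' Scan a genome for nullomer-materializing single-base edits
#'
#' Applies, at every position, the 3 substitutions (only where the
#' reference base is A/C/G/T) and the single deletion, and at every gap
#' (including the gap after the final base) the 4 insertions, each to a
#' local window of radius k-1.  Every k-window of the edited local sequence
#' overlapping the edit is checked against the nullomer set of `pmap`;
#' edits that materialize nothing are suppressed.  Insertions are keyed to
#' the gap before `pos` (1-based; `pos = n+1` is the end gap).
#'
#' In both-strand presence mode a materialized word and its reverse
#' complement both flip to present and both are listed.
#'
#' @param genome a `contig_set` or named character vector of DNA sequences.
#' @param pmap `presence_map` built on the same genome and strand mode.
#' @param k word length; must equal `pmap$k`.
#' @return data.frame of class `mutation_events` with columns `contig`,
#'   `pos`, `ref`, `alt`, `mclass` (SUB/INS/DEL) and the list column
#'   `materialized`.
#' @export
scan_materializing_mutations <- function(genome, pmap, k = pmap$k) {
  stopifnot(inherits(pmap, "presence_map"))
  if (k != pmap$k) stop("k = ", k, " does not match the presence map (k = ",
                        pmap$k, ")")
  if (pmap$alphabet != "dna") stop("mutation scans are DNA-only")
  genome <- as_sequences(genome)
  if (is.null(names(genome)))
    names(genome) <- sprintf("contig_%d", seq_along(genome))
  df <- cpp_scan_materializing(unname(genome), names(genome), pmap$bitmap, k,
                               DNA_LETTERS, pmap$strand_mode == "both")
  df$materialized <- strsplit(df$words, ",", fixed = TRUE)
  df$words <- NULL
  attr(df, "k") <- k
  attr(df, "strand_mode") <- pmap$strand_mode
  class(df) <- c("mutation_events", "data.frame")
  df
}

#' Number of materializing events per nullomer
#'
#' Counts distinct (event, word) pairs grouped by word.  Words supplied in
#' `all_words` but never materialized are reported with a count of 0
#' (nullomers unreachable by single-base edits).
#'
#' @param events a `mutation_events` data.frame.
#' @param all_words optional universe of words to report.
#' @return named numeric vector of counts.
#' @export
per_nullomer_event_counts <- function(events, all_words = NULL) {
  tab <- table(unlist(events$materialized))
  counts <- stats::setNames(as.numeric(tab), names(tab))
  if (!is.null(all_words)) {
    out <- stats::setNames(numeric(length(all_words)), all_words)
    hit <- intersect(all_words, names(counts))
    out[hit] <- counts[hit]
    out
  } else counts
}

#' Fold enrichment of observed mutation classes over expectation
#'
#' @param events a `mutation_events` data.frame.
#' @param expectation a `mutation_class_expectation`
#'   (defaults to `expected_class_counts(k)` for the events' k).
#' @return named numeric vector: observed class fraction divided by the
#'   expected class fraction, for SUB, INS and DEL.
#' @export
mutation_type_enrichment <- function(events,
                                     expectation = expected_class_counts(attr(events, "k"))) {
  if (nrow(events) == 0L) stop("no events: enrichment undefined")
  obs <- table(factor(events$mclass, levels = c("DEL", "SUB", "INS")))
  obs_frac <- as.numeric(obs) / sum(obs)
  names(obs_frac) <- names(obs)
  obs_frac / expectation$fractions[names(obs_frac)]
}

#' Trinucleotide substitution context spectrum
#'
#' Counts substitution events keyed by their (5' base, ref, 3' base, alt)
#' context and normalizes by the genome-wide trinucleotide frequency:
#' `rate = (context events / total events) / (context frequency)`.
#' Events at contig termini (or with an N in the context) are excluded and
#' their number reported.
#'
#' @param events a `mutation_events` data.frame (only SUB rows are used).
#' @param genome the genome the events were called on.
#' @return list of class `context_spectrum`: data.frame `spectrum`
#'   (`context`, `ref`, `alt`, `count`, `genome_freq`, `rate`) and
#'   `n_excluded`.
#' @export
substitution_context_spectrum <- function(events, genome) {
  genome <- as_sequences(genome)
  sub <- events[events$mclass == "SUB", , drop = FALSE]
  if (nrow(sub) == 0L)
    return(structure(list(spectrum = data.frame(context = character(0),
                                                ref = character(0),
                                                alt = character(0),
                                                count = numeric(0),
                                                genome_freq = numeric(0),
                                                rate = numeric(0)),
                          n_excluded = 0L),
                     class = "context_spectrum"))
  lens <- nchar(genome)[sub$contig]
  interior <- sub$pos > 1L & sub$pos < lens
  ctx <- rep(NA_character_, nrow(sub))
  ctx[interior] <- substring(genome[sub$contig[interior]],
                             sub$pos[interior] - 1L, sub$pos[interior] + 1L)
  valid <- !is.na(ctx) & !grepl("N", ctx, fixed = TRUE)
  n_excluded <- sum(!valid)
  sub <- sub[valid, , drop = FALSE]
  ctx <- ctx[valid]
  key <- paste(ctx, sub$alt, sep = ">")
  tab <- table(key)
  parts <- strsplit(names(tab), ">", fixed = TRUE)
  spectrum <- data.frame(
    context = vapply(parts, `[`, character(1), 1L),
    alt = vapply(parts, `[`, character(1), 2L),
    count = as.numeric(tab), stringsAsFactors = FALSE)
  spectrum$ref <- substring(spectrum$context, 2L, 2L)
  tri <- cpp_klet_counts(unname(genome), 3L, DNA_LETTERS)
  freq <- stats::setNames(tri$count / sum(tri$count), tri$word)
  spectrum$genome_freq <- as.numeric(freq[spectrum$context])
  spectrum$genome_freq[is.na(spectrum$genome_freq)] <- 0
  total <- sum(spectrum$count)
  spectrum$rate <- ifelse(spectrum$genome_freq > 0,
                          (spectrum$count / total) / spectrum$genome_freq, NA)
  spectrum <- spectrum[order(-spectrum$count),
                       c("context", "ref", "alt", "count", "genome_freq",
                         "rate")]
  rownames(spectrum) <- NULL
  structure(list(spectrum = spectrum, n_excluded = n_excluded),
            class = "context_spectrum")
}

#' Event density over interval sets
#'
#' Density = events falling in the (merged) intervals of a set divided by
#' the set's total length in bp.  Events outside every interval of a set
#' are excluded from that set's count.
#'
#' @param events data.frame with `contig` and `pos` columns
#'   (`mutation_events` or variant records).
#' @param interval_sets named list of interval data.frames
#'   (`contig`, `start`, `end`, 1-based inclusive).
#' @return data.frame with `label`, `n_events`, `total_bp`, `density`.
#' @export
region_density <- function(events, interval_sets) {
  if (is.data.frame(interval_sets)) interval_sets <- list(region = interval_sets)
  out <- lapply(names(interval_sets), function(nm) {
    iv <- interval_sets[[nm]]
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(iv$contig, IRanges::IRanges(iv$start, iv$end)))
    total <- sum(GenomicRanges::width(gr))
    if (total == 0) stop("interval set '", nm, "' has zero length")
    ev <- GenomicRanges::GRanges(events$contig,
                                 IRanges::IRanges(events$pos, events$pos))
    hits <- sum(IRanges::overlapsAny(ev, gr))
    data.frame(label = nm, n_events = hits, total_bp = total,
               density = hits / total, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene materializing-mutation density
#'
#' For each transcript, the number of events falling in its genomic span
#' divided by the span length; each gene is represented by its
#' maximum-density isoform.
#'
#' @param events data.frame with `contig` and `pos`.
#' @param gene_models list of `gene_model` objects.
#' @return data.frame with `gene_id`, `transcript_id` (of the densest
#'   isoform), `n_events`, `length`, `density`.
#' @export
transcript_mutation_density <- function(events, gene_models) {
  rows <- lapply(gene_models, function(gm) {
    lo <- min(gm$tss, gm$tes); hi <- max(gm$tss, gm$tes)
    n <- sum(events$contig == gm$contig & events$pos >= lo & events$pos <= hi)
    len <- hi - lo + 1L
    data.frame(gene_id = gm$gene_id, transcript_id = gm$transcript_id,
               n_events = n, length = len, density = n / len,
               stringsAsFactors = FALSE)
  })
  per_tx <- do.call(rbind, rows)
  keep <- unlist(lapply(split(seq_len(nrow(per_tx)), per_tx$gene_id),
                        function(i) i[which.max(per_tx$density[i])]))
  out <- per_tx[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- CDS -> nullpeptide substitution maps ---------------------------------

translate_cds <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  unname(aa)
}

#' Scan coding sequences for substitutions that materialize nullpeptides
#'
#' Applies every single-nucleotide substitution to each CDS, re-translates
#' the affected codon, and checks every L-residue window covering the
#' changed residue against the nullpeptide presence map.  Synonymous
#' substitutions and substitutions creating a stop codon yield no event.
#'
#' @param cds_sequences named character vector of spliced CDS (length
#'   divisible by 3, no internal stop codons).
#' @param nullpeptide_pmap protein `presence_map` of the proteome.
#' @param L peptide word length; must equal `nullpeptide_pmap$k`.
#' @return data.frame of class `peptide_mutation_events` with columns
#'   `transcript_id`, `cds_pos`, `ref`, `alt`, `residue_index` and list
#'   column `materialized`.
#' @export
cds_peptide_substitution_scan <- function(cds_sequences, nullpeptide_pmap,
                                          L = nullpeptide_pmap$k) {
  stopifnot(inherits(nullpeptide_pmap, "presence_map"))
  if (nullpeptide_pmap$alphabet != "protein")
    stop("nullpeptide_pmap must be a protein presence map")
  if (L != nullpeptide_pmap$k)
    stop("L does not match the presence map")
  if (is.null(names(cds_sequences)))
    names(cds_sequences) <- sprintf("cds_%d", seq_along(cds_sequences))
  rows <- list()
  for (tx in names(cds_sequences)) {
    cds <- cds_sequences[[tx]]
    n <- nchar(cds)
    if (n %% 3L != 0L)
      stop("CDS length not divisible by 3 for ", tx)
    prot <- translate_cds(cds)
    if (any(prot == "*"))
      stop("internal stop codon in CDS ", tx)
    np <- length(prot)
    chars <- strsplit(cds, "", fixed = TRUE)[[1]]
    bases <- alpha_chars("dna")
    for (pos in seq_len(n)) {
      ci <- (pos - 1L) %/% 3L + 1L           # codon / residue index
      off <- (pos - 1L) %% 3L + 1L
      codon <- substring(cds, 3L * ci - 2L, 3L * ci)
      for (alt in bases[bases != chars[pos]]) {
        new_codon <- codon
        substr(new_codon, off, off) <- alt
        new_aa <- unname(Biostrings::GENETIC_CODE[new_codon])
        if (is.na(new_aa) || new_aa == "*" || new_aa == prot[ci]) next
        lo <- max(1L, ci - L + 1L)
        hi <- min(np, ci + L - 1L)
        if (hi - lo + 1L < L) next
        mutated <- prot
        mutated[ci] <- new_aa
        local <- paste(mutated[lo:hi], collapse = "")
        wins <- substring(local, 1:(nchar(local) - L + 1L),
                          L:nchar(local))
        wins <- wins[!grepl("X", wins, fixed = TRUE)]
        if (length(wins) == 0L) next
        mat <- sort(unique(wins[!is_present(nullpeptide_pmap, wins)]))
        if (length(mat))
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = tx, cds_pos = pos, ref = chars[pos], alt = alt,
            residue_index = ci, words = paste(mat, collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(transcript_id = character(0), cds_pos = integer(0),
                        ref = character(0), alt = character(0),
                        residue_index = integer(0), words = character(0),
                        stringsAsFactors = FALSE)
  df$materialized <- strsplit(df$words, ",", fixed = TRUE)
  df$words <- NULL
  attr(df, "L") <- L
  class(df) <- c("peptide_mutation_events", "data.frame")
  df
}

#' Write mutation events as a VCF-compatible TSV
#'
#' Columns CHROM, POS, REF, ALT, CLASS, NULLOMERS (comma-joined).  The
#' insertion/deletion REF/ALT encoding mirrors the event convention
#' (deletion: REF = deleted base, ALT empty; insertion: REF empty,
#' ALT = inserted base, POS = gap position).
#'
#' @param events a `mutation_events` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_mutation_events <- function(events, path) {
  out <- data.frame(CHROM = events$contig, POS = events$pos,
                    REF = events$ref, ALT = events$alt,
                    CLASS = events$mclass,
                    NULLOMERS = vapply(events$materialized, paste,
                                       character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
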