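# Seeded synthetic genomes, annotations, variants and proteomes, plus
# brute-force oracles, so every pipeline stage is testable offline.

#' Generate a synthetic genome
#'
#' Random contigs at a requested GC content with optional runs of N, and a
#' rejection/repair pass that guarantees the planted motifs (and, in
#' both-strand mode, their reverse complements) never occur, so they are
#' nullomers by construction.  Repair resamples only the windows containing
#' a hit, leaving global composition essentially untouched.  Byte-identical
#' output for identical arguments and seed.
#'
#' @param length total contig length (recycled over `n_contigs`).
#' @param gc GC fraction (default 0.41, the human genome-wide value).
#' @param n_runs number of N runs to insert per contig.
#' @param n_run_length range of N-run lengths.
#' @param exclude character vector of motifs to exclude (each >= 2 bp).
#' @param strand_mode `"both"` also excludes reverse complements.
#' @param n_contigs number of contigs.
#' @param seed RNG seed.
#' @return a `contig_set` named `chr1`, `chr2`, ...
#' @export
synth_genome <- function(length = 10000L, gc = 0.41, n_runs = 0L,
                         n_run_length = c(20L, 100L), exclude = character(0),
                         strand_mode = c("both", "forward"), n_contigs = 1L,
                         seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  if (any(nchar(exclude) < 2L))
    stop("motif exclusion is infeasible for motifs shorter than 2 bp")
  targets <- unique(if (strand_mode == "both") c(exclude, revcomp(exclude))
                    else exclude)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withr::with_seed(seed, {
    contigs <- vapply(seq_len(n_contigs), function(ci) {
      chars <- sample(names(probs), length, replace = TRUE, prob = probs)
      if (n_runs > 0L) {
        for (r in seq_len(n_runs)) {
          len <- sample(n_run_length[1]:n_run_length[2], 1L)
          start <- sample(seq_len(max(1L, length - len)), 1L)
          chars[start:(start + len - 1L)] <- "N"
        }
      }
      s <- paste(chars, collapse = "")
      repair_exclusions(s, targets, probs)
    }, character(1))
    contig_set(stats::setNames(contigs, paste0("chr", seq_len(n_contigs))),
               "dna")
  })
}

# resample every window containing a motif hit until no motif occurs
repair_exclusions <- function(s, targets, probs, max_iter = 200L) {
  if (length(targets) == 0L) return(s)
  for (iter in seq_len(max_iter)) {
    hit <- FALSE
    for (m in targets) {
      pos <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (pos[1] == -1L) next
      hit <- TRUE
      w <- nchar(m)
      for (p in pos) {
        repl <- paste(sample(names(probs), w, replace = TRUE, prob = probs),
                      collapse = "")
        substr(s, p, p + w - 1L) <- repl
      }
    }
    if (!hit) return(s)
  }
  stop("motif exclusion did not converge after ", max_iter, " repair sweeps")
}

#' Generate a synthetic gene annotation on a genome
#'
#' Packs non-overlapping multi-exon gene models (alternating strands) into
#' N-free stretches of the genome.  Each model has UTRs on both sides of a
#' codon-aligned CDS.  In-frame stop codons inside a CDS are recoded in the
#' returned genome (first base of the stop codon replaced by C), so every
#' CDS translates cleanly; the patched genome is part of the return value.
#'
#' @param genome a `contig_set` from [synth_genome()].
#' @param n_genes number of gene models.
#' @param seed RNG seed.
#' @param gene_span range of genomic gene lengths.
#' @return list with `genome` (patched `contig_set`) and `models`
#'   (list of `gene_model`).
#' @export
synth_annotation <- function(genome, n_genes = 2L, seed = 1L,
                             gene_span = c(300L, 600L)) {
  genome <- as_sequences(genome)
  withr::with_seed(seed, {
    ctg <- names(genome)[1]
    s <- genome[[ctg]]
    n <- nchar(s)
    # candidate slots: evenly spaced, N-free
    span <- gene_span[2]
    slot_starts <- seq(1L, n - span, by = span + 50L)
    slot_starts <- slot_starts[
      !grepl("N", substring(s, slot_starts, slot_starts + span - 1L),
             fixed = TRUE)]
    if (length(slot_starts) < n_genes)
      stop("genome too short (or too gappy) to pack ", n_genes, " genes")
    slot_starts <- sort(sample(slot_starts, n_genes))
    models <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      glen <- sample(gene_span[1]:gene_span[2], 1L)
      gstart <- slot_starts[g]
      gend <- gstart + glen - 1L
      strand <- if (g %% 2L == 1L) "+" else "-"
      # three exons with two introns
      e1 <- round(glen * 0.3); e2 <- round(glen * 0.2); i1 <- round(glen * 0.2)
      exons <- data.frame(
        start = c(gstart, gstart + e1 + i1,
                  gstart + e1 + i1 + e2 + i1),
        end = c(gstart + e1 - 1L, gstart + e1 + i1 + e2 - 1L, gend))
      spliced_len <- sum(exons$end - exons$start + 1L)
      # codon-aligned CDS in transcript coordinates, UTR >= 10 nt each side
      cds_len <- ((spliced_len - 40L) %/% 3L) * 3L
      cds_tx_start <- 16L
      cds_iv <- tx_to_genomic(exons, strand, cds_tx_start,
                              cds_tx_start + cds_len - 1L)
      utr5_iv <- tx_to_genomic(exons, strand, 1L, cds_tx_start - 1L)
      utr3_iv <- tx_to_genomic(exons, strand, cds_tx_start + cds_len,
                               spliced_len)
      gm <- gene_model(sprintf("TX%03d", g), sprintf("GENE%03d", g), ctg,
                       strand, exons, cds_iv, utr5_iv, utr3_iv)
      # recode in-frame stops so the CDS translates cleanly
      repeat {
        cds_seq <- spliced_sequence(s, gm$cds, strand)
        aa <- translate_cds(cds_seq)
        stops <- which(aa == "*")
        if (length(stops) == 0L) break
        for (ci in stops) {
          gpos <- tx_to_genomic_pos(gm, 3L * ci - 2L)
          base <- if (strand == "+") "C" else "G"  # C on the coding strand
          substr(s, gpos, gpos) <- base
        }
      }
      models[[g]] <- gm
    }
    genome[[ctg]] <- s
    list(genome = contig_set(genome, "dna"), models = models)
  })
}

# map a transcript-coordinate interval to genomic interval pieces
tx_to_genomic <- function(exons, strand, tx_start, tx_end) {
  if (tx_end < tx_start) return(data.frame(start = integer(0), end = integer(0)))
  widths <- exons$end - exons$start + 1L
  order_idx <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  pieces <- list()
  offset <- 0L
  for (i in order_idx) {
    w <- widths[i]
    lo <- max(tx_start, offset + 1L)
    hi <- min(tx_end, offset + w)
    if (lo <= hi) {
      if (strand == "+") {
        pieces[[length(pieces) + 1L]] <-
          c(exons$start[i] + (lo - offset - 1L), exons$start[i] + (hi - offset - 1L))
      } else {
        pieces[[length(pieces) + 1L]] <-
          c(exons$end[i] - (hi - offset - 1L), exons$end[i] - (lo - offset - 1L))
      }
    }
    offset <- offset + w
  }
  df <- do.call(rbind, lapply(pieces, function(p)
    data.frame(start = p[1], end = p[2])))
  df[order(df$start), , drop = FALSE]
}

# genomic position of the tx-coordinate position `q` within the CDS
tx_to_genomic_pos <- function(gm, q) {
  cds <- gm$cds[order(gm$cds$start), , drop = FALSE]
  widths <- cds$end - cds$start + 1L
  order_idx <- if (gm$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  offset <- 0L
  for (i in order_idx) {
    w <- widths[i]
    if (q <= offset + w) {
      return(if (gm$strand == "+") cds$start[i] + (q - offset - 1L)
             else cds$end[i] - (q - offset - 1L))
    }
    offset <- offset + w
  }
  stop("position beyond CDS")
}

#' Generate a synthetic VCF-style variant table
#'
#' Random SNVs and 1-bp indels with REF matching the genome.  Allele
#' frequencies are drawn from Beta(0.5, 10) -- many rare, few common,
#' emulating the gnomAD site-frequency shape at toy scale -- independently
#' for the global AF and each population (a random 10% of population values
#' are set missing).  Optionally, variants are engineered to materialize
#' chosen nullomers by finding a 1-mismatch occurrence of the word and
#' encoding the fixing substitution.
#'
#' @param genome a `contig_set`.
#' @param n_variants number of random variants.
#' @param populations population suffixes.
#' @param seed RNG seed.
#' @param engineer character vector of absent words to materialize through
#'   dedicated substitution variants (skipped with a warning when no
#'   1-mismatch site exists).
#' @return variant data.frame in the [read_vcf_records()] layout
#'   (sorted by contig and position).
#' @export
synth_vcf <- function(genome, n_variants = 50L,
                      populations = GNOMAD_POPULATIONS, seed = 1L,
                      engineer = character(0)) {
  genome <- as_sequences(genome)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_variants)) {
      ctg <- sample(names(genome), 1L)
      s <- genome[[ctg]]
      pos <- sample(nchar(s) - 2L, 1L) + 1L
      ref1 <- substring(s, pos, pos)
      if (ref1 == "N") next
      type <- sample(c("SUB", "INS", "DEL"), 1L, prob = c(0.7, 0.15, 0.15))
      bases <- alpha_chars("dna")
      if (type == "SUB") {
        ref <- ref1; alt <- sample(bases[bases != ref1], 1L)
      } else if (type == "INS") {
        ref <- ref1; alt <- paste0(ref1, sample(bases, 1L))
      } else {
        nxt <- substring(s, pos + 1L, pos + 1L)
        if (nxt == "N") next
        ref <- paste0(ref1, nxt); alt <- ref1
      }
      rows[[length(rows) + 1L]] <- c(contig = ctg, pos = pos, ref = ref,
                                     alt = alt)
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    df$pos <- as.integer(df$pos)
    df <- df[!duplicated(df[c("contig", "pos")]), , drop = FALSE]
    df$af_global <- round(stats::rbeta(nrow(df), 0.5, 10), 6)
    for (p in populations) {
      af <- round(stats::rbeta(nrow(df), 0.5, 10), 6)
      af[stats::runif(nrow(df)) < 0.1] <- NA
      df[[paste0("af_", p)]] <- af
    }
    for (w in engineer) {
      eng <- engineer_variant(genome, w)
      if (is.null(eng)) {
        warning("no 1-mismatch site found for engineered word ", w)
        next
      }
      eng$af_global <- round(stats::rbeta(1, 2, 10), 6)
      for (p in populations)
        eng[[paste0("af_", p)]] <- round(stats::rbeta(1, 2, 10), 6)
      df <- df[!(df$contig == eng$contig & df$pos == eng$pos), , drop = FALSE]
      df <- rbind(df, eng)
    }
    df <- df[order(df$contig, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "populations") <- populations
    df
  })
}

# substitution variant turning a 1-mismatch occurrence into `word`
engineer_variant <- function(genome, word) {
  k <- nchar(word)
  for (ctg in names(genome)) {
    hits <- Biostrings::matchPattern(word, Biostrings::DNAString(genome[[ctg]]),
                                     max.mismatch = 1, fixed = TRUE)
    for (h in seq_along(hits)) {
      start <- Biostrings::start(hits)[h]
      window <- substring(genome[[ctg]], start, start + k - 1L)
      diffs <- which(strsplit(window, "")[[1]] != strsplit(word, "")[[1]])
      if (length(diffs) != 1L) next
      pos <- start + diffs - 1L
      return(data.frame(contig = ctg, pos = pos,
                        ref = substring(window, diffs, diffs),
                        alt = substring(word, diffs, diffs),
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Generate a synthetic proteome
#'
#' Random protein sequences over the 20 standard amino acids with mildly
#' non-uniform composition; planted motifs are excluded by the same
#' rejection/repair scheme as [synth_genome()] (forward strand only).
#'
#' @param n_proteins number of sequences.
#' @param len_range protein length range.
#' @param exclude peptide motifs to exclude.
#' @param seed RNG seed.
#' @return a protein `contig_set`.
#' @export
synth_proteome <- function(n_proteins = 20L, len_range = c(80L, 300L),
                           exclude = character(0), seed = 1L) {
  aa <- alpha_chars("protein")
  # roughly vertebrate-like usage: common L/A/S/E, rare W/C/M
  wt <- c(A = 7, C = 2, D = 5, E = 7, F = 4, G = 7, H = 2, I = 4, K = 6,
          L = 10, M = 2, N = 4, P = 6, Q = 5, R = 6, S = 8, T = 5, V = 6,
          W = 1, Y = 3)[aa]
  probs <- wt / sum(wt)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_proteins), function(i) {
      len <- sample(len_range[1]:len_range[2], 1L)
      s <- paste(sample(aa, len, replace = TRUE, prob = probs), collapse = "")
      repair_exclusions(s, exclude, probs)
    }, character(1))
    contig_set(stats::setNames(seqs, sprintf("prot_%03d", seq_len(n_proteins))),
               "protein")
  })
}

#' Generate synthetic coding sequences
#'
#' Sense codons only (no stop codons anywhere), so every CDS translates
#' cleanly and is divisible by 3.
#'
#' @param n_cds number of sequences.
#' @param n_codons codon-count range.
#' @param seed RNG seed.
#' @return named character vector of CDS.
#' @export
synth_cds <- function(n_cds = 5L, n_codons = c(50L, 150L), seed = 1L) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(seed, {
    stats::setNames(vapply(seq_len(n_cds), function(i) {
      nc <- sample(n_codons[1]:n_codons[2], 1L)
      paste(sample(codons, nc, replace = TRUE), collapse = "")
    }, character(1)), sprintf("CDS%03d", seq_len(n_cds)))
  })
}

# --- brute-force oracles ---------------------------------------------------

all_words <- function(k, alphabet) {
  chars <- alpha_chars(alphabet)
  if (length(chars)^k > 1e6) stop("word space above the oracle size guard")
  grid <- do.call(expand.grid,
                  c(rep(list(chars), k), stringsAsFactors = FALSE))
  # first position varies slowest: lexicographic order
  do.call(paste0, rev(grid))
}

# naive window enumeration used by both oracles
observed_words <- function(sequences, k, strand_mode, alphabet) {
  wins <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  ai <- alpha_info(alphabet)
  wins <- wins[!grepl(ai$invalid, wins, fixed = TRUE)]
  wins <- unique(wins)
  if (strand_mode == "both") unique(c(wins, revcomp(wins))) else wins
}

#' Brute-force nullomer oracle
#'
#' Independent of the bitmap scanner: enumerates every valid window into a
#' plain set and complements against the explicit word universe.  Refuses
#' word spaces above 10^6.
#'
#' @param sequences character vector of sequences.
#' @param k word length.
#' @param strand_mode,alphabet as in [scan_presence()].
#' @return sorted character vector of absent words.
#' @export
oracle_nullomers <- function(sequences, k, strand_mode = c("both", "forward"),
                             alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  strand_mode <- match.arg(strand_mode)
  if (alphabet == "protein") strand_mode <- "forward"
  sequences <- as_sequences(sequences)
  universe <- all_words(k, alphabet)
  present <- observed_words(sequences, k, strand_mode, alphabet)
  sort(universe[!universe %chin% present])
}

#' Brute-force mutation-map oracle
#'
#' Applies every possible single-base edit (substitutions at valid
#' reference bases, deletions everywhere, insertions at every gap) to the
#' whole genome, rescans the mutated contig completely, and diffs presence
#' sets.  Guarded to genomes of at most 2000 bp and k of at most 5.
#'
#' @param genome a `contig_set` or named character vector (DNA).
#' @param k word length.
#' @param strand_mode `"both"` or `"forward"`.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `mclass` and list
#'   column `materialized`, in the same convention as
#'   [scan_materializing_mutations()].
#' @export
oracle_mutation_scan <- function(genome, k, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  genome <- as_sequences(genome)
  if (is.null(names(genome)))
    names(genome) <- sprintf("contig_%d", seq_along(genome))
  if (sum(nchar(genome)) > 2000L || k > 5L)
    stop("oracle size guard: genome <= 2000 bp and k <= 5")
  # baseline presence set, reverse-complement closed in both mode; windows
  # of unmutated contigs are all in here, so diffing the fully rescanned
  # mutated contig against it recovers exactly the newly present words
  base_present <- observed_words(genome, k, strand_mode, "dna")
  bases <- alpha_chars("dna")
  rows <- list()
  emit <- function(ctg, mutated_contig, pos, ref, alt, cl) {
    nm <- nchar(mutated_contig)
    if (nm < k) return(invisible())
    wins <- substring(mutated_contig, 1:(nm - k + 1L), k:nm)
    wins <- wins[!grepl("N", wins, fixed = TRUE)]
    new <- unique(wins[!wins %chin% base_present])
    if (length(new) == 0L) return(invisible())
    mat <- if (strand_mode == "both") sort(unique(c(new, revcomp(new))))
           else sort(new)
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = ctg, pos = pos, ref = ref, alt = alt, mclass = cl,
      words = paste(mat, collapse = ","), stringsAsFactors = FALSE)
  }
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    n <- nchar(s)
    for (p in seq_len(n)) {
      refb <- substring(s, p, p)
      if (refb %in% bases) {
        for (alt in bases[bases != refb]) {
          mut <- s
          substr(mut, p, p) <- alt
          emit(ctg, mut, p, refb, alt, "SUB")
        }
      }
      emit(ctg, paste0(substring(s, 1L, p - 1L), substring(s, p + 1L, n)),
           p, refb, "", "DEL")
    }
    for (g in seq_len(n + 1L)) {
      for (b in bases)
        emit(ctg, paste0(substring(s, 1L, g - 1L), b, substring(s, g, n)),
             g, "", b, "INS")
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        mclass = character(0), words = character(0),
                        stringsAsFactors = FALSE)
  df$materialized <- strsplit(df$words, ",", fixed = TRUE)
  df$words <- NULL
  attr(df, "k") <- k
  attr(df, "strand_mode") <- strand_mode
  class(df) <- c("mutation_events", "data.frame")
  df
}
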