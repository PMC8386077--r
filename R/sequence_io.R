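#' Read and normalize a FASTA file
#'
#' Residues are uppercased (soft-masking is deliberately ignored: repeats are
#' analysed explicitly, not excluded).  For DNA every IUPAC code outside
#' A/C/G/T/N is mapped to N; for protein the nonstandard letters
#' (B, J, O, U, X, Z, `*`, ...) are mapped to the marker X.
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `contig_set`: named character vector of residues in file order,
#'   with an `alphabet` attribute.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(head_lines)))[1]
  if (is.na(first))
    stop("FASTA format error in ", path, ": file is empty")
  if (!startsWith(trimws(head_lines[first]), ">"))
    stop("FASTA format error in ", path, ": line ", first,
         " is not a header line")
  if (trimws(head_lines[first]) == ">")
    stop("FASTA format error in ", path, ": line ", first,
         " has an empty header")
  ss <- Biostrings::readBStringSet(path)
  res <- toupper(as.character(ss))
  names(res) <- sub("\\s.*$", "", names(ss))
  if (any(nchar(res) == 0L))
    stop("FASTA format error in ", path, ": record with empty sequence")
  res <- normalize_residues(res, alphabet)
  contig_set(res, alphabet)
}

normalize_residues <- function(res, alphabet) {
  if (alphabet == "dna") {
    gsub("[^ACGTN]", "N", res)
  } else {
    gsub(sprintf("[^%s]", AA_LETTERS), "X", res)
  }
}

contig_set <- function(res, alphabet) {
  structure(res, alphabet = alphabet, class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set (%s): %d sequence(s), %s residues\n",
              attr(x, "alphabet"), length(x),
              format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' @export
`[.contig_set` <- function(x, i) {
  contig_set(NextMethod(), attr(x, "alphabet"))
}

#' Write sequences to FASTA
#' @param x named character vector (or `contig_set` / `compartment_extract`).
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "compartment_extract")) {
    seqs <- x$sequences
    if (is.null(names(seqs)))
      names(seqs) <- sprintf("%s_%d", x$label, seq_along(seqs))
  } else seqs <- as_sequences(x)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# --- gene models -----------------------------------------------------------

gene_model <- function(transcript_id, gene_id, contig, strand, exons, cds,
                       utr5, utr3) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  tss <- if (strand == "+") min(exons$start) else max(exons$end)
  tes <- if (strand == "+") max(exons$end) else min(exons$start)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, tss = tss, tes = tes,
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s], %d exon(s), %d CDS piece(s)\n",
              x$transcript_id, x$gene_id, x$contig,
              min(x$tss, x$tes), max(x$tss, x$tes), x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

iv_df <- function(gr) {
  if (length(gr) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

df_iv <- function(df, contig) {
  GenomicRanges::GRanges(contig,
                         IRanges::IRanges(df$start, df$end))
}

#' Read a gene annotation into gene models
#'
#' Accepts GFF3 or GTF (GENCODE-style `gene_id` / `transcript_id`
#' attributes).  Produces one model per transcript; coordinates are 1-based
#' inclusive as in the source formats.  When UTR features are not explicit,
#' UTRs are derived as exons minus CDS, split 5'/3' by strand.  Transcripts
#' without exons are skipped with a warning.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return list of `gene_model` objects.
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  if (length(gr) == 0L) return(list())
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tx_of <- function(i) {
    if (dialect == "gtf") as.character(md$transcript_id[i])
    else {
      # features carry Parent=<transcript>; transcript rows carry ID
      p <- md$Parent[i]
      vapply(as.list(p), function(z) if (length(z)) as.character(z[1]) else NA_character_,
             character(1))
    }
  }
  feat <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR",
                      "5UTR", "3UTR", "UTR")
  idx <- which(feat)
  tx_ids <- tx_of(idx)
  keep <- !is.na(tx_ids)
  idx <- idx[keep]; tx_ids <- tx_ids[keep]

  gene_of_tx <- new.env(parent = emptyenv())
  if (dialect == "gtf") {
    for (j in seq_along(idx))
      assign(tx_ids[j], as.character(md$gene_id[idx[j]]), envir = gene_of_tx)
  } else {
    tx_rows <- which(type %in% c("mRNA", "transcript"))
    for (i in tx_rows) {
      id <- as.character(md$ID[i])
      p <- md$Parent[i]
      g <- if (length(p[[1]])) as.character(p[[1]][1]) else id
      if (!is.na(id)) assign(id, g, envir = gene_of_tx)
    }
  }

  models <- list()
  for (tx in unique(tx_ids)) {
    rows <- idx[tx_ids == tx]
    ty <- type[rows]
    ex <- rows[ty == "exon"]
    if (length(ex) == 0L) {
      warning("transcript ", tx, " has no exons; skipped")
      next
    }
    contig <- as.character(GenomicRanges::seqnames(gr)[ex[1]])
    strand <- as.character(GenomicRanges::strand(gr)[ex[1]])
    if (!strand %in% c("+", "-")) strand <- "+"
    exons_gr <- GenomicRanges::reduce(gr[ex])
    cds_gr <- GenomicRanges::reduce(gr[rows[ty == "CDS"]])
    u5_rows <- rows[ty %in% c("five_prime_UTR", "5UTR")]
    u3_rows <- rows[ty %in% c("three_prime_UTR", "3UTR")]
    if (length(u5_rows) || length(u3_rows)) {
      utr5_gr <- GenomicRanges::reduce(gr[u5_rows])
      utr3_gr <- GenomicRanges::reduce(gr[u3_rows])
    } else if (length(cds_gr)) {
      utr_gr <- GenomicRanges::setdiff(exons_gr, cds_gr)
      cds_lo <- min(GenomicRanges::start(cds_gr))
      cds_hi <- max(GenomicRanges::end(cds_gr))
      before <- utr_gr[GenomicRanges::end(utr_gr) < cds_lo]
      after <- utr_gr[GenomicRanges::start(utr_gr) > cds_hi]
      if (strand == "+") { utr5_gr <- before; utr3_gr <- after }
      else { utr5_gr <- after; utr3_gr <- before }
    } else {
      utr5_gr <- GenomicRanges::GRanges(); utr3_gr <- GenomicRanges::GRanges()
    }
    gid <- mget(tx, envir = gene_of_tx, ifnotfound = tx)[[1]]
    models[[tx]] <- gene_model(tx, gid, contig, strand,
                               iv_df(exons_gr), iv_df(cds_gr),
                               iv_df(utr5_gr), iv_df(utr3_gr))
  }
  unname(models)
}

#' Promoter window around a transcription start site
#'
#' Strand-aware window of `-upstream` to `+downstream` around the TSS
#' (defaults -2500/+500), clipped to the contig, 1-based inclusive.  The
#' resulting window never exceeds `upstream + downstream + 1` bp.
#'
#' @param gene a `gene_model` (or a list with `tss` and `strand`).
#' @param upstream,downstream window extents in bp.
#' @param contig_length length of the contig, for clipping.
#' @return integer vector `c(start, end)`.
#' @export
promoter_window <- function(gene, upstream = 2500L, downstream = 500L,
                            contig_length) {
  tss <- gene$tss
  if (tss < 1L || tss > contig_length)
    stop("TSS outside contig for ", gene$transcript_id)
  win <- if (gene$strand == "+") c(tss - upstream, tss + downstream)
         else c(tss - downstream, tss + upstream)
  c(max(1L, win[1]), min(contig_length, win[2]))
}

substr_iv <- function(seq, df) {
  substring(seq, df$start, df$end)
}

spliced_sequence <- function(seq, df, strand) {
  if (nrow(df) == 0L) return(character(0))
  s <- paste(substr_iv(seq, df[order(df$start), , drop = FALSE]), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Extract functional compartment sequences from a genome
#'
#' Genomic-interval compartments (`genic`, `promoter`, `intronic`, `custom`)
#' are returned as forward-strand interval sequences; mRNA-level
#' compartments (`exonic`, `ccds`, `utr5`, `utr3`) are spliced
#' (exon pieces concatenated in genomic order, reverse-complemented for
#' minus-strand transcripts), so k-mers may span splice junctions.
#' Intronic intervals are genic minus exonic intervals.  Duplicate
#' sequences are deduplicated per label.
#'
#' @param genome a `contig_set` (DNA).
#' @param gene_models list of `gene_model` objects.
#' @param labels subset of genome/genic/ccds/exonic/intronic/utr5/utr3/promoter.
#' @param custom optional named list of interval data.frames
#'   (`contig`,`start`,`end`, 1-based inclusive) for extra labels.
#' @param upstream,downstream promoter window extents.
#' @return named list of `compartment_extract` objects
#'   (fields `label`, `sequences`).
#' @export
extract_compartments <- function(genome, gene_models,
                                 labels = c("genic", "exonic", "intronic",
                                            "ccds", "utr5", "utr3", "promoter"),
                                 custom = NULL,
                                 upstream = 2500L, downstream = 500L) {
  genome <- as_sequences(genome)
  for (gm in gene_models)
    if (!gm$contig %in% names(genome))
      stop("unknown contig '", gm$contig, "' for transcript ", gm$transcript_id)
  out <- list()
  grab <- function(label, fn) {
    seqs <- unlist(lapply(gene_models, fn), use.names = FALSE)
    seqs <- unique(seqs[nchar(seqs) > 0])
    out[[label]] <<- structure(list(label = label, sequences = seqs),
                               class = "compartment_extract")
  }
  for (label in labels) {
    switch(label,
      genome = {
        out[["genome"]] <- structure(
          list(label = "genome", sequences = unique(unname(genome))),
          class = "compartment_extract")
      },
      genic = grab("genic", function(gm)
        substring(genome[[gm$contig]], min(gm$tss, gm$tes), max(gm$tss, gm$tes))),
      promoter = grab("promoter", function(gm) {
        w <- promoter_window(gm, upstream, downstream,
                             nchar(genome[[gm$contig]]))
        substring(genome[[gm$contig]], w[1], w[2])
      }),
      intronic = grab("intronic", function(gm) {
        genic <- IRanges::IRanges(min(gm$tss, gm$tes), max(gm$tss, gm$tes))
        ex <- IRanges::IRanges(gm$exons$start, gm$exons$end)
        introns <- IRanges::setdiff(genic, ex)
        substr_iv(genome[[gm$contig]],
                  data.frame(start = IRanges::start(introns),
                             end = IRanges::end(introns)))
      }),
      exonic = grab("exonic", function(gm)
        spliced_sequence(genome[[gm$contig]], gm$exons, gm$strand)),
      ccds = grab("ccds", function(gm)
        spliced_sequence(genome[[gm$contig]], gm$cds, gm$strand)),
      utr5 = grab("utr5", function(gm)
        spliced_sequence(genome[[gm$contig]], gm$utr5, gm$strand)),
      utr3 = grab("utr3", function(gm)
        spliced_sequence(genome[[gm$contig]], gm$utr3, gm$strand)),
      stop("unknown compartment label: ", label)
    )
  }
  for (nm in names(custom)) {
    iv <- custom[[nm]]
    seqs <- unique(mapply(function(ctg, s, e) substring(genome[[ctg]], s, e),
                          iv$contig, iv$start, iv$end, USE.NAMES = FALSE))
    out[[nm]] <- structure(list(label = nm, sequences = seqs),
                           class = "compartment_extract")
  }
  out
}

#' @export
print.compartment_extract <- function(x, ...) {
  cat(sprintf("compartment_extract '%s': %d sequence(s), %s bp\n", x$label,
              length(x$sequences), format(sum(nchar(x$sequences)),
                                          big.mark = ",")))
  invisible(x)
}

#' Read a BED file of regions
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention at this boundary.
#'
#' @param path BED3+ file.
#' @return data.frame with `contig`, `start`, `end` (1-based inclusive) and
#'   `name` when a fourth column is present.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(contig = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4) out$name <- bed[[4]]
  out
}

# --- VCF -------------------------------------------------------------------

GNOMAD_POPULATIONS <- c("afr", "ami", "amr", "asj", "eas", "fin", "nfe", "sas")

#' Read variants from a VCF with gnomAD-style allele frequencies
#'
#' Multi-allelic records are split into one record per ALT; only single-base
#' substitutions and 1-bp insertions/deletions are retained.  The global
#' allele frequency is taken from INFO/AF; per-population frequencies from
#' INFO/AF_<pop>.  Records without an AF value are dropped with a warning;
#' missing per-population values are recorded as `NA` (absent, not zero).
#'
#' @param path a VCF v4.x file.
#' @param population_keys lower-case population suffixes to look for
#'   (defaults to the eight gnomAD populations).
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `af_global` and
#'   one `af_<pop>` column per population; attribute `populations`.
#' @export
read_vcf_records <- function(path, population_keys = GNOMAD_POPULATIONS) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)   # split multi-allelics, Number=A INFO
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
                   pos = GenomicRanges::start(rr),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (!"AF" %in% colnames(info)) {
    warning("VCF has no INFO/AF field; all ", nrow(df), " records dropped")
    df <- df[0, , drop = FALSE]
    df$af_global <- numeric(0)
    for (p in population_keys) df[[paste0("af_", p)]] <- numeric(0)
    attr(df, "populations") <- population_keys
    return(df)
  }
  df$af_global <- unlist_af(info$AF)
  for (p in population_keys) {
    key <- paste0("AF_", p)
    df[[paste0("af_", p)]] <-
      if (key %in% colnames(info)) unlist_af(info[[key]]) else NA_real_
  }
  no_af <- is.na(df$af_global)
  if (any(no_af)) {
    warning(sum(no_af), " record(s) without an AF value dropped")
    df <- df[!no_af, , drop = FALSE]
  }
  keep <- (nchar(df$ref) == 1L & nchar(df$alt) == 1L) |  # SNV
          (nchar(df$ref) == 1L & nchar(df$alt) == 2L) |  # 1-bp insertion
          (nchar(df$ref) == 2L & nchar(df$alt) == 1L)    # 1-bp deletion
  df <- df[keep, , drop = FALSE]
  af_cols <- grep("^af_", names(df), value = TRUE)
  bad <- vapply(af_cols, function(cn) any(df[[cn]] < 0 | df[[cn]] > 1,
                                          na.rm = TRUE), logical(1))
  if (any(bad)) stop("allele frequencies outside [0, 1] in ", path)
  rownames(df) <- NULL
  attr(df, "populations") <- population_keys
  df
}

unlist_af <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.list(x), function(z) if (length(z)) as.numeric(z[1]) else NA_real_,
         numeric(1))
}

#' Write gene models to GFF3
#' @param models list of `gene_model` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    span <- range(c(gm$exons$start, gm$exons$end))
    add <- function(type, s, e, attrs)
      sprintf("%s\tnullomeR\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              gm$contig, type, s, e, gm$strand,
              if (type == "CDS") "0" else ".", attrs)
    lines <- c(lines,
               add("gene", span[1], span[2], sprintf("ID=%s", gm$gene_id)),
               add("mRNA", span[1], span[2],
                   sprintf("ID=%s;Parent=%s", gm$transcript_id, gm$gene_id)))
    emit <- function(df, type) {
      if (nrow(df) == 0L) return(character(0))
      mapply(function(s, e) add(type, s, e,
                                sprintf("Parent=%s", gm$transcript_id)),
             df$start, df$end)
    }
    lines <- c(lines, emit(gm$exons, "exon"), emit(gm$cds, "CDS"),
               emit(gm$utr5, "five_prime_UTR"), emit(gm$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write variant records to a minimal gnomAD-dialect VCF
#' @param records data.frame as returned by [read_vcf_records()].
#' @param path output file.
#' @param populations population suffixes to emit as `AF_<pop>` INFO keys.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, populations = GNOMAD_POPULATIONS) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           sprintf(paste0("##INFO=<ID=AF_%s,Number=A,Type=Float,",
                          "Description=\"Allele Frequency in %s\">"),
                   populations, populations),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_af <- function(x) sub("0+$", "", sprintf("%.6f", x))
  body <- vapply(seq_len(nrow(records)), function(i) {
    info <- sprintf("AF=%s", fmt_af(records$af_global[i]))
    for (p in populations) {
      v <- records[[paste0("af_", p)]][i]
      if (!is.null(v) && !is.na(v))
        info <- paste0(info, sprintf(";AF_%s=%s", p, fmt_af(v)))
    }
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", records$contig[i], records$pos[i],
            records$ref[i], records$alt[i], info)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
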