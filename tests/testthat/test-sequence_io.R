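test_that("read_fasta normalizes residues and preserves record order", {
  f <- write_tmp(c(">a", "ACGT"), ".fa")
  x <- read_fasta(f, "dna")
  expect_identical(as.character(x), "ACGT")
  expect_identical(names(x), "a")

  f2 <- write_tmp(c(">a", "acgtry"), ".fa")
  expect_identical(as.character(read_fasta(f2, "dna")), "ACGTNN")

  f3 <- write_tmp(c(">a", "AC", ">b", "GG"), ".fa")
  expect_length(read_fasta(f3, "dna"), 2)
  expect_identical(names(read_fasta(f3, "dna")), c("a", "b"))

  fp <- write_tmp(c(">p", "MKWBJOUXZ*L"), ".fa")
  expect_identical(as.character(read_fasta(fp, "protein")), "MKWXXXXXXXL")
})

test_that("read_fasta rejects malformed input with the offending line", {
  empty <- write_tmp(character(0), ".fa")
  expect_error(read_fasta(empty, "dna"), "empty")
  noheader <- write_tmp(c("ACGT", ">a", "ACGT"), ".fa")
  expect_error(read_fasta(noheader, "dna"), "line 1")
  expect_error(read_fasta(tempfile(), "dna"), "no such file")
})

test_that("FASTA round trip reproduces compartment sequences exactly", {
  g <- synth_genome(length = 3000, n_runs = 1, seed = 21)
  ann <- synth_annotation(g, n_genes = 2, seed = 3)
  comp <- extract_compartments(ann$genome, ann$models)
  f <- tempfile(fileext = ".fa")
  write_fasta(comp$ccds, f)
  back <- read_fasta(f, "dna")
  expect_identical(as.character(back), comp$ccds$sequences)
})

test_that("annotation parsing derives UTRs from exon minus CDS", {
  gtf <- write_tmp(c(
    paste("chr1", "src", "transcript", "1", "30", ".", "+", ".",
          "gene_id \"G1\"; transcript_id \"T1\";", sep = "\t"),
    paste("chr1", "src", "exon", "1", "10", ".", "+", ".",
          "gene_id \"G1\"; transcript_id \"T1\";", sep = "\t"),
    paste("chr1", "src", "exon", "21", "30", ".", "+", ".",
          "gene_id \"G1\"; transcript_id \"T1\";", sep = "\t"),
    paste("chr1", "src", "CDS", "5", "10", ".", "+", "0",
          "gene_id \"G1\"; transcript_id \"T1\";", sep = "\t"),
    paste("chr1", "src", "CDS", "21", "24", ".", "+", "0",
          "gene_id \"G1\"; transcript_id \"T1\";", sep = "\t")), ".gtf")
  models <- read_annotation(gtf, "gtf")
  expect_length(models, 1)
  gm <- models[[1]]
  expect_equal(gm$gene_id, "G1")
  expect_equal(gm$tss, 1)
  expect_equal(gm$tes, 30)
  # exon minus CDS: [1,4] upstream -> 5'UTR, [25,30] downstream -> 3'UTR
  expect_equal(gm$utr5, data.frame(start = 1L, end = 4L))
  expect_equal(gm$utr3, data.frame(start = 25L, end = 30L))
})

test_that("minus-strand transcripts put the TSS at the max coordinate", {
  gtf <- write_tmp(c(
    paste("chr1", "src", "exon", "11", "40", ".", "-", ".",
          "gene_id \"G2\"; transcript_id \"T2\";", sep = "\t")), ".gtf")
  gm <- read_annotation(gtf, "gtf")[[1]]
  expect_equal(gm$tss, 40)
  expect_equal(gm$tes, 11)
})

test_that("annotation edge cases: empty file and exonless transcripts", {
  empty <- write_tmp("##gff-version 3", ".gff3")
  expect_length(read_annotation(empty, "gff3"), 0)
  noexon <- write_tmp(c("##gff-version 3",
                        "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=T3;Parent=G3",
                        "chr1\tsrc\tCDS\t1\t9\t.\t+\t0\tParent=T3"), ".gff3")
  expect_warning(models <- read_annotation(noexon, "gff3"), "no exons")
  expect_length(models, 0)
})

test_that("promoter windows follow strand and clip to the contig", {
  plus <- list(transcript_id = "t", tss = 3000, strand = "+")
  minus <- list(transcript_id = "t", tss = 3000, strand = "-")
  expect_equal(promoter_window(plus, contig_length = 10000), c(500, 3500))
  expect_equal(promoter_window(minus, contig_length = 10000), c(2500, 5500))
  expect_equal(promoter_window(list(tss = 100, strand = "+"),
                               contig_length = 10000), c(1, 600))
  # never longer than 3001 bp, never off-contig
  set.seed(2)
  for (tss in sample(5000, 25)) {
    for (st in c("+", "-")) {
      w <- promoter_window(list(tss = tss, strand = st), contig_length = 5000)
      expect_lte(w[2] - w[1] + 1, 3001)
      expect_gte(w[1], 1)
      expect_lte(w[2], 5000)
    }
  }
})

test_that("compartment extraction: introns, splicing, promoters", {
  # 12-bp contig, exons [1,4] and [9,12]: the intron is [5,8]
  contig <- c(chr1 = "AACCGGTTACGT")
  gm <- nullomeR:::gene_model("T1", "G1", "chr1", "+",
                              exons = data.frame(start = c(1L, 9L),
                                                 end = c(4L, 12L)),
                              cds = data.frame(start = integer(0),
                                               end = integer(0)),
                              utr5 = data.frame(start = integer(0),
                                                end = integer(0)),
                              utr3 = data.frame(start = integer(0),
                                                end = integer(0)))
  comp <- extract_compartments(contig, list(gm), labels = c("intronic"))
  expect_identical(comp$intronic$sequences, substring(contig[[1]], 5, 8))

  # minus-strand CDS pieces "AC" and "GT" in genomic order splice to
  # revcomp("ACGT") == "ACGT"
  contig2 <- c(chr1 = "ACAAAAAAGTAA")
  gm2 <- nullomeR:::gene_model("T2", "G2", "chr1", "-",
                               exons = data.frame(start = c(1L, 9L),
                                                  end = c(2L, 10L)),
                               cds = data.frame(start = c(1L, 9L),
                                                end = c(2L, 10L)),
                               utr5 = data.frame(start = integer(0),
                                                 end = integer(0)),
                               utr3 = data.frame(start = integer(0),
                                                 end = integer(0)))
  comp2 <- extract_compartments(contig2, list(gm2), labels = "ccds")
  expect_identical(comp2$ccds$sequences, "ACGT")

  g <- synth_genome(length = 8000, seed = 31)
  ann <- synth_annotation(g, n_genes = 2, seed = 4)
  comp3 <- extract_compartments(ann$genome, ann$models, labels = "promoter")
  expect_length(comp3$promoter$sequences, 2)

  gm_bad <- nullomeR:::gene_model("TX", "GX", "chrMissing", "+",
                                  exons = data.frame(start = 1L, end = 4L),
                                  cds = data.frame(start = integer(0),
                                                   end = integer(0)),
                                  utr5 = data.frame(start = integer(0),
                                                    end = integer(0)),
                                  utr3 = data.frame(start = integer(0),
                                                    end = integer(0)))
  expect_error(extract_compartments(contig, list(gm_bad)), "TX")
})

test_that("intronic plus exonic coverage equals genic coverage", {
  g <- synth_genome(length = 10000, seed = 13)
  ann <- synth_annotation(g, n_genes = 3, seed = 7)
  for (gm in ann$models) {
    genic_len <- abs(gm$tes - gm$tss) + 1
    exonic_len <- sum(gm$exons$end - gm$exons$start + 1)
    comp <- extract_compartments(ann$genome, list(gm),
                                 labels = c("intronic"))
    intronic_len <- sum(nchar(comp$intronic$sequences))
    expect_equal(exonic_len + intronic_len, genic_len)
  }
})

test_that("read_bed converts 0-based half-open to 1-based inclusive", {
  bed <- write_tmp(c("chr1\t0\t10\tr1", "chr2\t99\t200\tr2"), ".bed")
  out <- read_bed(bed)
  expect_equal(out$start, c(1, 100))
  expect_equal(out$end, c(10, 200))
  expect_equal(out$name, c("r1", "r2"))
})

test_that("VCF parsing: AF extraction, length filtering, multiallelics", {
  vcf <- write_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "##INFO=<ID=AF_afr,Number=A,Type=Float,Description=\"AF afr\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t5\t.\tA\tC\t.\t.\tAF=0.12;AF_afr=0.3",
    "chr1\t8\t.\tA\tCT\t.\t.\tAF=0.01",       # net +1: kept
    "chr1\t12\t.\tAT\tA\t.\t.\tAF=0.02",      # 1-bp deletion: kept
    "chr1\t20\t.\tATG\tA\t.\t.\tAF=0.03",     # 2-bp deletion: dropped
    "chr1\t30\t.\tA\tC,G\t.\t.\tAF=0.05,0.06" # multiallelic: split
  ), ".vcf")
  rec <- read_vcf_records(vcf)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$af_global[rec$pos == 5], 0.12)
  expect_equal(rec$af_afr[rec$pos == 5], 0.3)
  expect_true(is.na(rec$af_afr[rec$pos == 8]))      # absent, not zero
  expect_equal(sum(rec$pos == 30), 2)
  expect_setequal(rec$alt[rec$pos == 30], c("C", "G"))
  expect_false(20 %in% rec$pos)
})

test_that("VCF records without AF are dropped with a warning", {
  vcf <- write_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t5\t.\tA\tC\t.\t.\tAF=0.12",
    "chr1\t9\t.\tG\tT\t.\t.\t."), ".vcf")
  expect_warning(rec <- read_vcf_records(vcf), "dropped")
  expect_equal(nrow(rec), 1)
})

test_that("write_vcf / read_vcf_records round trip", {
  g <- synth_genome(length = 2000, seed = 17)
  v <- synth_vcf(g, n_variants = 25, seed = 9)
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  back <- read_vcf_records(f)
  expect_equal(nrow(back), nrow(v))
  expect_equal(back$pos, v$pos)
  expect_equal(back$af_global, v$af_global, tolerance = 1e-6)
  expect_equal(back$af_eas, v$af_eas, tolerance = 1e-6)
})
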