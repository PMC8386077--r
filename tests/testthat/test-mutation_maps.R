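test_that("expected mutation-class combinatorics", {
  e <- expected_class_counts(2)
  expect_equal(c(e$deletions, e$substitutions, e$insertions), c(2, 6, 4))
  e11 <- expected_class_counts(11)
  expect_equal(c(e11$deletions, e11$substitutions, e11$insertions),
               c(11, 33, 40))
  for (k in c(2, 5, 9, 15))
    expect_equal(sum(expected_class_counts(k)$fractions), 1)
  expect_error(expected_class_counts(1), "k >= 2")
})

test_that("materializing scan reproduces hand-checked edits", {
  g <- c(chr = "AAAA")
  pm <- scan_presence(g, 2, "dna", "forward")
  ev <- scan_materializing_mutations(g, pm)
  hit <- ev[ev$mclass == "SUB" & ev$pos == 2 & ev$alt == "C", ]
  expect_equal(nrow(hit), 1)
  expect_setequal(hit$materialized[[1]], c("AC", "CA"))
  expect_false(any(ev$ref == ev$alt))

  g2 <- c(chr = "ACGT")
  pm3 <- scan_presence(g2, 3, "dna", "forward")
  ev3 <- scan_materializing_mutations(g2, pm3)
  del <- ev3[ev3$mclass == "DEL" & ev3$pos == 2, ]
  expect_equal(nrow(del), 1)
  expect_true("AGT" %in% del$materialized[[1]])

  expect_error(scan_materializing_mutations(g, pm3, k = 2), "does not match")
})

test_that("scan equals the exhaustive mutate-and-rescan oracle", {
  set.seed(33)
  for (rep in 1:4) {
    g <- c(chr = rand_dna(sample(80:200, 1), p = c(0.3, 0.2, 0.2, 0.3)))
    mode <- if (rep %% 2 == 0) "both" else "forward"
    for (k in 2:4) {
      pm <- scan_presence(g, k, "dna", mode)
      ev <- scan_materializing_mutations(g, pm)
      expect_identical(canon_events(ev),
                       canon_events(oracle_mutation_scan(g, k, mode)))
    }
  }
})

test_that("N runs are handled: no substitutions at N, deletions can bridge", {
  g <- c(chr = "ACGTNACGT")
  pm <- scan_presence(g, 3, "dna", "forward")
  ev <- scan_materializing_mutations(g, pm)
  expect_false(any(ev$mclass == "SUB" & ev$pos == 5))
  expect_identical(canon_events(ev),
                   canon_events(oracle_mutation_scan(g, 3, "forward")))
})

test_that("events are sound and respect the per-position edit cap", {
  g <- synth_genome(length = 900, seed = 41)
  pm <- scan_presence(g, 4, "dna", "both")
  ev <- scan_materializing_mutations(g, pm)
  expect_gt(nrow(ev), 0)
  # every materialized word was absent before the edit
  expect_false(any(is_present(pm, unique(unlist(ev$materialized)))))
  # re-apply each event on the full genome; the word (or its revcomp) must
  # occur in the mutated sequence
  s <- g[[1]]
  for (i in sample(nrow(ev), min(25, nrow(ev)))) {
    mut <- switch(ev$mclass[i],
      SUB = { x <- s; substr(x, ev$pos[i], ev$pos[i]) <- ev$alt[i]; x },
      DEL = paste0(substring(s, 1, ev$pos[i] - 1),
                   substring(s, ev$pos[i] + 1, nchar(s))),
      INS = paste0(substring(s, 1, ev$pos[i] - 1), ev$alt[i],
                   substring(s, ev$pos[i], nchar(s))))
    for (w in ev$materialized[[i]])
      expect_true(grepl(w, mut, fixed = TRUE) ||
                    grepl(revcomp(w), mut, fixed = TRUE))
  }
  per_site <- table(paste(ev$contig, ev$pos, ev$mclass))
  expect_lte(max(per_site[grepl("SUB", names(per_site))]), 3)
  expect_lte(max(per_site[grepl("DEL", names(per_site))]), 1)
  expect_lte(max(per_site[grepl("INS", names(per_site))]), 4)
})

test_that("per-nullomer event counts group (event, word) pairs", {
  ev <- structure(data.frame(contig = "c", pos = 1:3, ref = "A", alt = "C",
                             mclass = "SUB"),
                  class = c("mutation_events", "data.frame"))
  ev$materialized <- list(c("AC", "CA"), "AC", "AC")
  counts <- per_nullomer_event_counts(ev)
  expect_equal(counts[["AC"]], 3)
  expect_equal(counts[["CA"]], 1)
  counts2 <- per_nullomer_event_counts(ev, all_words = c("AC", "CA", "GG"))
  expect_equal(counts2[["GG"]], 0)
})

test_that("mutation-class enrichment is observed over expected fraction", {
  ev <- structure(data.frame(
    contig = "c", pos = 1, ref = "A", alt = "C",
    mclass = rep(c("SUB", "INS", "DEL"), c(50, 40, 10))),
    class = c("mutation_events", "data.frame"))
  ev$materialized <- replicate(100, "X", simplify = FALSE)
  attr(ev, "k") <- 13
  enr <- mutation_type_enrichment(ev)
  expect_equal(enr[["SUB"]], 0.5 / 0.39, tolerance = 1e-9)
  expect_equal(enr[["DEL"]], 0.10 / 0.13, tolerance = 1e-9)

  ev2 <- ev
  ev2$mclass <- rep(c("DEL", "SUB", "INS"), c(13, 39, 48))
  expect_equal(unname(mutation_type_enrichment(ev2)), c(1, 1, 1))
  expect_error(mutation_type_enrichment(ev[0, ]), "no events")
})

test_that("substitution context spectrum counts and normalizes", {
  g <- c(chr = "ACTGA")
  ev <- structure(data.frame(contig = "chr", pos = c(3, 1), ref = c("T", "A"),
                             alt = c("A", "C"), mclass = "SUB"),
                  class = c("mutation_events", "data.frame"))
  ev$materialized <- list("X", "Y")
  spec <- substitution_context_spectrum(ev, g)
  expect_equal(spec$n_excluded, 1)  # the pos-1 event has no 5' base
  expect_equal(nrow(spec$spectrum), 1)
  expect_equal(spec$spectrum$context, "CTG")
  expect_equal(spec$spectrum$ref, "T")
  expect_equal(spec$spectrum$count, 1)
  # rate identity: (count/total) / genome frequency
  g2 <- synth_genome(length = 600, seed = 51)
  pm <- scan_presence(g2, 4, "dna", "both")
  full <- substitution_context_spectrum(scan_materializing_mutations(g2, pm),
                                        g2)
  sp <- full$spectrum
  expect_equal(sp$rate, (sp$count / sum(sp$count)) / sp$genome_freq)
  empty <- substitution_context_spectrum(
    structure(data.frame(contig = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         mclass = character(0)),
              class = c("mutation_events", "data.frame")), g)
  expect_equal(nrow(empty$spectrum), 0)
})

test_that("region and transcript densities", {
  ev <- data.frame(contig = "chr1", pos = c(5, 20, 50, 90, 150))
  iv <- data.frame(contig = "chr1", start = 1, end = 100)
  d <- region_density(ev, list(roi = iv))
  expect_equal(d$density, 4 / 100)
  expect_error(region_density(ev, list(bad = iv[0, ])), "zero length")

  mk <- function(tx, gene, s, e)
    nullomeR:::gene_model(tx, gene, "chr1", "+",
                          exons = data.frame(start = s, end = e),
                          cds = data.frame(start = integer(0), end = integer(0)),
                          utr5 = data.frame(start = integer(0), end = integer(0)),
                          utr3 = data.frame(start = integer(0), end = integer(0)))
  models <- list(mk("iso1", "G", 1L, 100L),   # 2 events / 100 bp
                 mk("iso2", "G", 1L, 50L))    # 2 events / 50 bp
  ev2 <- data.frame(contig = "chr1", pos = c(10, 40))
  td <- transcript_mutation_density(ev2, models)
  expect_equal(nrow(td), 1)
  expect_equal(td$transcript_id, "iso2")
  expect_equal(td$density, 2 / 50)
})

test_that("CDS substitution scan translates, filters stops and synonymy", {
  # CDS TGG TGC -> "WC"; presence map from a proteome missing "CC"
  proteome <- c(p1 = "WCWC")
  ppm <- scan_presence(proteome, 2, "protein")
  ev <- cds_peptide_substitution_scan(c(tx1 = "TGGTGC"), ppm)
  hit <- ev[ev$cds_pos == 3 & ev$alt == "T", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$residue_index, 1)
  expect_true("CC" %in% hit$materialized[[1]])
  # synonymous TGC -> TGT yields no event
  expect_false(any(ev$cds_pos == 6 & ev$alt == "T"))
  # no event may involve a stop-creating substitution (TGG -> TGA/TAG)
  expect_false(any(ev$cds_pos == 3 & ev$alt == "A"))
  expect_false(any(ev$cds_pos == 2 & ev$alt == "A"))

  expect_error(cds_peptide_substitution_scan(c(bad = "TGGT"), ppm),
               "divisible by 3")
  expect_error(cds_peptide_substitution_scan(c(bad = "TGGTGA"), ppm),
               "internal stop")
})

test_that("CDS scan events are sound against the proteome map", {
  prot <- synth_proteome(8, c(50, 100), seed = 61)
  ppm <- scan_presence(prot, 3, "protein")
  cds <- synth_cds(2, c(30, 40), seed = 62)
  ev <- cds_peptide_substitution_scan(cds, ppm)
  expect_gt(nrow(ev), 0)
  words <- unique(unlist(ev$materialized))
  expect_false(any(is_present(ppm, words)))
  # every event's substitution is non-synonymous by construction
  for (i in sample(nrow(ev), min(10, nrow(ev)))) {
    cdsstr <- cds[[ev$transcript_id[i]]]
    expect_equal(substring(cdsstr, ev$cds_pos[i], ev$cds_pos[i]), ev$ref[i])
    mut <- cdsstr
    substr(mut, ev$cds_pos[i], ev$cds_pos[i]) <- ev$alt[i]
    aa_old <- nullomeR:::translate_cds(cdsstr)
    aa_new <- nullomeR:::translate_cds(mut)
    expect_false(identical(aa_old, aa_new))
    expect_false(any(aa_new == "*"))
    for (w in ev$materialized[[i]])
      expect_true(grepl(w, paste(aa_new, collapse = ""), fixed = TRUE))
  }
})
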