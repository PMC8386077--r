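make_variants <- function(contig, pos, ref, alt, af = 0.1, ...) {
  df <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                   af_global = af, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

test_that("variants materialize absent words through local re-scanning", {
  g <- c(chr = "AAAA")
  pm <- scan_presence(g, 2, "dna", "forward")
  v <- make_variants("chr", 2, "A", "C")
  assoc <- variant_materialized_nullomers(g, v, pm)
  expect_setequal(names(assoc), c("AC", "CA"))
  expect_equal(nrow(assoc[["AC"]]), 1)

  # an edit creating only already-present words leaves no entry
  g2 <- c(chr = "ACACCA")
  pm2 <- scan_presence(g2, 2, "dna", "forward")
  v2 <- make_variants("chr", 3, "A", "C")   # ACCCCA: creates only CC...
  assoc2 <- variant_materialized_nullomers(g2, v2, pm2)
  expect_false(any(c("AC", "CA", "CC") %in% names(assoc2)))

  # two variants materializing the same word are both listed
  g3 <- c(chr = "AAAAAAAA")
  pm3 <- scan_presence(g3, 2, "dna", "forward")
  v3 <- make_variants("chr", c(2, 6), "A", "C")
  assoc3 <- variant_materialized_nullomers(g3, v3, pm3)
  expect_equal(nrow(assoc3[["AC"]]), 2)
})

test_that("REF mismatches are skipped with a warning", {
  g <- c(chr = "AAAA")
  pm <- scan_presence(g, 2, "dna", "forward")
  v <- make_variants("chr", c(2, 3), c("G", "A"), c("C", "C"))
  expect_warning(assoc <- variant_materialized_nullomers(g, v, pm),
                 "skipped")
  expect_equal(attr(assoc, "n_ref_mismatch"), 1)
  expect_true("CA" %in% names(assoc))
})

test_that("variant-associated words are a subset of the potential map", {
  g <- synth_genome(length = 1500, seed = 71)
  pm <- scan_presence(g, 5, "dna", "both")
  v <- synth_vcf(g, n_variants = 60, seed = 72)
  assoc <- variant_materialized_nullomers(g, v, pm)
  ev <- scan_materializing_mutations(g, pm)
  key <- function(pos, ref, alt, cl) paste(pos, ref, alt, cl)
  ev_keys <- with(ev, key(pos, ref, alt, mclass))
  for (w in names(assoc)) {
    for (i in seq_len(nrow(assoc[[w]]))) {
      vr <- assoc[[w]][i, ]
      e <- nullomeR:::vcf_to_edit(vr$pos, vr$ref, vr$alt)
      k <- key(e$pos, if (e$type == "INS") "" else substring(g[[1]], e$pos, e$pos),
               e$base, e$type)
      j <- which(ev_keys == k)
      expect_length(j, 1)
      expect_true(w %in% ev$materialized[[j]])
    }
  }
})

test_that("aggregate resurfacing probability", {
  expect_equal(aggregate_resurfacing_probability(c(0.1, 0.2)), 0.28)
  expect_equal(aggregate_resurfacing_probability(numeric(0)), 0)
  expect_equal(aggregate_resurfacing_probability(c(0.3, 1.0)), 1.0)
  expect_error(aggregate_resurfacing_probability(c(0.5, 1.2)), "0, 1")
  # order invariance and monotonicity
  set.seed(3)
  afs <- stats::runif(6, 0, 0.4)
  expect_equal(aggregate_resurfacing_probability(afs),
               aggregate_resurfacing_probability(rev(afs)))
  for (m in 2:6)
    expect_gte(aggregate_resurfacing_probability(afs[1:m]),
               aggregate_resurfacing_probability(afs[1:(m - 1)]))
  expect_equal(aggregate_resurfacing_probability(c(0.1, 0.2), method = "sum"),
               0.3)
  expect_equal(aggregate_resurfacing_probability(c(0.9, 0.9), method = "sum"),
               1)
})

test_that("resurfacing profiles aggregate per population", {
  assoc <- list(
    AA = make_variants("c", 1:2, "A", "C", af = c(0.1, 0.2),
                       af_afr = c(0.3, NA), af_eas = c(NA, NA)),
    CC = make_variants("c", 5, "A", "C", af = 0.5, af_afr = 0.01,
                       af_eas = 0.02))
  prof <- resurfacing_profiles(assoc, populations = c("afr", "eas"))
  expect_equal(prof$aggregate_probability[prof$word == "AA"], 0.28)
  expect_equal(prof$p_afr[prof$word == "AA"], 0.3)  # NA treated as 0
  expect_equal(prof$p_eas[prof$word == "AA"], 0)
  expect_equal(prof$n_variants, c(2, 1))
})

test_that("population-specific calls need one common, all others rare", {
  prof <- data.frame(word = c("w1", "w2", "w3"),
                     p_afr = c(0.08, 0.08, 0.005),
                     p_eas = c(0.005, 0.06, 0.004),
                     p_nfe = c(0.001, 0.001, 0.002))
  calls <- population_specific_nullomers(prof)
  expect_equal(calls$word, "w1")
  expect_equal(calls$carrier_population, "afr")
  expect_error(population_specific_nullomers(prof[, 1:2, drop = FALSE]),
               "at least 2")
  # borderline: other population at exactly the rare threshold is rejected
  prof2 <- data.frame(word = "w", p_afr = 0.2, p_eas = 0.01)
  expect_equal(nrow(population_specific_nullomers(prof2)), 0)
  # at most one carrier per word by construction
  expect_lte(max(table(calls$word)), 1)
})

test_that("non-resurfacing fraction counts unprofiled words as safe", {
  prof <- data.frame(word = c("a", "b"),
                     aggregate_probability = c(0.06, 0.06))
  expect_equal(non_resurfacing_fraction(c("a", "b", "c", "d"), prof), 0.5)
  expect_equal(non_resurfacing_fraction(c("a", "b"), prof, threshold = 1), 1)
  prof0 <- data.frame(word = "a", aggregate_probability = 0)
  expect_equal(non_resurfacing_fraction(c("a", "x"), prof0), 1)
  expect_error(non_resurfacing_fraction(character(0), prof), "empty")
})
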