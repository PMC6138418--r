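ref <- utr_reference()

test_that("the synthetic reference respects the published intron topology", {
  s <- ref$snps
  off <- function(n) s$offset[s$name == n]
  expect_true(off("SNP2") >= ref$intron[1] && off("SNP2") < ref$intron[2])
  expect_true(off("Af1") >= ref$intron[1] && off("Af1") < ref$intron[2])
  expect_lt(off("SNP1"), ref$intron[1])
  expect_gt(off("Af3"), ref$intron[2])
  expect_false(any(duplicated(s$offset)))
  expect_equal(nchar(ref$seq), 497)  # emulated UTR span 6872-7368
})

test_that("SNP calling reads reference alleles and flags the unexpected", {
  al <- call_snps(ref$seq, ref)
  expect_equal(as.character(al), ref$snps$ref)
  expect_length(attr(al, "unknown"), 0)
  # a novel base at SNP3 is reported, not coerced
  s <- strsplit(ref$seq, "")[[1]]
  s[ref$snps$offset[ref$snps$name == "SNP3"] + 1] <- "C"  # allele set is {G,A}
  al2 <- call_snps(paste(s, collapse = ""), ref)
  expect_equal(attr(al2, "unknown"), "SNP3")
  # ambiguity codes and length changes are errors
  s2 <- strsplit(ref$seq, "")[[1]]
  s2[ref$snps$offset[1] + 1] <- "N"
  expect_error(call_snps(paste(s2, collapse = ""), ref), "ambiguity")
  expect_error(call_snps(substr(ref$seq, 1, 400), ref), "length")
})

test_that("classification applies SNP3G dominance and the two major classes", {
  al <- c(SNP1 = "C", SNP2 = "A", SNP3 = "G", SNP4 = "T", Af1 = "T", Af3 = "T")
  expect_equal(classify_haplotype(al), "SNP3G")
  al["SNP3"] <- "A"
  expect_equal(classify_haplotype(al), "C/A/T/T")
  al[c("SNP1", "SNP2", "Af1", "Af3")] <- c("T", "T", "C", "A")
  expect_equal(classify_haplotype(al), "T/T/C/A")
  al[c("SNP1", "SNP2", "Af1", "Af3")] <- c("C", "T", "C", "A")
  expect_equal(classify_haplotype(al), "other:C/T/C/A")
  expect_error(classify_haplotype(al[c("SNP1", "SNP2")]), "missing")
})

test_that("splice-site checks pass the reference and localize mutations", {
  expect_true(check_splice_sites(ref$seq, ref))
  s <- strsplit(ref$seq, "")[[1]]
  s[ref$ss5$span[1] + 2] <- "C"
  ok <- check_splice_sites(paste(s, collapse = ""), ref)
  expect_false(as.logical(ok))
  expect_match(attr(ok, "report"), "5'ss")
  expect_error(check_splice_sites("ACGT", ref), "intron")
})

test_that("classification inverts the generator on all six haplotypes", {
  utr <- simulate_utr_fasta("deterministic")
  calls <- call_haplotypes(utr$fasta)
  expect_equal(nrow(calls), 42)
  merged <- merge(calls, utr$truth, by = c("line_id", "region"))
  lab <- ifelse(merged$haplotype.y %in% c("SNP3G", "C/A/T/T", "T/T/C/A"),
                merged$haplotype.y, paste0("other:", merged$haplotype.y))
  expect_equal(merged$haplotype.x, lab)
  expect_true(all(calls$splice_sites_ok))
  # single-haplotype spec: every tropical record classifies C/A/T/T
  utr2 <- simulate_utr_fasta("stochastic",
                             freqs = list(tropical = c("C/A/T/T" = 1)),
                             n_lines = c(tropical = 10), seed = 1)
  expect_true(all(call_haplotypes(utr2$fasta)$haplotype == "C/A/T/T"))
})

test_that("stochastic haplotype draws match their target frequencies", {
  freqs <- list(tropical = c("C/A/T/T" = 0.7, "T/T/C/A" = 0.3))
  u1 <- simulate_utr_fasta("stochastic", freqs = freqs,
                           n_lines = c(tropical = 1000), seed = 1)
  u2 <- simulate_utr_fasta("stochastic", freqs = freqs,
                           n_lines = c(tropical = 1000), seed = 2)
  f1 <- mean(u1$truth$haplotype == "C/A/T/T")
  f2 <- mean(u2$truth$haplotype == "C/A/T/T")
  expect_lt(abs(f1 - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
  expect_lt(abs(f2 - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
  expect_false(identical(u1$truth$haplotype, u2$truth$haplotype))
  expect_error(simulate_utr_fasta("stochastic",
                                  freqs = list(tropical = c("C/A/T/T" = 0.5)),
                                  n_lines = c(tropical = 5)),
               "sum to 1")
})

test_that("the contingency table counts the two focal classes by region", {
  calls <- call_haplotypes(simulate_utr_fasta("deterministic")$fasta)
  m <- build_contingency(calls)
  expect_equal(unname(m), matrix(c(9L, 3L, 2L, 6L), 2))
  # order invariance
  m2 <- build_contingency(calls[sample(nrow(calls)), ])
  expect_identical(m, m2)
  expect_error(build_contingency(calls[calls$haplotype == "SNP3G", ]),
               "no lines")
})

test_that("FASTA output round-trips through file I/O", {
  utr <- simulate_utr_fasta("deterministic")
  f <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(utr$fasta, f)
  calls <- call_haplotypes(f)
  expect_equal(nrow(calls), 42)
  expect_equal(sum(calls$haplotype == "SNP3G"), 12)
})
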