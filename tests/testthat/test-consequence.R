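test_that("CDS SNVs translate to the expected coding terms", {
  f <- toy_coding_fixture()
  at <- f$cds_at
  # codon 2 GAA -> TAA via G>T at its first base
  expect_equal(assign_consequences("1", at + 3, "G", "T", f$tx, f$genome),
               "stop_gained")
  # synonymous: GAA -> GAG (both Glu)
  expect_equal(assign_consequences("1", at + 5, "A", "G", f$tx, f$genome),
               "synonymous_variant")
  # missense: GAA -> GCA
  expect_equal(assign_consequences("1", at + 4, "A", "C", f$tx, f$genome),
               "missense_variant")
  # stop codon TAA -> TAG is still a stop: synonymous by convention
  expect_equal(assign_consequences("1", at + 8, "A", "G", f$tx, f$genome),
               "synonymous_variant")
  # stop codon TAA -> CAA loses the stop
  expect_equal(assign_consequences("1", at + 6, "T", "C", f$tx, f$genome),
               "stop_lost")
  # any SNV in codon 1 disrupts the start
  expect_equal(assign_consequences("1", at, "A", "G", f$tx, f$genome),
               "start_lost")
  # outside the transcript span: no interaction
  expect_equal(assign_consequences("1", 2, substr(f$genome, 2, 2),
                                   setdiff(c("A","C","G","T"),
                                           substr(f$genome, 2, 2))[1],
                                   f$tx, f$genome),
               character(0))
  expect_error(assign_consequences("1", at + 3, "C", "T", f$tx, f$genome),
               "reference mismatch")
})

test_that("every CDS SNV receives exactly one coding term", {
  f <- toy_spliced_fixture("+")
  coding <- c("synonymous_variant", "missense_variant", "stop_gained",
              "stop_lost", "start_lost")
  for (p in c(51:62, 83:97)) {
    b <- substr(f$genome, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), b)) {
      terms <- assign_consequences("1", p, b, alt, f$tx, f$genome)
      expect_length(intersect(terms, coding), 1)
    }
  }
})

test_that("indels follow the length-mod-3 rule and exclude each other", {
  f <- toy_coding_fixture()
  at <- f$cds_at
  # 1-base deletion inside the CDS
  expect_equal(assign_consequences("1", at + 4, "A", "", f$tx, f$genome),
               "frameshift_variant")
  # 3-base deletion aligned inside the CDS
  ref3 <- substr(f$genome, at + 3, at + 5)
  expect_equal(assign_consequences("1", at + 3, ref3, "", f$tx, f$genome),
               "inframe_deletion")
  # insertion of 2 bases
  expect_equal(assign_consequences("1", at + 4, "", "GG", f$tx, f$genome),
               "frameshift_variant")
  expect_equal(assign_consequences("1", at + 4, "", "GGG", f$tx, f$genome),
               "inframe_insertion")
})

test_that("splice windows are strand-aware and intron terms assigned", {
  for (strand in c("+", "-")) {
    f <- toy_spliced_fixture(strand)
    # intron is 63..82; on + strand donor = 63,64 and acceptor = 81,82
    donor <- if (strand == "+") c(63, 64) else c(81, 82)
    acceptor <- if (strand == "+") c(81, 82) else c(63, 64)
    for (p in donor) {
      b <- substr(f$genome, p, p)
      expect_equal(assign_consequences("1", p, b, setdiff(c("A","C","G","T"), b)[1],
                                       f$tx, f$genome),
                   "splice_donor_variant", info = paste("strand", strand))
    }
    for (p in acceptor) {
      b <- substr(f$genome, p, p)
      expect_equal(assign_consequences("1", p, b, setdiff(c("A","C","G","T"), b)[1],
                                       f$tx, f$genome),
                   "splice_acceptor_variant", info = paste("strand", strand))
    }
    p <- 70  # middle of the intron
    b <- substr(f$genome, p, p)
    expect_equal(assign_consequences("1", p, b, setdiff(c("A","C","G","T"), b)[1],
                                     f$tx, f$genome),
                 "intron_variant", info = paste("strand", strand))
  }
})

test_that("boundary-spanning indels take the splice classification", {
  f <- toy_spliced_fixture("+")
  # deletion spanning last CDS base of exon1 (62) and donor bases (63, 64)
  ref <- substr(f$genome, 62, 64)
  terms <- assign_consequences("1", 62, ref, "", f$tx, f$genome)
  expect_true("splice_donor_variant" %in% terms)
  expect_false(any(c("frameshift_variant", "inframe_deletion") %in% terms))
})

test_that("UTR positions are classified strand-aware", {
  cfg <- sim_config(seed = 5, n_genes = 1, n_families = 2,
                    etiologies = list())
  ref <- simulate_reference(cfg, file.path(tempdir(), "csqref"))
  tx <- ref$transcripts[[1]]
  u5 <- ref$sites[site_type == "utr5"][1]
  expect_equal(assign_consequences("1", u5$pos, u5$ref, u5$alt, tx, ref$genome),
               "5_prime_UTR_variant")
  # a base in the 3' UTR (after the CDS end on the + strand)
  p <- max(tx$cds$end) + 10
  b <- substr(ref$genome[["1"]], p, p)
  expect_equal(assign_consequences("1", p, b, setdiff(c("A","C","G","T"), b)[1],
                                   tx, ref$genome),
               "3_prime_UTR_variant")
})

test_that("seqfx emits rows only for interacting pairs with nonzero masks", {
  f <- toy_coding_fixture()
  at <- f$cds_at
  variants <- data.frame(chrom = "1", pos = c(at + 3, 2),
                         ref = c("G", substr(f$genome, 2, 2)),
                         alt = c("T", setdiff(c("A","C","G","T"),
                                              substr(f$genome, 2, 2))[1]))
  out <- seqfx(variants, list(f$tx), f$genome)
  expect_equal(nrow(out), 1)
  expect_equal(out$transcript_id, "toy.t1")
  expect_true(meets_impact(out$csq, "high"))
})
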