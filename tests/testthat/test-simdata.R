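test_that("identical seeds produce byte-identical artifacts", {
  cfg <- sim_config(seed = 31, n_families = 30, n_genes = 2,
                    etiologies = list(list(
                      gene = 1, moi = "dominant", variant_class = "high",
                      n_variants = 2, penetrance = 1, phenocopy = 0,
                      case_set = "D", disease_group = "DG",
                      n_carrier_families = 3)),
                    phenotype_cluster = list(case_set = "D", n_terms = 2))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    ref <- simulate_reference(cfg, d)
    cohort <- simulate_cohort(cfg, ref, d)
    simulate_annotations(cfg, ref, cohort, d)
  }
  for (fn in c("ref.fa", "transcripts.gtf", "cohort.vcf", "cohort.ped",
               "samples.tsv", "case_sets.tsv", "truth.tsv", "ref_counts.tsv",
               "cadd.tsv", "panels.tsv", "ontology.obo",
               "family_terms.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))), label = fn)
  }
})

test_that("reference structure is internally consistent", {
  cfg <- sim_config(seed = 32, n_genes = 3, n_families = 2,
                    etiologies = list())
  ref <- simulate_reference(cfg, file.path(tempdir(), "refstruct"))
  tx <- read_transcripts_gtf(ref$gtf)
  expect_length(tx, 3)
  genome <- read_genome_fasta(ref$fasta)
  for (t in tx) {
    # CDS within exons is enforced by the constructor; check phase and stops
    cds <- cds_seq <- rsvr:::cds_sequence(t, genome)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_equal(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")
  }
  # planted site catalogue is recovered by the consequence module
  for (st in c("stop_gained", "missense", "frameshift", "utr5")) {
    sites <- as.data.frame(ref$sites)
    s <- sites[sites$site_type == st & sites$gene_id == "G1", ][1, ]
    terms <- assign_consequences("1", s$pos, s$ref, s$alt,
                                 ref$transcripts[["G1.t1"]], genome)
    want <- c(stop_gained = "stop_gained", missense = "missense_variant",
              frameshift = "frameshift_variant",
              utr5 = "5_prime_UTR_variant")[[st]]
    expect_true(want %in% terms, info = st)
  }
})

test_that("cohorts are Mendelian and penetrance shapes the truth table", {
  cfg <- sim_config(seed = 33, n_families = 60, n_genes = 2,
                    etiologies = list(list(
                      gene = 1, moi = "dominant", variant_class = "high",
                      n_variants = 2, penetrance = 1, phenocopy = 0,
                      case_set = "D", disease_group = "DG",
                      n_carrier_families = 5)),
                    phenotype_cluster = list(case_set = "D", n_terms = 2))
  ref <- simulate_reference(cfg, file.path(tempdir(), "mend"))
  cohort <- simulate_cohort(cfg, ref, file.path(tempdir(), "mend"))
  G <- cohort$genotype_matrix
  ped <- data.table::fread(cohort$ped,
                           col.names = c("family_id", "sample_id", "father",
                                         "mother", "sex", "phenotype"))
  # independent transmission checks on every child x variant
  kids <- ped[ped$father != "0", ]
  for (i in seq_len(nrow(kids))) {
    k <- G[kids$sample_id[i], ]
    f <- G[kids$father[i], ]; m <- G[kids$mother[i], ]
    expect_true(all(f[k == 2] >= 1 & m[k == 2] >= 1))
    expect_true(all((f + m)[k >= 1] >= 1))
    expect_true(all(k[f == 2 & m == 2] == 2))
    expect_true(all(k[f == 0 & m == 0] == 0))
    expect_true(all(k[f == 2 & m == 0] == 1))
  }
  # degenerate penetrance: every configuration carrier is affected
  expect_true(all(cohort$affected[cohort$config]))
  # with zero phenocopy rate, every affected sample carries a configuration
  expect_true(all(cohort$config[cohort$affected]))
})

test_that("annotations place planted variants outside the reference", {
  cfg <- sim_config(seed = 34, n_families = 40, n_genes = 2,
                    etiologies = list(list(
                      gene = 1, moi = "dominant", variant_class = "high",
                      n_variants = 2, penetrance = 1, phenocopy = 0,
                      case_set = "D", disease_group = "DG",
                      n_carrier_families = 4)),
                    phenotype_cluster = list(case_set = "D", n_terms = 2))
  dir <- file.path(tempdir(), "annet")
  ref <- simulate_reference(cfg, dir)
  cohort <- simulate_cohort(cfg, ref, dir)
  ann <- simulate_annotations(cfg, ref, cohort, dir)
  rc <- read_population_counts(ann$ref_counts)
  truth <- data.table::fread(cohort$truth)
  planted_ids <- encode_rsvr(truth$chrom, truth$pos, truth$ref, truth$alt)$id
  expect_false(any(planted_ids %in% rc$rsvr_id))
  expect_true(all(pmaf_scores(planted_ids, rc) == 3L))
  # a genuinely common background variant scores 0
  common <- cohort$variants[cohort$variants$freq > 0.02, ][1, ]
  cid <- encode_rsvr(common$chrom, common$pos, common$ref, common$alt)$id
  if (cid %in% rc$rsvr_id) {
    expect_equal(pmaf_scores(cid, rc), 0L)
  }
})
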