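# Build inputs shared by the database tests: a tiny reference with one gene
# plus a hand-assembled merged VCF exercising every build-stage filter.
make_build_fixture <- function(dir) {
  cfg <- sim_config(seed = 21, n_genes = 1, n_families = 2,
                    etiologies = list())
  ref <- simulate_reference(cfg, dir)
  sites <- ref$sites
  stop1 <- sites[sites$site_type == "stop_gained", ][1, ]
  stop2 <- sites[sites$site_type == "stop_gained", ][2, ]
  mis <- sites[sites$site_type == "missense", ][1, ]
  u5 <- sites[sites$site_type == "utr5", ][1, ]
  samples <- sprintf("S%04d", 1:1500)
  gt <- function(carriers, hom = character(0)) {
    g <- stats::setNames(rep("0/0", length(samples)), samples)
    g[carriers] <- "0/1"
    g[hom] <- "1/1"
    paste0(g, ":99")
  }
  rows <- c(
    # rare variant kept end to end (2 carriers / 3000 alleles)
    paste(c("1", stop1$pos, ".", stop1$ref, stop1$alt, "100", "PASS", ".",
            "GT:GQ", gt(c("S001", "S002"))), collapse = "\t"),
    # internally common variant (MAF 0.01)
    paste(c("1", mis$pos, ".", mis$ref, mis$alt, "100", "PASS", ".",
            "GT:GQ", gt(samples[1:30])), collapse = "\t"),
    # non-PASS record
    paste(c("1", u5$pos, ".", u5$ref, u5$alt, "100", "lowq", ".",
            "GT:GQ", gt("S003")), collapse = "\t"),
    # rare in cohort but common in the population reference (PMAF 0)
    paste(c("1", stop2$pos, ".", stop2$ref, stop2$alt, "100", "PASS", ".",
            "GT:GQ", gt("S004")), collapse = "\t"))
  vcf <- file.path(dir, "mini.vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               rows), vcf)
  sheet <- file.path(dir, "samples.tsv")
  data.table::fwrite(data.table::data.table(
    sample_id = samples, sex = "F",
    family_id = paste0("FAM_", samples), unrelated_flag = 1L,
    ancestry = "SIM", affected_flag = 0L), sheet, sep = "\t")
  refc <- file.path(dir, "refcounts.tsv")
  common_id <- encode_rsvr(stop2$chrom, stop2$pos, stop2$ref, stop2$alt)$id
  data.table::fwrite(data.table::data.table(
    rsvr_id = common_id, population = "POP1", ac = 500L, an = 20000L,
    ac_male = NA_integer_, an_male = NA_integer_), refc, sep = "\t")
  list(cfg = cfg, ref = ref, vcf = vcf, sheet = sheet, refc = refc,
       stop1 = stop1, mis = mis, u5 = u5, stop2 = stop2)
}

test_that("the staged build applies every filter and reports counts", {
  dir <- file.path(tempdir(), "resv1")
  f <- make_build_fixture(dir)
  db <- file.path(dir, "mini.db")
  unlink(db)
  cfg <- build_config(vcf = f$vcf, sample_sheet = f$sheet,
                      ref_counts = f$refc, gtf = f$ref$gtf,
                      fasta = f$ref$fasta, seed = 1)
  b <- build_reservoir(cfg, db)
  r <- b$report
  expect_equal(r$records_read, 4)
  expect_equal(r$records_pass_filter, 3)   # non-PASS dropped
  expect_equal(r$internal_af_deleted, 1)   # the MAF 0.05 variant
  expect_equal(r$pmaf0_deleted, 1)         # common in the reference
  expect_equal(r$variants_final, 1)
  con <- rsvr_connect(db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  v <- DBI::dbGetQuery(con, "SELECT * FROM VARIANT")
  expect_equal(v$rsvr_id,
               encode_rsvr(f$stop1$chrom, f$stop1$pos, f$stop1$ref,
                           f$stop1$alt)$id)
  expect_equal(v$pmaf, 3L)  # absent from the reference
  # referential integrity
  orphan_g <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) n FROM GENOTYPE g LEFT JOIN VARIANT v
      ON v.rsvr_id = g.rsvr_id WHERE v.rsvr_id IS NULL")$n
  orphan_c <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) n FROM CONSEQUENCE c LEFT JOIN TX t
      ON t.transcript_id = c.transcript_id WHERE t.transcript_id IS NULL")$n
  expect_equal(orphan_g + orphan_c, 0)
  expect_equal(build_report(con)$variants_final, 1)
})

test_that("an empty input builds a valid empty database", {
  dir <- file.path(tempdir(), "resv2")
  f <- make_build_fixture(dir)
  empty_vcf <- file.path(dir, "empty.vcf")
  lines <- readLines(f$vcf)
  writeLines(lines[startsWith(lines, "#")], empty_vcf)
  db <- file.path(dir, "empty.db")
  unlink(db)
  b <- build_reservoir(build_config(vcf = empty_vcf, sample_sheet = f$sheet,
                                    gtf = f$ref$gtf, fasta = f$ref$fasta),
                       db)
  expect_equal(b$report$records_read, 0)
  expect_equal(b$report$variants_final, 0)
  con <- rsvr_connect(db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  expect_equal(DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM GENOTYPE")$n, 0)
})

test_that("rebuilding from identical inputs is byte-reproducible", {
  dir <- file.path(tempdir(), "resv3")
  f <- make_build_fixture(dir)
  cfg <- build_config(vcf = f$vcf, sample_sheet = f$sheet,
                      ref_counts = f$refc, gtf = f$ref$gtf,
                      fasta = f$ref$fasta, seed = 5)
  db1 <- file.path(dir, "a.db"); db2 <- file.path(dir, "b.db")
  unlink(c(db1, db2))
  build_reservoir(cfg, db1)
  build_reservoir(cfg, db2)
  c1 <- rsvr_connect(db1); c2 <- rsvr_connect(db2)
  on.exit({DBI::dbDisconnect(c1); DBI::dbDisconnect(c2)}, add = TRUE)
  for (tab in c("VARIANT", "GENOTYPE", "CONSEQUENCE", "SAMPLE", "TX")) {
    expect_identical(DBI::dbReadTable(c1, tab), DBI::dbReadTable(c2, tab),
                     label = tab)
  }
})

test_that("gene variant queries filter by class and PMAF", {
  dir <- file.path(tempdir(), "resv4")
  f <- make_build_fixture(dir)
  db <- file.path(dir, "q.db")
  unlink(db)
  build_reservoir(build_config(vcf = f$vcf, sample_sheet = f$sheet,
                               ref_counts = f$refc, gtf = f$ref$gtf,
                               fasta = f$ref$fasta), db)
  con <- rsvr_connect(db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  expect_equal(nrow(query_gene_variants(con, "G1", "high", 1)), 1)
  expect_equal(nrow(query_gene_variants(con, "G1", "high", 3)), 1)
  expect_equal(nrow(query_gene_variants(con, "G1", "utr5", 1)), 0)
  expect_error(query_gene_variants(con, "NOPE", "high"), "unknown gene")
})

test_that("participants are classified against a case set", {
  dir <- file.path(tempdir(), "resv5")
  f <- make_build_fixture(dir)
  # trio family plus an unrelated control family
  sheet <- file.path(dir, "trio.tsv")
  data.table::fwrite(data.table::data.table(
    sample_id = c("kid", "dad", "mum", "ctrl", "ctrl_rel"),
    sex = c("F", "M", "F", "M", "F"),
    family_id = c("T1", "T1", "T1", "C1", "C1"),
    unrelated_flag = c(1L, 1L, 0L, 1L, 0L),
    ancestry = "SIM", affected_flag = c(1L, 0L, 0L, 0L, 0L)), sheet,
    sep = "\t")
  cs <- file.path(dir, "cs.tsv")
  data.table::fwrite(data.table::data.table(
    name = "DiseaseT", level = "specific_disease", disease_group = "DG",
    sample_id = "kid"), cs, sep = "\t")
  empty_vcf <- file.path(dir, "e.vcf")
  lines <- readLines(f$vcf)
  writeLines(c(lines[startsWith(lines, "##")],
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "kid", "dad", "mum", "ctrl",
                       "ctrl_rel"), collapse = "\t")), empty_vcf)
  db <- file.path(dir, "t.db")
  unlink(db)
  build_reservoir(build_config(vcf = empty_vcf, sample_sheet = sheet,
                               case_sets = cs, gtf = f$ref$gtf,
                               fasta = f$ref$fasta), db)
  con <- rsvr_connect(db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  lab <- classify_participants(con, "DiseaseT")
  got <- stats::setNames(lab$label, lab$sample_id)
  expect_equal(unname(got["kid"]), "case_proband")
  expect_equal(unname(got[c("dad", "mum")]), rep("case_relative", 2))
  expect_equal(unname(got["ctrl"]), "control")
  expect_equal(unname(got["ctrl_rel"]), "control_relative")
  expect_error(classify_participants(con, "NOPE"), "unknown or empty")
})
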