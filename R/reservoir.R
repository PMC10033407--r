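#' Open (or create) a reservoir database
#'
#' @param path SQLite file path (":memory:" for transient databases).
#' @return a DBI connection.
#' @export
rsvr_connect <- function(path) {
  DBI::dbConnect(RSQLite::SQLite(), path)
}

SCHEMA_DDL <- c(
  "CREATE TABLE IF NOT EXISTS VARIANT (
     rsvr_id TEXT PRIMARY KEY, pmaf INTEGER, cadd REAL, gq_median REAL)",
  "CREATE TABLE IF NOT EXISTS OVERFLOW_VARIANT (
     rsvr_id TEXT PRIMARY KEY, chrom INTEGER, pos INTEGER, ref TEXT, alt TEXT)",
  "CREATE TABLE IF NOT EXISTS GENOTYPE (
     sample_id TEXT, rsvr_id TEXT, allele_count INTEGER)",
  "CREATE TABLE IF NOT EXISTS CONSEQUENCE (
     rsvr_id TEXT, transcript_id TEXT, csq REAL, loftee TEXT)",
  "CREATE TABLE IF NOT EXISTS SAMPLE (
     sample_id TEXT PRIMARY KEY, sex TEXT, family_id TEXT,
     unrelated_flag INTEGER, ancestry TEXT, affected_flag INTEGER)",
  "CREATE TABLE IF NOT EXISTS TX (
     transcript_id TEXT PRIMARY KEY, gene_id TEXT, chrom TEXT, strand TEXT,
     biotype TEXT, canonical INTEGER)",
  "CREATE TABLE IF NOT EXISTS FEATURE (
     transcript_id TEXT, type TEXT, start INTEGER, end INTEGER)",
  "CREATE TABLE IF NOT EXISTS GENE (gene_id TEXT PRIMARY KEY, symbol TEXT)",
  "CREATE TABLE IF NOT EXISTS PHENOTYPE (term_id TEXT PRIMARY KEY, name TEXT)",
  "CREATE TABLE IF NOT EXISTS SAMPLE_PHENOTYPE (sample_id TEXT, term_id TEXT)",
  "CREATE TABLE IF NOT EXISTS CASE_SET (
     name TEXT, level TEXT, disease_group TEXT, sample_id TEXT)",
  "CREATE TABLE IF NOT EXISTS META (key TEXT PRIMARY KEY, value TEXT)")

SCHEMA_INDEXES <- c(
  "CREATE INDEX IF NOT EXISTS idx_geno_rsvr ON GENOTYPE (rsvr_id)",
  "CREATE INDEX IF NOT EXISTS idx_geno_sample ON GENOTYPE (sample_id)",
  "CREATE INDEX IF NOT EXISTS idx_csq_rsvr ON CONSEQUENCE (rsvr_id)",
  "CREATE INDEX IF NOT EXISTS idx_csq_tx ON CONSEQUENCE (transcript_id)",
  "CREATE INDEX IF NOT EXISTS idx_tx_gene ON TX (gene_id)",
  "CREATE INDEX IF NOT EXISTS idx_cs_name ON CASE_SET (name)")

#' Create the reservoir schema
#'
#' Tables: VARIANT (id, PMAF, CADD, median GQ), OVERFLOW_VARIANT (full
#' alleles of ambiguously encoded variants), GENOTYPE (non-reference calls
#' only), CONSEQUENCE, SAMPLE, TX/FEATURE/GENE (transcript models),
#' PHENOTYPE/SAMPLE_PHENOTYPE, CASE_SET and META.
#'
#' @param con a connection from [rsvr_connect()].
#' @export
rsvr_create_schema <- function(con) {
  for (ddl in SCHEMA_DDL) DBI::dbExecute(con, ddl)
  invisible(con)
}

rsvr_index <- function(con) {
  for (ddl in SCHEMA_INDEXES) DBI::dbExecute(con, ddl)
  invisible(con)
}

#' Build configuration
#'
#' @param input_mode "merged_vcf" or "gvcf_set".
#' @param vcf merged VCF path, or character vector of per-sample VCF paths.
#' @param sample_sheet TSV with columns sample_id, sex, family_id,
#'   unrelated_flag, ancestry, affected_flag.
#' @param case_sets optional TSV with columns name, level, disease_group,
#'   sample_id.
#' @param ref_counts population allele-count TSV (see
#'   [read_population_counts()]); NULL scores everything 3.
#' @param cadd optional pathogenicity-score TSV.
#' @param gtf transcript-model GTF.
#' @param fasta reference FASTA.
#' @param loftee optional TSV with columns rsvr_id, transcript_id, loftee.
#' @param depth_records optional TSV (sample, start, end, pass) of gVCF
#'   coverage records for the subsampled files; required for the depth
#'   pass-rate prefilter, which is skipped (and logged) when absent because
#'   plain VCFs carry no reference-coverage blocks.
#' @param internal_maf within-cohort MAF threshold (default 0.002).
#' @param depth_threshold minimum gVCF pass rate (gvcf mode, default 0.9).
#' @param subsample_size gVCF subsample size for the prefilters (default 10).
#' @param seed subsampling seed (recorded in the build report).
#' @return a build_config list.
#' @export
build_config <- function(input_mode = c("merged_vcf", "gvcf_set"), vcf,
                         sample_sheet, case_sets = NULL, ref_counts = NULL,
                         cadd = NULL, gtf, fasta, loftee = NULL,
                         depth_records = NULL, internal_maf = 0.002,
                         depth_threshold = 0.9, subsample_size = 10,
                         seed = 1) {
  stopifnot(internal_maf > 0, internal_maf < 1,
            depth_threshold > 0, depth_threshold < 1)
  list(input_mode = match.arg(input_mode), vcf = vcf,
       sample_sheet = sample_sheet, case_sets = case_sets,
       ref_counts = ref_counts, cadd = cadd, gtf = gtf, fasta = fasta,
       loftee = loftee, depth_records = depth_records,
       internal_maf = internal_maf,
       depth_threshold = depth_threshold, subsample_size = subsample_size,
       seed = seed)
}

# Parse one (single- or multi-sample) VCF into per-alt variant records and
# long-format non-reference genotypes. Multiallelic rows must be split
# upstream (bcftools norm -m -), matching the build procedure's use of
# bcftools for extraction and normalization.
parse_vcf_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alts) > 1)) {
    stop("multiallelic records in ", path,
         "; split them first (bcftools norm -m -)")
  }
  filt <- as.character(VariantAnnotation::filt(vcf))
  variants <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alts)),
    filter = filt)
  gt <- VariantAnnotation::geno(vcf)$GT
  gq <- if ("GQ" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$GQ else NULL
  if (nrow(variants) == 0) {
    return(list(variants = variants, genotypes = NULL,
                samples = if (is.null(gt)) character(0) else colnames(gt)))
  }
  n_alt <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) sum(x == "1"), integer(1))
  }
  long <- NULL
  if (!is.null(gt) && ncol(gt) > 0) {
    ac <- apply(gt, 2, n_alt)
    ac <- matrix(ac, nrow = nrow(variants),
                 dimnames = list(NULL, colnames(gt)))
    idx <- which(ac > 0, arr.ind = TRUE)
    long <- data.table(row = idx[, 1], sample_id = colnames(gt)[idx[, 2]],
                       allele_count = ac[idx])
    if (!is.null(gq)) {
      variants$gq_median <- apply(gq, 1, function(x) {
        stats::median(suppressWarnings(as.numeric(x)), na.rm = TRUE)
      })
    }
  }
  list(variants = variants, genotypes = long,
       samples = if (is.null(gt)) character(0) else colnames(gt))
}

db_count <- function(con, table) {
  DBI::dbGetQuery(con, paste0("SELECT COUNT(*) AS n FROM ", table))$n
}

#' Build a reservoir database
#'
#' Runs the staged build procedure: extract and normalize variants, encode
#' ids, (gVCF mode: drop almost-surely-common variants and sites failing the
#' depth pass-rate threshold; merged mode: keep PASSing records only), load
#' non-reference genotypes, delete internally common variants, annotate PMAF
#' scores and delete variants with PMAF 0, attach pathogenicity scores,
#' annotate transcript consequences and keep only variants with at least one
#' consequence on a canonical transcript, then load sample metadata and case
#' sets and index. Every stage's record count is returned in the report and
#' stored in the META table as JSON.
#'
#' @param cfg a [build_config()].
#' @param db_path output SQLite file.
#' @return the build report (named list of stage counts), invisibly the path.
#' @export
build_reservoir <- function(cfg, db_path) {
  con <- rsvr_connect(db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  rsvr_create_schema(con)
  report <- list(input_mode = cfg$input_mode, seed = cfg$seed)

  if (cfg$input_mode == "merged_vcf") {
    parsed <- parse_vcf_genotypes(cfg$vcf)
    report$records_read <- nrow(parsed$variants)
    keep <- parsed$variants$filter == "PASS"
    parsed$variants <- parsed$variants[keep]
    if (!is.null(parsed$genotypes)) {
      parsed$genotypes <- parsed$genotypes[row %in% which(keep)]
      parsed$genotypes$row <- match(parsed$genotypes$row, which(keep))
    }
    report$records_pass_filter <- nrow(parsed$variants)
    samples <- parsed$samples
  } else {
    pieces <- lapply(cfg$vcf, parse_vcf_genotypes)
    report$records_read <- sum(vapply(pieces, function(p) nrow(p$variants),
                                      numeric(1)))
    # prefilters on a seeded subsample of gVCFs
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
    sub <- sample(seq_along(pieces), min(cfg$subsample_size, length(pieces)))
    subcounts <- rbindlist(lapply(pieces[sub], function(p) {
      v <- p$variants
      v$id <- encode_variants(v)$id
      g <- p$genotypes
      if (is.null(g) || nrow(g) == 0) return(NULL)
      data.table(rsvr_id = v$id[g$row], ac = g$allele_count)
    }))
    common <- character(0)
    if (nrow(subcounts) > 0) {
      an_sub <- 2 * length(sub)
      counts <- subcounts[, list(ac = sum(ac), an = an_sub), by = rsvr_id]
      common <- tabulate_common(counts)
    }
    report$tabulate_common_dropped <- length(common)
    merged <- rbindlist(lapply(pieces, function(p) {
      v <- p$variants
      g <- p$genotypes
      if (is.null(g) || nrow(g) == 0) return(NULL)
      cbind(v[g$row], g[, list(sample_id, allele_count)])
    }))
    merged$id <- encode_variants(merged)$id
    merged <- merged[!(id %in% common)]
    if (!is.null(cfg$depth_records) && nrow(merged) > 0) {
      recs <- fread(cfg$depth_records)
      pr <- depth_pass_rate(recs, unique(merged$pos))
      ok_pos <- pr$pos[pr$pass_rate >= cfg$depth_threshold]
      report$depth_dropped <- length(unique(merged$pos)) - length(ok_pos)
      merged <- merged[pos %in% ok_pos]
    } else {
      report$depth_dropped <- NA
    }
    report$records_pass_filter <- length(unique(merged$id))
    parsed <- list(
      variants = unique(merged[, list(chrom, pos, ref, alt, filter)]),
      genotypes = NULL)
    samples <- unique(merged$sample_id)
  }

  # normalize + encode
  v <- parsed$variants
  if (nrow(v) > 0) {
    norm <- normalize_variant(v$chrom, v$pos, v$ref, v$alt)
    enc <- encode_rsvr(chrom_name(norm$chrom), norm$pos, norm$ref, norm$alt)
    v$id <- enc$id
    v$ambiguous <- enc$ambiguous
    v <- cbind(norm[, list(nchrom = chrom, npos = pos, nref = ref, nalt = alt)], v)
  } else {
    v <- data.table(nchrom = integer(0), npos = integer(0),
                    nref = character(0), nalt = character(0),
                    chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    filter = character(0), id = character(0),
                    ambiguous = logical(0))
  }

  # long genotype table keyed by id
  if (cfg$input_mode == "merged_vcf") {
    g <- parsed$genotypes
    geno <- if (is.null(g) || nrow(g) == 0) {
      data.table(sample_id = character(0), rsvr_id = character(0),
                 allele_count = integer(0))
    } else {
      data.table(sample_id = g$sample_id, rsvr_id = v$id[g$row],
                 allele_count = g$allele_count)
    }
  } else {
    geno <- if (nrow(merged) == 0) {
      data.table(sample_id = character(0), rsvr_id = character(0),
                 allele_count = integer(0))
    } else {
      norm2 <- normalize_variant(merged$chrom, merged$pos, merged$ref, merged$alt)
      data.table(sample_id = merged$sample_id,
                 rsvr_id = encode_rsvr(chrom_name(norm2$chrom), norm2$pos,
                                       norm2$ref, norm2$alt)$id,
                 allele_count = merged$allele_count)
    }
  }
  report$genotypes_loaded <- nrow(geno)

  sheet <- fread(cfg$sample_sheet)
  n_samples <- nrow(sheet)

  # internal allele-frequency filter
  drop_af <- internal_af_filter(geno, n_samples, threshold = cfg$internal_maf)
  geno <- geno[!(rsvr_id %in% drop_af)]
  v <- v[!(id %in% drop_af)]
  report$internal_af_deleted <- length(drop_af)

  # PMAF annotation; variants with PMAF 0 are deleted
  ref_counts <- if (is.null(cfg$ref_counts)) NULL
                else read_population_counts(cfg$ref_counts)
  uids <- unique(v$id)
  pm <- if (is.null(ref_counts)) rep(3L, length(uids))
        else pmaf_scores(uids, ref_counts)
  pmaf_map <- stats::setNames(pm, uids)
  drop_pmaf <- uids[pm == 0]
  v <- v[!(id %in% drop_pmaf)]
  geno <- geno[!(rsvr_id %in% drop_pmaf)]
  report$pmaf0_deleted <- length(drop_pmaf)

  # pathogenicity scores
  cadd <- if (is.null(cfg$cadd)) NULL else read_cadd_scores(cfg$cadd)

  # transcript consequences; keep variants hitting a canonical transcript
  transcripts <- read_transcripts_gtf(cfg$gtf)
  canonical <- Filter(function(tx) tx$canonical, transcripts)
  genome <- read_genome_fasta(cfg$fasta)
  vu <- unique(v[, list(chrom = nchrom, pos = npos, ref = nref, alt = nalt, id)])
  csq <- seqfx(vu, canonical, genome)
  if (!is.null(cfg$loftee)) {
    lof <- fread(cfg$loftee, colClasses = list(character = "rsvr_id"))
    csq <- merge(csq, lof, by = c("rsvr_id", "transcript_id"), all.x = TRUE)
  } else {
    csq$loftee <- NA_character_
  }
  with_csq <- unique(csq$rsvr_id)
  report$no_consequence_deleted <- length(setdiff(unique(v$id), with_csq))
  v <- v[id %in% with_csq]
  geno <- geno[rsvr_id %in% with_csq]

  # load tables
  uv <- unique(v, by = "id")
  variant_tbl <- data.table(
    rsvr_id = uv$id, pmaf = as.integer(pmaf_map[uv$id]),
    cadd = if (is.null(cadd)) NA_real_ else cadd$cadd[match(uv$id, cadd$rsvr_id)],
    gq_median = if ("gq_median" %in% names(uv)) uv$gq_median else NA_real_)
  DBI::dbWriteTable(con, "VARIANT", variant_tbl, append = TRUE)
  over <- uv[ambiguous == TRUE,
             list(rsvr_id = id, chrom = nchrom, pos = npos, ref = nref, alt = nalt)]
  if (nrow(over) > 0) DBI::dbWriteTable(con, "OVERFLOW_VARIANT", over, append = TRUE)
  DBI::dbWriteTable(con, "GENOTYPE", geno, append = TRUE)
  DBI::dbWriteTable(con, "CONSEQUENCE",
                    csq[, list(rsvr_id, transcript_id, csq, loftee)],
                    append = TRUE)

  tx_tbl <- rbindlist(lapply(transcripts, function(tx) {
    data.table(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
               chrom = tx$chrom, strand = tx$strand, biotype = tx$biotype,
               canonical = as.integer(tx$canonical))
  }))
  if (nrow(tx_tbl) > 0) DBI::dbWriteTable(con, "TX", tx_tbl, append = TRUE)
  feat_tbl <- rbindlist(lapply(transcripts, function(tx) {
    rbind(data.table(transcript_id = tx$transcript_id, type = "exon",
                     start = tx$exons$start, end = tx$exons$end),
          if (nrow(tx$cds) > 0)
            data.table(transcript_id = tx$transcript_id, type = "CDS",
                       start = tx$cds$start, end = tx$cds$end))
  }))
  if (nrow(feat_tbl) > 0) DBI::dbWriteTable(con, "FEATURE", feat_tbl, append = TRUE)
  if (nrow(tx_tbl) > 0) {
    DBI::dbWriteTable(con, "GENE",
                      unique(tx_tbl[, list(gene_id, symbol = gene_id)]),
                      append = TRUE)
  }

  DBI::dbWriteTable(con, "SAMPLE", sheet[, list(
    sample_id, sex, family_id,
    unrelated_flag = as.integer(unrelated_flag),
    ancestry = if ("ancestry" %in% names(sheet)) ancestry else NA_character_,
    affected_flag = as.integer(affected_flag))], append = TRUE)
  if (!is.null(cfg$case_sets)) {
    cs <- fread(cfg$case_sets)
    DBI::dbWriteTable(con, "CASE_SET",
                      cs[, list(name, level, disease_group, sample_id)],
                      append = TRUE)
  }
  rsvr_index(con)
  report$variants_final <- db_count(con, "VARIANT")
  report$genotypes_final <- db_count(con, "GENOTYPE")
  report$consequences_final <- db_count(con, "CONSEQUENCE")
  DBI::dbExecute(con, "INSERT OR REPLACE INTO META VALUES ('build_report', ?)",
                 params = list(jsonlite::toJSON(report, auto_unbox = TRUE)))
  invisible(structure(list(path = db_path, report = report),
                      class = "rsvr_build"))
}

# helper used by the gvcf branch above
encode_variants <- function(v) {
  norm <- normalize_variant(v$chrom, v$pos, v$ref, v$alt)
  encode_rsvr(chrom_name(norm$chrom), norm$pos, norm$ref, norm$alt)
}

#' Query qualifying variants of a gene
#'
#' Returns the variants of a gene whose consequence on any of its (canonical)
#' transcripts meets the impact class and whose PMAF score reaches
#' `pmaf_min`, with their consequence masks and scores, ordered by id.
#'
#' @param con reservoir connection.
#' @param gene_id gene identifier.
#' @param class impact class ("high", "moderate", "utr5").
#' @param pmaf_min minimum PMAF score (default 1).
#' @return data.table(rsvr_id, transcript_id, csq, loftee, pmaf, cadd,
#'   gq_median).
#' @export
query_gene_variants <- function(con, gene_id, class = "moderate",
                                pmaf_min = 1) {
  known <- DBI::dbGetQuery(con, "SELECT gene_id FROM GENE WHERE gene_id = ?",
                           params = list(gene_id))
  if (nrow(known) == 0) stop("unknown gene: ", gene_id)
  x <- DBI::dbGetQuery(con,
    "SELECT c.rsvr_id, c.transcript_id, c.csq, c.loftee,
            v.pmaf, v.cadd, v.gq_median
       FROM CONSEQUENCE c
       JOIN TX t ON t.transcript_id = c.transcript_id
       JOIN VARIANT v ON v.rsvr_id = c.rsvr_id
      WHERE t.gene_id = ? AND v.pmaf >= ?", params = list(gene_id, pmaf_min))
  setDT(x)
  x <- x[meets_impact(x$csq, class)]
  x[rsvr_order(rsvr_id)]
}

#' Classify every sample with respect to a case set
#'
#' Labels each sample as a case proband (affected member of the case set; one
#' per pedigree, chosen deterministically), a relative of a case, an
#' unrelated control, or a relative of a control.
#'
#' @param con reservoir connection.
#' @param case_set case-set name.
#' @return data.table(sample_id, label).
#' @export
classify_participants <- function(con, case_set) {
  members <- DBI::dbGetQuery(con,
    "SELECT sample_id FROM CASE_SET WHERE name = ?",
    params = list(case_set))$sample_id
  if (length(members) == 0) stop("unknown or empty case set: ", case_set)
  s <- setDT(DBI::dbGetQuery(con, "SELECT * FROM SAMPLE"))
  in_set <- s[sample_id %in% members]
  probands <- in_set[order(sample_id), list(sample_id = sample_id[1]),
                     by = family_id]$sample_id
  case_fams <- unique(in_set$family_id)
  s[, label := ifelse(sample_id %in% probands, "case_proband",
               ifelse(family_id %in% case_fams, "case_relative",
               ifelse(unrelated_flag == 1, "control", "control_relative")))]
  s[, list(sample_id, label)]
}

#' Genotypes of a variant set
#'
#' @param con reservoir connection.
#' @param variant_ids character vector of ids.
#' @return data.table(sample_id, rsvr_id, allele_count).
#' @export
query_genotypes <- function(con, variant_ids) {
  if (length(variant_ids) == 0) {
    return(data.table(sample_id = character(0), rsvr_id = character(0),
                      allele_count = integer(0)))
  }
  q <- sprintf("SELECT sample_id, rsvr_id, allele_count FROM GENOTYPE
                WHERE rsvr_id IN (%s)",
               paste(sprintf("'%s'", variant_ids), collapse = ","))
  setDT(DBI::dbGetQuery(con, q))[]
}

#' Build report stored in a reservoir
#'
#' @param con reservoir connection.
#' @return named list of stage counts.
#' @export
build_report <- function(con) {
  x <- DBI::dbGetQuery(con, "SELECT value FROM META WHERE key = 'build_report'")
  if (nrow(x) == 0) stop("no build report in this database")
  jsonlite::fromJSON(x$value)
}
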