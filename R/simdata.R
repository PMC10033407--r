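#' Simulation configuration
#'
#' The generator emulates the statistical structure the association model
#' assumes: pedigreed cohorts carrying rare pathogenic configurations at a
#' configurable penetrance over a rare-variant background whose site
#' frequency spectrum follows a discretized neutral 1/x density truncated to
#' the interval from 1/(2N) to `max_background_maf`, so that sub-0.1% variants account for a
#' small share of non-reference genotypes. Defaults: 1,000 families (60% trios,
#' 40% quads, about 3,400 samples so that variants private to a few
#' pedigrees sit below the 0.2% internal-frequency filter), 6 genes,
#' penetrance 0.95, phenocopy rate 0.005, 3 pathogenic
#' variants per etiology, 8 carrier families per etiology.
#'
#' @param seed integer seed; fully determines all output bytes.
#' @param n_families number of pedigrees.
#' @param quad_fraction fraction of 4-member pedigrees (rest are trios).
#' @param n_genes number of toy genes on the synthetic chromosome.
#' @param n_background_per_gene background variant sites per gene.
#' @param max_background_maf upper truncation of the background spectrum.
#' @param etiologies list of lists with elements gene (index), moi,
#'   variant_class, n_variants, penetrance, phenocopy, case_set,
#'   disease_group, n_carrier_families.
#' @param phenotype_cluster list(case_set, n_terms): the etiology whose
#'   carrier families share extra phenotype terms.
#' @return a sim_config list.
#' @export
sim_config <- function(seed = 1, n_families = 1000, quad_fraction = 0.4,
                       n_genes = 6, n_background_per_gene = 15,
                       max_background_maf = 0.05,
                       etiologies = list(
                         list(gene = 1, moi = "dominant",
                              variant_class = "high", n_variants = 3,
                              penetrance = 0.95, phenocopy = 0.005,
                              case_set = "Disease A", disease_group = "Group 1",
                              n_carrier_families = 8),
                         list(gene = 2, moi = "recessive",
                              variant_class = "high", n_variants = 6,
                              penetrance = 0.95, phenocopy = 0.005,
                              case_set = "Disease B", disease_group = "Group 1",
                              n_carrier_families = 6)),
                       phenotype_cluster = list(case_set = "Disease A",
                                                n_terms = 3)) {
  stopifnot(n_genes >= 1, n_families >= 2)
  for (e in etiologies) {
    stopifnot(e$gene <= n_genes, e$moi %in% c("dominant", "recessive"),
              e$variant_class %in% c("high", "moderate", "utr5"),
              e$penetrance >= 0, e$penetrance <= 1,
              e$phenocopy >= 0, e$phenocopy <= 1)
  }
  list(seed = seed, n_families = n_families, quad_fraction = quad_fraction,
       n_genes = n_genes, n_background_per_gene = n_background_per_gene,
       max_background_maf = max_background_maf, etiologies = etiologies,
       phenotype_cluster = phenotype_cluster)
}

GENE_SPAN <- 10000L
GENE_OFFSET <- 1000L
NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Simulate a toy reference genome and transcript models
#'
#' Lays `n_genes` three-exon plus-strand genes along one synthetic
#' chromosome. Each gene has a 100-codon CDS starting ATG and ending TAA,
#' with TGG codons planted at codons 10, 20, ..., 90 (one SNV from a stop)
#' and GCT codons at 15, 25, ..., 95 (one SNV from a missense change), a
#' 100 bp 5' UTR and 3' UTR, and 200 bp introns. Writes ref.fa and
#' transcripts.gtf and returns the planted-site catalogue used to position
#' etiological variants of every consequence class.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return list(genome, transcripts, genes, sites, fasta, gtf).
#' @export
simulate_reference <- function(cfg, dir) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_len <- GENE_OFFSET + cfg$n_genes * GENE_SPAN + 1000L
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  genes <- data.table(gene_id = sprintf("G%d", seq_len(cfg$n_genes)))
  genes$start <- GENE_OFFSET + (seq_len(cfg$n_genes) - 1L) * GENE_SPAN + 1L
  sites <- list()
  transcripts <- list()
  gtf_lines <- character(0)
  for (i in seq_len(cfg$n_genes)) {
    s <- genes$start[i]
    gid <- genes$gene_id[i]
    tid <- paste0(gid, ".t1")
    utr5 <- c(s, s + 99L)
    cds1 <- c(s + 100L, s + 198L)
    intron1 <- c(s + 199L, s + 398L)
    cds2 <- c(s + 399L, s + 497L)
    intron2 <- c(s + 498L, s + 697L)
    cds3 <- c(s + 698L, s + 799L)
    utr3 <- c(s + 800L, s + 899L)
    exons <- data.frame(start = c(utr5[1], cds2[1], cds3[1]),
                        end = c(cds1[2], cds2[2], utr3[2]))
    cds <- data.frame(start = c(cds1[1], cds2[1], cds3[1]),
                      end = c(cds1[2], cds2[2], cds3[2]))
    codons <- c("ATG", sample(NONSTOP_CODONS, 98, replace = TRUE), "TAA")
    codons[10 * 1:9] <- "TGG"
    codons[15 + 10 * 0:8] <- "GCT"
    cds_seq <- strsplit(paste(codons, collapse = ""), "")[[1]]
    cds_pos <- c(seq(cds1[1], cds1[2]), seq(cds2[1], cds2[2]),
                 seq(cds3[1], cds3[2]))
    seq_chars[cds_pos] <- cds_seq
    transcripts[[tid]] <- transcript_model(tid, gid, "1", "+", exons, cds)
    attr_str <- function(extra = "") {
      sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "protein_coding"; canonical "1";%s',
              gid, tid, extra)
    }
    feat <- function(type, st, en) {
      sprintf("1\tsim\t%s\t%d\t%d\t.\t+\t.\t%s", type, st, en, attr_str())
    }
    gtf_lines <- c(gtf_lines,
                   feat("gene", utr5[1], utr3[2]),
                   feat("transcript", utr5[1], utr3[2]),
                   feat("exon", exons$start[1], exons$end[1]),
                   feat("exon", exons$start[2], exons$end[2]),
                   feat("exon", exons$start[3], exons$end[3]),
                   feat("CDS", cds$start[1], cds$end[1]),
                   feat("CDS", cds$start[2], cds$end[2]),
                   feat("CDS", cds$start[3], cds$end[3]))
    # planted sites, positioned on the genomic CDS map
    stop_pos <- cds_pos[10 * 1:9 * 3]        # third base of each TGG codon
    mis_pos <- cds_pos[(15 + 10 * 0:8) * 3 - 1]  # second base of each GCT
    sites[[gid]] <- rbind(
      data.table(gene_id = gid, site_type = "stop_gained", chrom = "1",
                 pos = stop_pos, ref = "G", alt = "A"),
      data.table(gene_id = gid, site_type = "missense", chrom = "1",
                 pos = mis_pos, ref = "C", alt = "T"),
      data.table(gene_id = gid, site_type = "frameshift", chrom = "1",
                 pos = seq(cds2[1] + 10L, cds2[1] + 58L, by = 6L),
                 ref = seq_chars[seq(cds2[1] + 10L, cds2[1] + 58L, by = 6L)],
                 alt = ""),
      data.table(gene_id = gid, site_type = "utr5", chrom = "1",
                 pos = seq(utr5[1] + 10L, utr5[1] + 90L, by = 10L),
                 ref = seq_chars[seq(utr5[1] + 10L, utr5[1] + 90L, by = 10L)],
                 alt = NA_character_))
  }
  sites <- rbindlist(sites)
  # give UTR SNVs an alt differing from the reference base
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  sites[site_type == "utr5", alt := flip[ref]]
  genome <- c("1" = paste(seq_chars, collapse = ""))
  fasta <- file.path(dir, "ref.fa")
  writeLines(c(">1", genome), fasta)
  gtf <- file.path(dir, "transcripts.gtf")
  writeLines(gtf_lines, gtf)
  genes$end <- genes$start + 899L
  list(genome = genome, transcripts = transcripts, genes = genes,
       sites = sites, fasta = fasta, gtf = gtf)
}

# anchored VCF representation of a possibly empty-allele variant
anchor_variant <- function(genome, chrom, pos, ref, alt) {
  if (nchar(ref) > 0 && nchar(alt) > 0) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  base <- substr(genome[[chrom]], pos - 1, pos - 1)
  list(pos = pos - 1L, ref = paste0(base, ref), alt = paste0(base, alt))
}

#' Simulate a pedigreed cohort with planted etiologies
#'
#' Generates founder haplotypes from the background spectrum, transmits
#' alleles through trio/quad pedigrees under Mendelian inheritance, plants
#' pathogenic configurations (one heterozygous founder per carrier family
#' under a dominant etiology; two carrier founders under a recessive one, so
#' children can be homozygous or compound heterozygous), assigns affection
#' status with probability `penetrance` to configuration carriers and
#' `phenocopy` to everyone else, and writes a merged VCF, a PED file, a
#' sample sheet (founders form the maximal unrelated set), a case-set table
#' (affected members of each etiology-labelled family) and a truth table.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [simulate_reference()].
#' @param dir output directory.
#' @return list(vcf, ped, sample_sheet, case_sets, truth, variants,
#'   genotype_matrix, samples).
#' @export
simulate_cohort <- function(cfg, ref, dir) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # pedigree scaffolding
  fam_ids <- sprintf("FAM%04d", seq_len(cfg$n_families))
  n_children <- 1L + stats::rbinom(cfg$n_families, 1, cfg$quad_fraction)
  ped <- rbindlist(lapply(seq_len(cfg$n_families), function(f) {
    fid <- fam_ids[f]
    kids <- sprintf("%s_C%d", fid, seq_len(n_children[f]))
    rbind(data.table(family_id = fid,
                     sample_id = c(paste0(fid, "_P1"), paste0(fid, "_P2")),
                     father = "0", mother = "0", founder = TRUE),
          data.table(family_id = fid, sample_id = kids,
                     father = paste0(fid, "_P1"), mother = paste0(fid, "_P2"),
                     founder = FALSE))
  }))
  ped$sex <- ifelse(grepl("_P1$", ped$sample_id), "M",
             ifelse(grepl("_P2$", ped$sample_id), "F",
                    sample(c("M", "F"), nrow(ped), replace = TRUE)))
  samples <- ped$sample_id
  n <- length(samples)

  # family disease labels: etiologies assigned round-robin, carriers first
  labels <- rep(NA_character_, cfg$n_families)
  carrier_fams <- list()
  next_free <- 1
  for (e in cfg$etiologies) {
    idx <- seq(next_free, length.out = e$n_carrier_families)
    if (max(idx) > cfg$n_families) stop("not enough families for etiologies")
    carrier_fams[[e$case_set]] <- fam_ids[idx]
    labels[idx] <- e$case_set
    next_free <- max(idx) + 1
  }
  # remaining families share the case sets too (non-carrier members)
  remaining <- which(is.na(labels))
  if (length(cfg$etiologies) > 0 && length(remaining) > 0) {
    labels[remaining] <- vapply(cfg$etiologies, `[[`, "", "case_set")[
      1 + (seq_along(remaining) - 1) %% length(cfg$etiologies)]
  }

  # background variant sites
  bg <- list()
  for (i in seq_len(cfg$n_genes)) {
    g <- ref$genes[i]
    exonic <- c(seq(g$start, g$start + 198L), seq(g$start + 399L, g$start + 497L),
                seq(g$start + 698L, g$start + 899L))
    taken <- ref$sites[gene_id == g$gene_id, pos]
    pool <- setdiff(exonic, taken)
    pos <- sort(sample(pool, cfg$n_background_per_gene))
    refb <- vapply(pos, function(p) substr(ref$genome[["1"]], p, p), "")
    flip <- c(A = "G", C = "T", G = "A", T = "C")
    lo <- 1 / (2 * n)
    u <- stats::runif(length(pos))
    freq <- lo * (cfg$max_background_maf / lo)^u  # log-uniform ~ 1/x density
    bg[[i]] <- data.table(gene_id = g$gene_id, chrom = "1", pos = pos,
                          ref = refb, alt = flip[refb], freq = freq,
                          planted = FALSE, site_type = "background")
  }
  bg <- rbindlist(bg)

  # planted etiological variants
  planted <- list()
  for (e in cfg$etiologies) {
    gid <- sprintf("G%d", e$gene)
    type <- switch(e$variant_class, high = "stop_gained",
                   moderate = "missense", utr5 = "utr5")
    cand <- ref$sites[gene_id == gid & site_type == type]
    stopifnot(nrow(cand) >= e$n_variants)
    pv <- cand[seq_len(e$n_variants)]
    # recessive alleles also segregate in the background population as
    # unaffected heterozygous carriers, which is what makes the recessive
    # mode of inheritance identifiable; dominant planted variants are private
    bg_freq <- if (e$moi == "recessive") 5e-4 else 0
    planted[[e$case_set]] <- data.table(
      gene_id = gid, chrom = pv$chrom, pos = pv$pos, ref = pv$ref,
      alt = pv$alt, freq = bg_freq, planted = TRUE, site_type = type,
      case_set = e$case_set)
  }
  planted_dt <- if (length(planted) > 0) rbindlist(planted) else NULL
  variants <- rbind(bg[, list(gene_id, chrom, pos, ref, alt, freq, planted,
                              site_type)],
                    if (!is.null(planted_dt))
                      planted_dt[, list(gene_id, chrom, pos, ref, alt, freq,
                                        planted, site_type)])
  variants <- unique(variants, by = c("chrom", "pos", "ref", "alt"))
  setorder(variants, pos)
  m <- nrow(variants)

  # haplotypes: 2 per sample; founders drawn from the spectrum, children
  # inherit one haplotype from each parent
  H1 <- matrix(0L, n, m, dimnames = list(samples, NULL))
  H2 <- matrix(0L, n, m, dimnames = list(samples, NULL))
  founders <- ped$sample_id[ped$founder]
  for (v in seq_len(m)) {
    q <- variants$freq[v]
    if (q > 0) {
      H1[founders, v] <- stats::rbinom(length(founders), 1, q)
      H2[founders, v] <- stats::rbinom(length(founders), 1, q)
    }
  }
  # plant carriers in founders
  if (!is.null(planted_dt)) {
    for (e in cfg$etiologies) {
      pv <- planted[[e$case_set]]
      vidx <- match(paste(pv$pos, pv$ref, pv$alt),
                    paste(variants$pos, variants$ref, variants$alt))
      fams <- carrier_fams[[e$case_set]]
      for (k in seq_along(fams)) {
        j <- vidx[1 + (k - 1) %% length(vidx)]
        p1 <- paste0(fams[k], "_P1")
        if (e$moi == "dominant") {
          H1[p1, j] <- 1L
        } else {
          j2 <- vidx[1 + k %% length(vidx)]
          p2 <- paste0(fams[k], "_P2")
          H1[p1, j] <- 1L
          H1[p2, j2] <- 1L
        }
      }
    }
  }
  # transmission
  for (r in which(!ped$founder)) {
    kid <- ped$sample_id[r]
    fa <- ped$father[r]; mo <- ped$mother[r]
    pick_f <- stats::rbinom(m, 1, 0.5)
    pick_m <- stats::rbinom(m, 1, 0.5)
    H1[kid, ] <- ifelse(pick_f == 1, H1[fa, ], H2[fa, ])
    H2[kid, ] <- ifelse(pick_m == 1, H1[mo, ], H2[mo, ])
  }
  G <- H1 + H2

  # pathogenic configurations and affection
  etiology_vidx <- lapply(cfg$etiologies, function(e) {
    pv <- planted[[e$case_set]]
    match(paste(pv$pos, pv$ref, pv$alt),
          paste(variants$pos, variants$ref, variants$alt))
  })
  compute_config <- function(G) {
    config <- rep(FALSE, nrow(G))
    names(config) <- rownames(G)
    for (k in seq_along(cfg$etiologies)) {
      e <- cfg$etiologies[[k]]
      path_alleles <- rowSums(G[, etiology_vidx[[k]], drop = FALSE])
      config <- config | if (e$moi == "dominant") path_alleles >= 1
                         else path_alleles >= 2
    }
    config
  }
  truth_rows <- list()
  for (e in cfg$etiologies) {
    pv <- planted[[e$case_set]]
    truth_rows[[e$case_set]] <- data.table(
      case_set = e$case_set, gene_id = pv$gene_id[1], moi = e$moi,
      variant_class = e$variant_class,
      chrom = pv$chrom, pos = pv$pos, ref = pv$ref, alt = pv$alt)
  }
  fam_of <- stats::setNames(ped$family_id, ped$sample_id)
  lab_of <- stats::setNames(labels, fam_ids)
  draw_affected <- function(config, idx = seq_len(n)) {
    vapply(idx, function(i) {
      lab <- lab_of[[fam_of[[samples[i]]]]]
      e <- Filter(function(x) identical(x$case_set, lab), cfg$etiologies)
      f1 <- if (length(e) > 0) e[[1]]$penetrance else 0.95
      f0 <- if (length(e) > 0) e[[1]]$phenocopy else 0.005
      stats::rbinom(1, 1, if (config[i]) f1 else f0) == 1
    }, logical(1))
  }
  config <- compute_config(G)
  affected <- draw_affected(config)

  # Ascertainment: a carrier family enters the cohort because it has an
  # affected member, as in proband-based rare-disease enrollment. Redraw the
  # children's transmissions and the family's affection status until at
  # least one member is affected.
  for (e in cfg$etiologies) {
    for (fid in carrier_fams[[e$case_set]]) {
      members <- which(ped$family_id == fid)
      kids <- members[!ped$founder[members]]
      tries <- 0
      while (!any(affected[members]) && tries < 200) {
        for (r in kids) {
          kid <- ped$sample_id[r]
          fa <- ped$father[r]; mo <- ped$mother[r]
          pf <- stats::rbinom(m, 1, 0.5); pm <- stats::rbinom(m, 1, 0.5)
          H1[kid, ] <- ifelse(pf == 1, H1[fa, ], H2[fa, ])
          H2[kid, ] <- ifelse(pm == 1, H1[mo, ], H2[mo, ])
          G[kid, ] <- H1[kid, ] + H2[kid, ]
        }
        config[members] <- compute_config(G[members, , drop = FALSE])
        affected[members] <- draw_affected(config, members)
        tries <- tries + 1
      }
    }
  }

  # files
  vcf_path <- file.path(dir, "cohort.vcf")
  anch <- lapply(seq_len(m), function(v) {
    anchor_variant(ref$genome, "1", variants$pos[v], variants$ref[v],
                   variants$alt[v])
  })
  gt_str <- matrix("0/0", n, m)
  gt_str[G == 1] <- "0/1"
  gt_str[G == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(m), function(v) {
    paste(c("1", anch[[v]]$pos, ".", anch[[v]]$ref, anch[[v]]$alt, "100",
            "PASS", ".", "GT:GQ",
            paste0(gt_str[, v], ":99")), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  ped_path <- file.path(dir, "cohort.ped")
  ped_out <- data.table(family_id = ped$family_id, sample_id = ped$sample_id,
                        father = ped$father, mother = ped$mother,
                        sex = ifelse(ped$sex == "M", 1L, 2L),
                        phenotype = ifelse(affected, 2L, 1L))
  fwrite(ped_out, ped_path, sep = "\t", col.names = FALSE)

  sheet_path <- file.path(dir, "samples.tsv")
  sheet <- data.table(sample_id = samples, sex = ped$sex,
                      family_id = ped$family_id,
                      unrelated_flag = as.integer(ped$founder),
                      ancestry = "SIM", affected_flag = as.integer(affected))
  fwrite(sheet, sheet_path, sep = "\t")

  cs_path <- file.path(dir, "case_sets.tsv")
  cs <- data.table(sample_id = samples,
                   name = unname(lab_of[fam_of[samples]]))[!is.na(name)]
  dg <- stats::setNames(vapply(cfg$etiologies, `[[`, "", "disease_group"),
                        vapply(cfg$etiologies, `[[`, "", "case_set"))
  cs[, `:=`(level = "specific_disease", disease_group = unname(dg[name]))]
  cs <- cs[sample_id %in% samples[affected]]
  fwrite(cs[, list(name, level, disease_group, sample_id)], cs_path, sep = "\t")

  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (length(truth_rows) > 0) rbindlist(truth_rows) else
    data.table(case_set = character(0), gene_id = character(0),
               moi = character(0), variant_class = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0))
  fwrite(truth, truth_path, sep = "\t")

  list(vcf = vcf_path, ped = ped_path, sample_sheet = sheet_path,
       case_sets = cs_path, truth = truth_path, variants = variants,
       genotype_matrix = G, samples = samples, affected = affected,
       config = config, carrier_families = carrier_fams,
       family_labels = stats::setNames(labels, fam_ids))
}

#' Simulate annotation resources
#'
#' Writes a population allele-count reference (planted pathogenic variants
#' absent; background variants at counts consistent with their simulated
#' frequency in a 50,000-genome reference population), a CADD-like score
#' table (planted high-impact SNVs ~ 35, planted missense ~ 25, background
#' SNVs uniform between 0 and 20), a panel table matching each etiology's case set
#' except those listed in `novel`, a small three-level ontology in OBO
#' format, and per-family term annotations with a planted phenotypically
#' similar cluster among the carrier families of the configured case set.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [simulate_reference()].
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory.
#' @param novel case sets whose gene is left out of the panel table.
#' @return list of file paths (ref_counts, cadd, panels, obo, family_terms).
#' @export
simulate_annotations <- function(cfg, ref, cohort, dir, novel = character(0)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 2)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  norm <- normalize_variant(v$chrom, v$pos, v$ref, v$alt)
  ids <- encode_rsvr(chrom_name(norm$chrom), norm$pos, norm$ref, norm$alt)$id

  an_ref <- 100000L
  bgi <- which(!v$planted)
  rc <- data.table(rsvr_id = ids[bgi], population = "POP1",
                   ac = stats::rbinom(length(bgi), an_ref, v$freq[bgi]),
                   an = an_ref, ac_male = NA_integer_, an_male = NA_integer_)
  rc <- rc[ac > 0]
  rc_path <- file.path(dir, "ref_counts.tsv")
  fwrite(rc, rc_path, sep = "\t")

  is_snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1
  cadd <- data.table(rsvr_id = ids[is_snv])
  cadd$cadd <- round(stats::runif(nrow(cadd), 0, 20), 2)
  cadd$cadd[v$planted[is_snv] & v$site_type[is_snv] == "stop_gained"] <- 35
  cadd$cadd[v$planted[is_snv] & v$site_type[is_snv] == "missense"] <- 25
  cadd$cadd[v$planted[is_snv] & v$site_type[is_snv] == "utr5"] <- 15
  cadd_path <- file.path(dir, "cadd.tsv")
  fwrite(cadd, cadd_path, sep = "\t")

  panels_path <- file.path(dir, "panels.tsv")
  pan <- rbindlist(lapply(cfg$etiologies, function(e) {
    if (e$case_set %in% novel) return(NULL)
    data.table(panel = e$case_set, type = "Rare Disease",
               sub_group = e$disease_group, gene = sprintf("G%d", e$gene),
               evidence = "green", gene_count = 25L)
  }))
  if (is.null(pan) || nrow(pan) == 0) {
    pan <- data.table(panel = character(0), type = character(0),
                      sub_group = character(0), gene = character(0),
                      evidence = character(0), gene_count = integer(0))
  }
  fwrite(pan, panels_path, sep = "\t")

  # three-level ontology: root -> 4 systems -> 4 leaves each
  systems <- sprintf("SIM:%04d", 1:4)
  leaves <- sprintf("SIM:%04d", 11:26)
  obo_path <- file.path(dir, "ontology.obo")
  stanza <- function(id, name, isa = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      if (!is.null(isa)) paste0("is_a: ", isa), "")
  }
  obo <- c("format-version: 1.2", "",
           stanza("SIM:0000", "phenotypic abnormality (root)"))
  for (i in seq_along(systems)) {
    obo <- c(obo, stanza(systems[i], paste("system", i), "SIM:0000"))
  }
  for (i in seq_along(leaves)) {
    obo <- c(obo, stanza(leaves[i], paste("feature", i),
                         systems[1 + (i - 1) %/% 4]))
  }
  writeLines(obo, obo_path)

  fams <- names(cohort$family_labels)
  cluster_fams <- character(0)
  if (!is.null(cfg$phenotype_cluster)) {
    cluster_fams <- cohort$carrier_families[[cfg$phenotype_cluster$case_set]]
  }
  cluster_terms <- leaves[1:cfg$phenotype_cluster$n_terms]
  rows <- lapply(fams, function(f) {
    ts <- sample(leaves, 3)
    if (f %in% cluster_fams) {
      keep <- stats::runif(length(cluster_terms)) < 0.9
      ts <- unique(c(cluster_terms[keep], ts[1]))
    }
    data.table(family_id = f, term_id = ts)
  })
  ft_path <- file.path(dir, "family_terms.tsv")
  fwrite(rbindlist(rows), ft_path, sep = "\t")

  list(ref_counts = rc_path, cadd = cadd_path, panels = panels_path,
       obo = obo_path, family_terms = ft_path)
}
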