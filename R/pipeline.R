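# Variant annotation table for one gene: one row per variant with the union
# of consequence bits over the gene's canonical transcripts, the most severe
# LOFTEE call, and the VARIANT-level scores.
gene_variant_table <- function(con, gene_id) {
  x <- setDT(DBI::dbGetQuery(con,
    "SELECT c.rsvr_id, c.csq, c.loftee, v.pmaf, v.cadd, v.gq_median
       FROM CONSEQUENCE c
       JOIN TX t ON t.transcript_id = c.transcript_id
       JOIN VARIANT v ON v.rsvr_id = c.rsvr_id
      WHERE t.gene_id = ? AND t.canonical = 1", params = list(gene_id)))
  if (nrow(x) == 0) {
    return(data.table(rsvr_id = character(0), csq = numeric(0),
                      loftee = character(0), pmaf = integer(0),
                      cadd = numeric(0), gq_median = numeric(0)))
  }
  x[, list(csq = {
      bits <- Reduce(bitwOr, as.integer(csq)); as.numeric(bits)
    },
    loftee = if (any(loftee == "low_confidence", na.rm = TRUE))
      "low_confidence" else if (all(is.na(loftee))) NA_character_
      else stats::na.omit(loftee)[1],
    pmaf = pmaf[1], cadd = cadd[1], gq_median = gq_median[1]),
    by = rsvr_id]
}

#' Gene-disease association scan over a reservoir
#'
#' For each gene, selects the unrelated case/control cohort for the case set,
#' extracts qualifying variants and genotypes and runs the seven-model
#' comparison.
#'
#' @param con reservoir connection.
#' @param case_set case-set name.
#' @param genes gene ids (default: all genes in the database).
#' @param specs,risk model and risk priors.
#' @param explained optional data.frame(sample_id, gene) of solved cases.
#' @param seed estimator seed.
#' @param max_enumeration,mc_draws see [model_evidence()].
#' @return data.table(gene, case_set, ppa, modal_moi, modal_class,
#'   n_cases, n_controls, estimator) with a "variant_posteriors" attribute
#'   (data.table gene, rsvr_id, posterior).
#' @export
run_association <- function(con, case_set, genes = NULL,
                            specs = default_model_specs(),
                            risk = risk_prior(), explained = NULL, seed = 1,
                            max_enumeration = 12, mc_draws = 5000) {
  if (is.null(genes)) {
    genes <- DBI::dbGetQuery(con, "SELECT gene_id FROM GENE ORDER BY gene_id")$gene_id
  }
  samples <- setDT(DBI::dbGetQuery(con, "SELECT * FROM SAMPLE"))
  samples[, unrelated_flag := unrelated_flag == 1]
  members <- DBI::dbGetQuery(con,
    "SELECT sample_id FROM CASE_SET WHERE name = ?",
    params = list(case_set))$sample_id
  if (length(members) == 0) stop("unknown or empty case set: ", case_set)
  out <- list()
  vp_out <- list()
  for (g in genes) {
    cohort <- select_analysis_cohort(samples, members, explained, g)
    variants <- gene_variant_table(con, g)
    genotypes <- query_genotypes(con, variants$rsvr_id)
    res <- gene_association(variants, genotypes, cohort$cases,
                            cohort$controls, specs = specs, risk = risk,
                            seed = seed, max_enumeration = max_enumeration,
                            mc_draws = mc_draws)
    out[[g]] <- data.table(
      gene = g, case_set = case_set, ppa = res$ppa,
      modal_moi = res$modal_model$moi,
      modal_class = res$modal_model$variant_class,
      n_cases = length(cohort$cases), n_controls = length(cohort$controls),
      estimator = paste(unique(res$estimator[-1]), collapse = "+"))
    if (length(res$variant_posterior) > 0) {
      vp_out[[g]] <- data.table(gene = g,
                                rsvr_id = names(res$variant_posterior),
                                posterior = unname(res$variant_posterior))
    }
  }
  res <- rbindlist(out)
  attr(res, "variant_posteriors") <-
    if (length(vp_out) > 0) rbindlist(vp_out)
    else data.table(gene = character(0), rsvr_id = character(0),
                    posterior = numeric(0))
  res
}

# Affected relatives of the analysis cases: affected members of case
# pedigrees who are not the selected cases themselves.
affected_relatives <- function(samples, cases) {
  s <- as.data.table(samples)
  fams <- s[sample_id %in% cases, unique(family_id)]
  s[family_id %in% fams & !(sample_id %in% cases) & affected_flag == 1,
    sample_id]
}

#' Post-inference re-run of one association
#'
#' Recomputes the PPA for a significant gene/case-set pair under one of the
#' three filter modes and applies [refilter_decision()]:
#' `with_relatives` re-runs on the full cohort including relatives of cases
#' and controls; `affected_relative_variants` removes qualifying variants
#' that are absent from all affected relatives of the cases carrying them
#' (when such relatives exist); `relatedness_pruned` flags case pairs whose
#' rare-variant sharing is in the top percentile of their ancestry and keeps
#' at most one case per variant-sharing cluster.
#'
#' @param con reservoir connection.
#' @param gene,case_set the association.
#' @param mode re-run mode.
#' @param specs,risk,explained,seed,max_enumeration,mc_draws as in
#'   [run_association()].
#' @return list(keep, rerun_ppa, threshold, mode).
#' @export
refilter_association <- function(con, gene, case_set,
                                 mode = c("with_relatives",
                                          "affected_relative_variants",
                                          "relatedness_pruned"),
                                 specs = default_model_specs(),
                                 risk = risk_prior(), explained = NULL,
                                 seed = 1, max_enumeration = 12,
                                 mc_draws = 5000) {
  mode <- match.arg(mode)
  samples <- setDT(DBI::dbGetQuery(con, "SELECT * FROM SAMPLE"))
  samples[, unrelated_flag := unrelated_flag == 1]
  members <- DBI::dbGetQuery(con,
    "SELECT sample_id FROM CASE_SET WHERE name = ?",
    params = list(case_set))$sample_id
  cohort <- select_analysis_cohort(samples, members, explained, gene)
  variants <- gene_variant_table(con, gene)
  genotypes <- query_genotypes(con, variants$rsvr_id)
  cases <- cohort$cases
  controls <- cohort$controls

  if (mode == "with_relatives") {
    case_fams <- samples[sample_id %in% members, unique(family_id)]
    cases <- samples[family_id %in% case_fams & sample_id %in% members,
                     sort(sample_id)]
    controls <- samples[!(family_id %in% case_fams), sort(sample_id)]
  } else if (mode == "affected_relative_variants") {
    rel <- affected_relatives(samples, cases)
    if (length(rel) > 0) {
      carriers <- split(genotypes$sample_id, genotypes$rsvr_id)
      fam_of <- stats::setNames(samples$family_id, samples$sample_id)
      drop <- vapply(variants$rsvr_id, function(vid) {
        carrying_cases <- intersect(carriers[[vid]], cases)
        if (length(carrying_cases) == 0) return(FALSE)
        rel_here <- rel[fam_of[rel] %in% fam_of[carrying_cases]]
        length(rel_here) > 0 && !any(rel_here %in% carriers[[vid]])
      }, logical(1))
      variants <- variants[!drop]
      genotypes <- genotypes[rsvr_id %in% variants$rsvr_id]
    }
  } else {
    sharing <- pairwise_sharing(
      setDT(DBI::dbGetQuery(con, "SELECT sample_id, rsvr_id FROM GENOTYPE")),
      samples[, list(sample_id, ancestry)])
    cases <- prune_related_cases(cases, sharing,
                                 genotypes[sample_id %in% cases])
  }
  res <- gene_association(variants, genotypes, cases, controls,
                          specs = specs, risk = risk, seed = seed,
                          max_enumeration = max_enumeration,
                          mc_draws = mc_draws)
  refilter_decision(res$ppa, mode)
}

#' Apply all three re-run filters and the Disease-Group deduplication
#'
#' Takes a [run_association()]-style results table (optionally spanning
#' several case sets), keeps rows with PPA > `ppa_threshold`, drops rows
#' failing any re-run filter, and deduplicates per gene and Disease Group.
#'
#' @param con reservoir connection.
#' @param results data.table with columns gene, case_set, ppa and (for the
#'   deduplication) disease_group.
#' @param ppa_threshold significance threshold (default 0.95).
#' @param ... passed to [refilter_association()].
#' @return filtered data.table with re-run PPAs appended.
#' @export
postprocess_associations <- function(con, results, ppa_threshold = 0.95, ...) {
  r <- as.data.table(results)[ppa > ppa_threshold]
  if (nrow(r) == 0) return(r)
  keeps <- logical(nrow(r))
  details <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    ks <- lapply(c("with_relatives", "affected_relative_variants",
                   "relatedness_pruned"), function(mode) {
      refilter_association(con, r$gene[i], r$case_set[i], mode = mode, ...)
    })
    keeps[i] <- all(vapply(ks, `[[`, logical(1), "keep"))
    details[[i]] <- vapply(ks, `[[`, numeric(1), "rerun_ppa")
  }
  r <- cbind(r, rbindlist(lapply(details, function(d) {
    as.list(stats::setNames(d, c("ppa_with_relatives",
                                 "ppa_affected_rel_variants",
                                 "ppa_relatedness_pruned")))
  })))
  r <- r[keeps]
  if ("disease_group" %in% names(r)) r <- dedup_disease_group(r)
  r
}
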