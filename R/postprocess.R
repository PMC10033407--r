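REFILTER_THRESHOLDS <- c(with_relatives = 0.9,
                         affected_relative_variants = 0.25,
                         relatedness_pruned = 0.25)

#' Keep/drop decision for a post-inference re-run
#'
#' Significant associations (PPA > 0.95) are re-tested three ways and dropped
#' when the recomputed PPA falls below a mode-specific threshold: re-running
#' with all samples including relatives (drop below 0.9, conflicting evidence
#' within families), re-running after removing variants absent from affected
#' relatives of the cases (drop below 0.25), and re-running after pruning
#' potentially related cases (drop below 0.25).
#'
#' @param rerun_ppa PPA from the re-run.
#' @param mode one of "with_relatives", "affected_relative_variants",
#'   "relatedness_pruned".
#' @return list(keep, rerun_ppa, threshold, mode).
#' @export
refilter_decision <- function(rerun_ppa,
                              mode = c("with_relatives",
                                       "affected_relative_variants",
                                       "relatedness_pruned")) {
  mode <- match.arg(mode)
  thr <- REFILTER_THRESHOLDS[[mode]]
  list(keep = rerun_ppa >= thr, rerun_ppa = rerun_ppa, threshold = thr,
       mode = mode)
}

#' Deduplicate associations within disease groups
#'
#' Case sets within one Disease Group are correlated; for each gene only the
#' most strongly associated case set per Disease Group is reported. Exact PPA
#' ties break to the lexicographically first case-set name.
#'
#' @param results data.frame with columns gene, case_set, disease_group, ppa.
#' @return filtered data.table.
#' @export
dedup_disease_group <- function(results) {
  r <- as.data.table(results)
  if (nrow(r) == 0) return(r)
  r <- r[order(gene, disease_group, -ppa, case_set)]
  r[, .SD[1], by = list(gene, disease_group)]
}

EVIDENCE_ORDER <- c(red = 1, amber = 2, green = 3)

#' Match an association to a gene panel
#'
#' Staged matching: first panels that contain the gene and whose name equals
#' the case-set name (case-insensitively); failing that, panels that contain
#' the gene and belong to a Disease Sub Group with the same name as the case
#' set's Disease Sub Group. Among multiple matches the panel(s) with the
#' highest evidence level (green > amber > red) are kept, then the panel with
#' the smallest number of genes; any remaining tie breaks to the
#' lexicographically first panel name. No match marks a candidate novel
#' association.
#'
#' @param gene gene identifier.
#' @param case_set case-set name.
#' @param sub_group the case set's Disease Sub Group.
#' @param panels data.frame with columns panel, sub_group, gene, evidence,
#'   gene_count.
#' @return one-row data.table (panel, evidence, gene_count) or NULL.
#' @export
match_panel <- function(gene, case_set, sub_group, panels) {
  want_gene <- gene; want_name <- tolower(case_set); want_sg <- tolower(sub_group)
  p <- as.data.table(panels)
  p <- p[p$gene == want_gene]
  if (nrow(p) == 0) return(NULL)
  m <- p[tolower(p$panel) == want_name]
  if (nrow(m) == 0) m <- p[tolower(p$sub_group) == want_sg]
  if (nrow(m) == 0) return(NULL)
  m <- m[EVIDENCE_ORDER[evidence] == max(EVIDENCE_ORDER[evidence])]
  m <- m[gene_count == min(gene_count)]
  m <- m[order(panel)][1]
  m[, list(panel, evidence, gene_count)]
}

#' Cosegregation counting with the mosaicism rule
#'
#' Counts, among relatives who were not part of the association analysis, how
#' many track the variants with their affection status: affected carriers and
#' unaffected non-carriers. An affected relative called homozygous reference
#' but with two or more reads supporting the alternate allele is treated as a
#' mosaic carrier. The consistency flag is FALSE if any affected relative
#' lacks the variants and is not mosaic. Missing read counts are treated as
#' zero supporting reads.
#'
#' @param relatives data.frame with columns sample_id, affected (logical),
#'   carrier (logical) and optionally alt_reads (integer).
#' @return list(count, consistent).
#' @export
count_cosegregation <- function(relatives) {
  r <- as.data.table(relatives)
  if (nrow(r) == 0) return(list(count = 0L, consistent = TRUE))
  if (!"alt_reads" %in% names(r)) r$alt_reads <- 0L
  r$alt_reads[is.na(r$alt_reads)] <- 0L
  mosaic <- r$affected & !r$carrier & r$alt_reads >= 2
  effective_carrier <- r$carrier | mosaic
  tracks <- (r$affected & effective_carrier) |
    (!r$affected & !effective_carrier)
  consistent <- !any(r$affected & !effective_carrier)
  list(count = sum(tracks), consistent = consistent)
}

#' Plausibility score of a previously unidentified association
#'
#' Range 0-3, summing three independent evidence points: (1) selection -
#' recessive inheritance scores by default, a dominant high-impact
#' association scores with pLI > 0.9, a dominant moderate-impact association
#' with missense depletion Z > 2; (2) cosegregation in at least three
#' additional relatives with no affected relative lacking the variants
#' (mosaic carriers supported by two or more alternate reads count); (3)
#' supportive biological function or related disease associations (a
#' judgement supplied as input, never computed).
#'
#' @param moi "dominant" or "recessive".
#' @param variant_class "high", "moderate" or "utr5".
#' @param pli probability of loss-of-function intolerance.
#' @param z missense depletion score.
#' @param coseg_relatives number of additional cosegregating relatives.
#' @param coseg_consistent logical.
#' @param biology_support logical.
#' @return integer score 0-3.
#' @export
plausibility_score <- function(moi, variant_class, pli, z, coseg_relatives,
                               coseg_consistent, biology_support) {
  stopifnot(moi %in% c("dominant", "recessive"),
            variant_class %in% c("high", "moderate", "utr5"))
  selection <- (moi == "recessive") ||
    (moi == "dominant" && variant_class == "high" && !is.na(pli) && pli > 0.9) ||
    (moi == "dominant" && variant_class == "moderate" && !is.na(z) && z > 2)
  coseg <- coseg_relatives >= 3 && isTRUE(coseg_consistent)
  as.integer(selection) + as.integer(coseg) + as.integer(biology_support)
}

#' Pairwise rare-variant sharing and relatedness flags
#'
#' Counts, for each pair of samples within an ancestry, the number of rare
#' variants both carry, and flags pairs at or above the empirical 99th
#' percentile of their ancestry's distribution as potentially related.
#'
#' @param genotypes data.frame with columns sample_id, rsvr_id.
#' @param samples data.frame with columns sample_id, ancestry.
#' @param percentile flagging quantile (default 0.99).
#' @return data.table(sample1, sample2, shared, ancestry, flagged).
#' @export
pairwise_sharing <- function(genotypes, samples, percentile = 0.99) {
  g <- as.data.table(genotypes)
  s <- as.data.table(samples)
  out <- list()
  for (anc in unique(s$ancestry)) {
    ids <- sort(s$sample_id[s$ancestry == anc])
    if (length(ids) < 2) next
    gg <- g[sample_id %in% ids]
    pairs <- merge(gg, gg, by = "rsvr_id", allow.cartesian = TRUE)
    pairs <- pairs[sample_id.x < sample_id.y]
    cnt <- pairs[, list(shared = .N), by = list(sample1 = sample_id.x,
                                                sample2 = sample_id.y)]
    all_pairs <- CJ(sample1 = ids, sample2 = ids)[sample1 < sample2]
    cnt <- merge(all_pairs, cnt, by = c("sample1", "sample2"), all.x = TRUE)
    cnt[is.na(shared), shared := 0L]
    thr <- stats::quantile(cnt$shared, percentile, type = 1)
    cnt[, `:=`(ancestry = anc, flagged = shared >= thr & shared > 0)]
    out[[anc]] <- cnt
  }
  if (length(out) == 0) {
    return(data.table(sample1 = character(0), sample2 = character(0),
                      shared = integer(0), ancestry = character(0),
                      flagged = logical(0)))
  }
  rbindlist(out)
}

#' Prune potentially related cases
#'
#' Given relatedness flags and the variants each case carries, ensures no
#' more than one case from any set of potentially related cases sharing a
#' variant remains: within each connected component of the
#' flagged-and-sharing graph the lexicographically first case is kept.
#'
#' @param cases character vector of case sample ids.
#' @param sharing output of [pairwise_sharing()].
#' @param genotypes data.frame with columns sample_id, rsvr_id restricted to
#'   the qualifying variants of the association.
#' @return pruned character vector of case ids.
#' @export
prune_related_cases <- function(cases, sharing, genotypes) {
  cases <- sort(cases)
  g <- as.data.table(genotypes)[sample_id %in% cases]
  fl <- as.data.table(sharing)[flagged == TRUE &
                               sample1 %in% cases & sample2 %in% cases]
  if (nrow(fl) == 0) return(cases)
  shares_variant <- function(a, b) {
    length(intersect(g[sample_id == a, rsvr_id],
                     g[sample_id == b, rsvr_id])) > 0
  }
  edges <- fl[mapply(shares_variant, sample1, sample2)]
  if (nrow(edges) == 0) return(cases)
  # union-find over flagged variant-sharing pairs
  parent <- stats::setNames(cases, cases)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges$sample1[i]); b <- find(edges$sample2[i])
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  roots <- vapply(cases, find, character(1))
  keep <- cases[!duplicated(roots)]
  sort(keep)
}

#' Shortlist evidence table for candidate novel associations
#'
#' The packaged evidence table for the nineteen candidate associations that
#' lacked prior panel support: inferred MOI and variant class, gene
#' constraint metrics (pLI, missense Z), cosegregation counts and the
#' biology-support judgement, together with the published score for
#' comparison. `score_evidence_table` recomputes the plausibility score for
#' every row with [plausibility_score()].
#'
#' @return data.table (with a `score` column added by
#'   `score_evidence_table`).
#' @export
novel_association_evidence <- function() {
  fread(system.file("extdata", "novel_association_evidence.tsv",
                    package = "rsvr"))
}

#' @rdname novel_association_evidence
#' @param x an evidence table shaped like [novel_association_evidence()].
#' @export
score_evidence_table <- function(x = novel_association_evidence()) {
  x <- as.data.table(x)
  x$score <- mapply(plausibility_score, x$moi, x$variant_class, x$pli, x$z,
                    x$coseg_relatives, x$coseg_consistent, x$biology_support)
  x
}
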