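#' One-sided binomial rarity test
#'
#' Upper-tail p-value P(X >= ac | n = an, p = t) for the observed allele count
#' against the null hypothesis that the population allele frequency equals the
#' threshold `t`. An allele count of zero (or an allele number of zero, i.e.
#' no information) gives p = 1.
#'
#' @param ac observed allele count(s).
#' @param an allele number(s).
#' @param t null allele frequency.
#' @return p-value vector.
#' @examples
#' rarity_test(1, 100, 0.001)  # 1 - 0.999^100
#' @export
rarity_test <- function(ac, an, t) {
  stopifnot(all(ac >= 0), all(ac <= an | an == 0), t > 0, t < 1)
  p <- stats::pbinom(ac - 1, an, t, lower.tail = FALSE)
  p[ac == 0 | an == 0] <- 1
  p
}

#' Probabilistic minor allele frequency (PMAF) score
#'
#' Ordinal 0-3 rarity score for one variant from population allele counts.
#' Each population is tested with [rarity_test()] at significance 0.05:
#' if any population rejects the null MAF = 0.001 with an allele count of at
#' least two the score is 0; otherwise if any population rejects MAF = 0.0001
#' the score is 1; otherwise 2. A variant absent from the reference (no rows,
#' or total allele count zero) scores 3. On the non-pseudoautosomal region of
#' chromosome X only male allele counts are used.
#'
#' @param counts data.frame with columns population, ac, an and optionally
#'   ac_male, an_male; zero rows mean the variant is absent.
#' @param chrx_nonpar use male-only counts (default FALSE).
#' @param alpha significance threshold (default 0.05, rejection is strict).
#' @return integer score in 0:3.
#' @export
pmaf_score <- function(counts, chrx_nonpar = FALSE, alpha = 0.05) {
  if (is.null(counts) || nrow(counts) == 0) return(3L)
  counts <- as.data.frame(counts)
  if (chrx_nonpar) {
    if (!all(c("ac_male", "an_male") %in% names(counts)))
      stop("male allele counts required for non-PAR chromosome X")
    ac <- counts$ac_male; an <- counts$an_male
  } else {
    ac <- counts$ac; an <- counts$an
  }
  ac[is.na(ac)] <- 0L; an[is.na(an)] <- 0L
  if (sum(ac) == 0) return(3L)
  p1 <- rarity_test(ac, an, 0.001)
  p2 <- rarity_test(ac, an, 1e-4)
  if (any(p1 < alpha & ac >= 2)) return(0L)
  if (any(p2 < alpha)) return(1L)
  2L
}

#' Vectorized PMAF scoring of a variant table
#'
#' @param variant_ids character vector of RSVR ids to score.
#' @param ref_counts data.frame with columns rsvr_id, population, ac, an and
#'   optionally ac_male, an_male (the population reference).
#' @param chrx_nonpar logical vector (recycled) marking ids on non-PAR chrX.
#' @return integer vector of scores aligned with `variant_ids`.
#' @export
pmaf_scores <- function(variant_ids, ref_counts, chrx_nonpar = FALSE) {
  ref_counts <- as.data.table(ref_counts)
  chrx_nonpar <- rep_len(chrx_nonpar, length(variant_ids))
  idx <- split(seq_len(nrow(ref_counts)), ref_counts$rsvr_id)
  vapply(seq_along(variant_ids), function(i) {
    rows <- idx[[variant_ids[i]]]
    pmaf_score(if (is.null(rows)) ref_counts[0] else ref_counts[rows],
               chrx_nonpar = chrx_nonpar[i])
  }, integer(1))
}

#' Read a population allele-count reference from TSV
#'
#' Expected columns: rsvr_id (or chrom, pos, ref, alt, which are encoded),
#' population, ac, an and optionally ac_male, an_male.
#'
#' @param path TSV file.
#' @return data.table keyed by rsvr_id.
#' @export
read_population_counts <- function(path) {
  x <- fread(path, colClasses = list(character = intersect(
    "rsvr_id", names(fread(path, nrows = 0)))))
  if (!"rsvr_id" %in% names(x)) {
    x$rsvr_id <- encode_rsvr(x$chrom, x$pos, x$ref, x$alt)$id
  }
  setkey(x, rsvr_id)
  x[]
}

#' Per-position variant quality pass rates from a gVCF subsample
#'
#' For each queried position, the fraction of sampled gVCFs whose covering
#' record passes the quality filter. A position not covered by any record of
#' a sample counts as failing for that sample (conservative default).
#'
#' @param records data.frame with columns sample, start, end, pass (logical);
#'   one row per gVCF record of the subsample.
#' @param positions integer vector of positions to query.
#' @return data.table with columns pos, pass_rate.
#' @export
depth_pass_rate <- function(records, positions) {
  records <- as.data.table(records)
  if (nrow(records) == 0 || length(unique(records$sample)) == 0)
    stop("empty gVCF subsample")
  n <- length(unique(records$sample))
  rate <- vapply(positions, function(p) {
    cov <- records[records$start <= p & records$end >= p]
    sum(tapply(cov$pass, cov$sample, any)) / n
  }, numeric(1))
  data.table(pos = positions, pass_rate = rate)
}

#' Flag variants almost surely common from a subsample
#'
#' Returns the ids whose subsample allele counts reject, at significance
#' 1e-6, the one-sided binomial null that the MAF equals `maf` (default 0.01):
#' such variants are statistically almost certain to be common and can be
#' dropped before the full cohort is read.
#'
#' @param counts data.frame with columns rsvr_id, ac, an (subsample counts).
#' @param maf null minor allele frequency (default 0.01).
#' @param alpha significance level (default 1e-6).
#' @return character vector of flagged ids.
#' @export
tabulate_common <- function(counts, maf = 0.01, alpha = 1e-6) {
  counts <- as.data.table(counts)
  if (nrow(counts) == 0) return(character(0))
  p <- rarity_test(counts$ac, counts$an, maf)
  counts$rsvr_id[p < alpha]
}

#' Read a pathogenicity-score table (CADD-like, Phred scale)
#'
#' Expected columns: rsvr_id (or chrom, pos, ref, alt) and cadd. Missing
#' scores stay missing: they are treated as unavailable downstream, and the
#' SNV score filter only applies where a score exists.
#'
#' @param path TSV file.
#' @return data.table with columns rsvr_id, cadd, keyed by rsvr_id.
#' @export
read_cadd_scores <- function(path) {
  x <- fread(path, colClasses = list(character = intersect(
    "rsvr_id", names(fread(path, nrows = 0)))))
  if (!"rsvr_id" %in% names(x)) {
    x$rsvr_id <- encode_rsvr(x$chrom, x$pos, x$ref, x$alt)$id
  }
  setkey(x, rsvr_id)
  x[, list(rsvr_id, cadd)]
}

#' Within-cohort allele-frequency filter
#'
#' Computes the internal minor allele frequency of each variant from the
#' genotype table and returns the ids at or above the threshold (only
#' variants with internal MAF strictly below the threshold are retained).
#'
#' @param genotypes data.frame with columns rsvr_id, allele_count.
#' @param n_samples number of samples in the cohort.
#' @param threshold internal MAF threshold (default 0.002).
#' @param ploidy_total total number of haplotypes; defaults to 2 * n_samples.
#' @return character vector of ids to delete.
#' @export
internal_af_filter <- function(genotypes, n_samples, threshold = 0.002,
                               ploidy_total = 2 * n_samples) {
  stopifnot(threshold > 0, threshold < 1)
  g <- as.data.table(genotypes)
  if (nrow(g) == 0) return(character(0))
  af <- g[, list(ac = sum(allele_count)), by = rsvr_id]
  af$rsvr_id[af$ac / ploidy_total >= threshold]
}
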