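#' Default model specifications
#'
#' The seven models compared per gene and case set: a baseline model of no
#' association (prior probability 0.99) and six association models crossing
#' mode of inheritance (dominant, recessive) with the class of etiological
#' variant (high impact, moderate impact, 5' UTR). Dominant models admit
#' variants with PMAF >= 2 (target MAF < 0.01%), recessive models PMAF >= 1
#' (target MAF < 0.1%), reflecting the stronger negative selection against
#' dominant variants. High/moderate models carry prior probability 0.002475
#' each and the two 5' UTR models 0.00005, so the overall prior probability
#' of association is 0.01 with equal mass on dominant and recessive
#' inheritance. The prior on per-variant pathogenicity is Beta(3,1) (mean
#' 75%) for high-impact models, because loss-of-function variants tend to be
#' functionally equivalent, and Beta(2,8) (mean 20%) otherwise.
#'
#' @return data.table with one row per model: model, kind, moi, variant_class,
#'   pmaf_min, prior, path_a, path_b.
#' @export
default_model_specs <- function() {
  data.table(
    model = 1:7,
    kind = c("baseline", rep("association", 6)),
    moi = c(NA, "dominant", "dominant", "dominant",
            "recessive", "recessive", "recessive"),
    variant_class = c(NA, "high", "moderate", "utr5",
                      "high", "moderate", "utr5"),
    pmaf_min = c(NA, 2L, 2L, 2L, 1L, 1L, 1L),
    prior = c(0.99, 0.002475, 0.002475, 0.00005,
              0.002475, 0.002475, 0.00005),
    path_a = c(NA, 3, 2, 2, 3, 2, 2),
    path_b = c(NA, 1, 8, 8, 1, 8, 8))
}

#' Prior on case risk with and without a pathogenic configuration
#'
#' Conjugate Beta priors on the probability of case status for individuals
#' without (`tau0`) and with (`tau1`) a pathogenic configuration of alleles.
#' The defaults Beta(1,9) and Beta(4,2) encode a low baseline case rate and a
#' high penetrance expectation; they are documented substitutes for the
#' published sampler's hyperparameters and are configurable.
#'
#' @param tau0,tau1 numeric length-2 vectors (Beta shape parameters).
#' @return list with elements tau0, tau1.
#' @export
risk_prior <- function(tau0 = c(1, 9), tau1 = c(4, 2)) {
  stopifnot(all(c(tau0, tau1) > 0))
  list(tau0 = tau0, tau1 = tau1)
}

# log of the beta-binomial marginal likelihood of k successes in a stratum of
# size n under tau ~ Beta(a, b)
lbb <- function(k, n, a, b) lbeta(a + k, b + n - k) - lbeta(a, b)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Baseline (no-association) model evidence
#'
#' Marginal likelihood of the case indicators when no individual has a
#' pathogenic configuration: a single beta-binomial stratum under the tau0
#' prior.
#'
#' @param y 0/1 case indicator vector.
#' @param risk a [risk_prior()].
#' @return log marginal likelihood.
#' @export
baseline_evidence <- function(y, risk = risk_prior()) {
  lbb(sum(y), length(y), risk$tau0[1], risk$tau0[2])
}

# log ML(y | x) for a matrix of configuration indicators X (n x m)
log_ml_strata <- function(X, y, risk) {
  n <- length(y)
  n1 <- colSums(X)
  k1 <- as.vector(crossprod(X, y))
  k <- sum(y)
  lbb(k1, n1, risk$tau1[1], risk$tau1[2]) +
    lbb(k - k1, n - n1, risk$tau0[1], risk$tau0[2])
}

config_matrix <- function(G, Z, moi, ploidy) {
  counts <- G %*% Z
  if (moi == "dominant") {
    X <- counts >= 1
  } else {
    X <- counts >= ploidy
  }
  storage.mode(X) <- "double"
  X
}

all_z <- function(J) {
  matrix(vapply(seq_len(2^J) - 1, function(v) (v %/% 2^(0:(J - 1))) %% 2,
                numeric(J)), nrow = J)
}

#' Model evidence with latent per-variant pathogenicity
#'
#' Log marginal likelihood of the case indicators under one association
#' model. Each of the J qualifying variants is latently pathogenic or benign;
#' pathogenicity indicators z follow an exchangeable beta-Bernoulli prior
#' with parameters `path_prior`. An individual has a pathogenic configuration
#' when the number of pathogenic alleles they carry reaches 1 (dominant) or
#' their ploidy (recessive), which switches their case-probability prior from
#' tau0 to tau1. The evidence is the sum over z of the prior mass times the
#' closed-form beta-binomial likelihood of the two strata; it is computed by
#' exact enumeration when J <= `max_enumeration` and otherwise by Monte Carlo
#' sampling of z from its prior (seeded, with a standard error estimate).
#' With J = 0 the evidence equals the baseline evidence.
#'
#' @param G individuals x variants allele-count matrix (0/1/2).
#' @param y 0/1 case indicator.
#' @param moi "dominant" or "recessive".
#' @param path_prior Beta parameters c(a, b) of the pathogenicity prior.
#' @param risk a [risk_prior()].
#' @param ploidy per-individual ploidy (default 2; 1 for male non-PAR chrX).
#' @param max_enumeration exact-sum cutoff on J (default 12).
#' @param mc_draws Monte Carlo draws beyond the cutoff (default 5000).
#' @param seed seed for the Monte Carlo estimator (required when used).
#' @return list(log_evidence, estimator, draws, std_error).
#' @export
model_evidence <- function(G, y, moi = c("dominant", "recessive"),
                           path_prior = c(2, 8), risk = risk_prior(),
                           ploidy = rep(2, length(y)), max_enumeration = 12,
                           mc_draws = 5000, seed = NULL) {
  moi <- match.arg(moi)
  y <- as.numeric(y)
  G <- as.matrix(G)
  if (nrow(G) != length(y)) stop("G and y are misaligned")
  J <- ncol(G)
  a <- path_prior[1]; b <- path_prior[2]
  if (J == 0) {
    return(list(log_evidence = baseline_evidence(y, risk),
                estimator = "exact_enumeration", draws = 0L,
                std_error = 0))
  }
  if (J <= max_enumeration) {
    Z <- all_z(J)
    X <- config_matrix(G, Z, moi, ploidy)
    logml <- log_ml_strata(X, y, risk)
    s <- colSums(Z)
    logpz <- lbeta(a + s, b + J - s) - lbeta(a, b)
    le <- logsumexp(logpz + logml)
    if (!is.finite(le)) stop("non-finite evidence (J = ", J, ", moi = ", moi, ")")
    return(list(log_evidence = le, estimator = "exact_enumeration",
                draws = 0L, std_error = 0))
  }
  if (is.null(seed)) stop("a seed is required for the Monte Carlo estimator")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- stats::rbeta(mc_draws, a, b)
  Z <- matrix(stats::rbinom(J * mc_draws, 1, rep(p, each = J)), nrow = J)
  X <- config_matrix(G, Z, moi, ploidy)
  logml <- log_ml_strata(X, y, risk)
  m <- max(logml)
  w <- exp(logml - m)
  le <- m + log(mean(w))
  se <- stats::sd(w) / (sqrt(mc_draws) * mean(w))
  if (!is.finite(le)) stop("non-finite evidence (J = ", J, ", moi = ", moi, ")")
  list(log_evidence = le, estimator = "monte_carlo", draws = mc_draws,
       std_error = se)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-variant pathogenicity posteriors
#'
#' Posterior probability that each variant is pathogenic, conditional on one
#' association model (normally the modal model), computed from the same sum
#' over latent indicators as [model_evidence()]. A variant carried by no one
#' keeps its prior mean.
#'
#' @inheritParams model_evidence
#' @return numeric vector of posterior probabilities, one per column of G.
#' @export
variant_pathogenicity <- function(G, y, moi = c("dominant", "recessive"),
                                  path_prior = c(2, 8), risk = risk_prior(),
                                  ploidy = rep(2, length(y)),
                                  max_enumeration = 12, mc_draws = 5000,
                                  seed = NULL) {
  moi <- match.arg(moi)
  y <- as.numeric(y)
  G <- as.matrix(G)
  J <- ncol(G)
  if (J == 0) return(numeric(0))
  a <- path_prior[1]; b <- path_prior[2]
  if (J <= max_enumeration) {
    Z <- all_z(J)
    X <- config_matrix(G, Z, moi, ploidy)
    logml <- log_ml_strata(X, y, risk)
    s <- colSums(Z)
    logw <- lbeta(a + s, b + J - s) - lbeta(a, b) + logml
    tot <- logsumexp(logw)
    vapply(seq_len(J), function(j) {
      exp(logsumexp(logw[Z[j, ] == 1]) - tot)
    }, numeric(1))
  } else {
    if (is.null(seed)) stop("a seed is required for the Monte Carlo estimator")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    p <- stats::rbeta(mc_draws, a, b)
    Z <- matrix(stats::rbinom(J * mc_draws, 1, rep(p, each = J)), nrow = J)
    X <- config_matrix(G, Z, moi, ploidy)
    logml <- log_ml_strata(X, y, risk)
    w <- exp(logml - max(logml))
    as.vector((Z %*% w) / sum(w))
  }
}

#' Posterior probabilities of association from model evidences
#'
#' Normalizes prior x evidence over the seven models. The posterior
#' probability of association (PPA) is the total mass on the six association
#' models; the modal model is the association model with the greatest
#' posterior, ties broken by model order (dominant before recessive, high
#' before moderate before 5' UTR).
#'
#' @param log_evidence numeric vector of log evidences aligned with `specs`.
#' @param specs model table from [default_model_specs()].
#' @return list(ppa, posterior (named by model), modal_model (one-row spec)).
#' @export
compute_ppa <- function(log_evidence, specs = default_model_specs()) {
  stopifnot(length(log_evidence) == nrow(specs))
  lp <- log(specs$prior) + log_evidence
  post <- exp(lp - logsumexp(lp))
  post <- post / sum(post)
  assoc <- which(specs$kind == "association")
  ppa <- sum(post[assoc])
  modal <- assoc[which.max(post[assoc])]
  list(ppa = ppa, posterior = stats::setNames(post, specs$model),
       modal_model = specs[modal])
}

#' Filter qualifying variants for one model specification
#'
#' A variant qualifies when its consequence mask meets the model's impact
#' class, its PMAF score reaches the model's minimum, its median genotype
#' quality is at least 35 (when available), it is not a low-confidence
#' loss-of-function call under the high-impact class, and - for SNVs with an
#' available score - its CADD Phred score is at least 10.
#'
#' @param variants data.frame with columns rsvr_id, csq, pmaf and optionally
#'   cadd, gq_median, loftee, is_snv (inferred from allele lengths if absent).
#' @param spec one row of [default_model_specs()].
#' @param cadd_min,gq_min filter thresholds (defaults 10 and 35).
#' @return character vector of qualifying rsvr_ids.
#' @export
qualifying_variants <- function(variants, spec, cadd_min = 10, gq_min = 35) {
  v <- as.data.table(variants)
  if (nrow(v) == 0) return(character(0))
  if (!"is_snv" %in% names(v)) {
    d <- decode_rsvr(v$rsvr_id)
    v$is_snv <- d$ref_len == 1 & d$alt_len == 1
  }
  keep <- meets_impact(v$csq, spec$variant_class) & v$pmaf >= spec$pmaf_min
  if ("gq_median" %in% names(v)) {
    keep <- keep & (is.na(v$gq_median) | v$gq_median >= gq_min)
  }
  if ("cadd" %in% names(v)) {
    keep <- keep & !(v$is_snv & !is.na(v$cadd) & v$cadd < cadd_min)
  }
  if (spec$variant_class == "high" && "loftee" %in% names(v)) {
    keep <- keep & (is.na(v$loftee) | v$loftee != "low_confidence")
  }
  v$rsvr_id[keep]
}

#' Select the case/control cohort for one gene and case set
#'
#' One case is chosen from each pedigree containing at least one affected
#' member of the case set (the lexicographically first affected member, for
#' determinism). Controls are the members of the maximal unrelated set who do
#' not belong to any case pedigree. Cases explained by variants in a
#' different gene are reassigned to the control group.
#'
#' @param samples data.frame with columns sample_id, family_id,
#'   unrelated_flag (logical).
#' @param case_members character vector of sample ids in the case set.
#' @param explained optional data.frame with columns sample_id, gene (the
#'   gene whose variants explain that sample).
#' @param gene the gene under analysis.
#' @return list(cases, controls) of sample-id vectors.
#' @export
select_analysis_cohort <- function(samples, case_members, explained = NULL,
                                   gene = NA_character_) {
  s <- as.data.table(samples)
  if (length(case_members) == 0) stop("empty case set")
  in_set <- s[sample_id %in% case_members]
  if (nrow(in_set) == 0) stop("case set has no members in the sample table")
  case_fams <- unique(in_set$family_id)
  cases <- in_set[order(sample_id), list(case = sample_id[1]), by = family_id]$case
  controls <- s[!(family_id %in% case_fams) & unrelated_flag == TRUE, sample_id]
  if (!is.null(explained) && nrow(as.data.frame(explained)) > 0) {
    e <- as.data.frame(explained)
    moved <- intersect(cases, e$sample_id[e$gene != gene])
    cases <- setdiff(cases, moved)
    controls <- union(controls, moved)
  }
  list(cases = cases, controls = sort(controls))
}

#' Full model comparison for one gene and case set
#'
#' Runs [model_evidence()] for the baseline model and each association model
#' on its own qualifying-variant set, then [compute_ppa()] and
#' [variant_pathogenicity()] under the modal model.
#'
#' @param variants per-gene variant annotation table (see
#'   [qualifying_variants()]).
#' @param genotypes data.frame with columns sample_id, rsvr_id, allele_count.
#' @param cases,controls sample-id vectors from [select_analysis_cohort()].
#' @param specs model table (default [default_model_specs()]).
#' @param risk a [risk_prior()].
#' @param ploidy named per-sample ploidy vector (default 2 for everyone).
#' @param max_enumeration,mc_draws,seed estimator controls, see
#'   [model_evidence()].
#' @return list(ppa, posterior, modal_model, variant_posterior (named by
#'   rsvr_id), log_evidence, estimator).
#' @export
gene_association <- function(variants, genotypes, cases, controls,
                             specs = default_model_specs(),
                             risk = risk_prior(), ploidy = NULL,
                             max_enumeration = 12, mc_draws = 5000,
                             seed = 1) {
  ids <- c(cases, controls)
  y <- c(rep(1, length(cases)), rep(0, length(controls)))
  if (is.null(ploidy)) ploidy <- stats::setNames(rep(2, length(ids)), ids)
  g <- as.data.table(genotypes)[sample_id %in% ids]
  ev <- numeric(nrow(specs))
  est <- character(nrow(specs))
  qv <- vector("list", nrow(specs))
  for (m in seq_len(nrow(specs))) {
    spec <- specs[m]
    if (spec$kind == "baseline") {
      ev[m] <- baseline_evidence(y, risk)
      est[m] <- "exact"
      next
    }
    vars <- qualifying_variants(variants, spec)
    qv[[m]] <- vars
    G <- genotype_matrix(g, ids, vars)
    r <- model_evidence(G, y, moi = spec$moi,
                        path_prior = c(spec$path_a, spec$path_b), risk = risk,
                        ploidy = unname(ploidy[ids]),
                        max_enumeration = max_enumeration,
                        mc_draws = mc_draws, seed = seed + m)
    ev[m] <- r$log_evidence
    est[m] <- r$estimator
  }
  res <- compute_ppa(ev, specs)
  modal_idx <- res$modal_model$model
  vars <- qv[[modal_idx]]
  G <- genotype_matrix(g, ids, vars)
  vp <- variant_pathogenicity(G, y, moi = res$modal_model$moi,
                              path_prior = c(res$modal_model$path_a,
                                             res$modal_model$path_b),
                              risk = risk, ploidy = unname(ploidy[ids]),
                              max_enumeration = max_enumeration,
                              mc_draws = mc_draws, seed = seed + modal_idx)
  list(ppa = res$ppa, posterior = res$posterior,
       modal_model = res$modal_model,
       variant_posterior = stats::setNames(vp, vars),
       log_evidence = stats::setNames(ev, specs$model), estimator = est)
}

#' Dense genotype matrix for selected samples and variants
#'
#' @param genotypes data.frame with columns sample_id, rsvr_id, allele_count.
#' @param sample_ids row order.
#' @param variant_ids column order.
#' @return numeric matrix (samples x variants).
#' @export
genotype_matrix <- function(genotypes, sample_ids, variant_ids) {
  G <- matrix(0, nrow = length(sample_ids), ncol = length(variant_ids),
              dimnames = list(sample_ids, variant_ids))
  if (length(variant_ids) == 0) return(G)
  g <- as.data.table(genotypes)[sample_id %in% sample_ids & rsvr_id %in% variant_ids]
  if (nrow(g) > 0) {
    G[cbind(match(g$sample_id, sample_ids), match(g$rsvr_id, variant_ids))] <-
      g$allele_count
  }
  G
}
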