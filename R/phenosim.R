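#' Ontology DAG
#'
#' A rooted directed acyclic graph of phenotype terms with is-a edges from
#' child to parent. `ontology_dag` validates acyclicity and reachability of
#' the single root and precomputes the ancestor closure (every term is its
#' own ancestor; the root is an ancestor of everything).
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping each term to its parent term ids (the
#'   root maps to an empty vector).
#' @param names optional named character vector of term labels.
#' @return an object of class "ontology_dag" with elements terms, parents,
#'   ancestors (named list), root.
#' @export
ontology_dag <- function(terms, parents, names = NULL) {
  stopifnot(all(names(parents) %in% terms) || length(parents) == 0)
  parents <- lapply(terms, function(t) {
    p <- parents[[t]]
    if (is.null(p)) character(0) else intersect(p, terms)
  })
  names(parents) <- terms
  roots <- terms[vapply(parents, length, integer(1)) == 0]
  if (length(roots) != 1) {
    stop("ontology must have exactly one root, found ", length(roots))
  }
  anc <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  closure <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (!is.null(visiting[[t]])) stop("cycle in ontology at term ", t)
    assign(t, TRUE, envir = visiting)
    res <- unique(c(t, unlist(lapply(parents[[t]], closure))))
    assign(t, res, envir = anc)
    res
  }
  ancestors <- lapply(terms, closure)
  names(ancestors) <- terms
  ok <- vapply(ancestors, function(a) roots %in% a, logical(1))
  if (!all(ok)) stop("term(s) not reaching the root: ",
                     paste(terms[!ok], collapse = ", "))
  structure(list(terms = terms, parents = parents, ancestors = ancestors,
                 root = roots, labels = names),
            class = "ontology_dag")
}

#' Read a minimal OBO ontology
#'
#' Parses `[Term]` stanzas for id, name and is_a relations. This covers the
#' subset of OBO needed for ancestor closure and information content; no
#' other relationship types are read.
#'
#' @param path OBO file.
#' @return an [ontology_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0)
  labels <- character(0)
  parents <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "[Term]") {
      cur <- NULL
    } else if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      terms <- c(terms, cur)
      parents[[cur]] <- character(0)
    } else if (!is.null(cur) && startsWith(ln, "name: ")) {
      labels[cur] <- sub("^name: ", "", ln)
    } else if (!is.null(cur) && startsWith(ln, "is_a: ")) {
      p <- sub("^is_a: ", "", ln)
      p <- sub(" !.*$", "", p)
      parents[[cur]] <- c(parents[[cur]], trimws(p))
    }
  }
  ontology_dag(terms, parents, names = labels)
}

#' Ancestor-closed family phenotypes
#'
#' @param annotations data.frame with columns family_id, term_id.
#' @param dag an [ontology_dag()].
#' @return named list: per family, list(assigned, closed) term sets.
#' @export
family_phenotypes <- function(annotations, dag) {
  a <- as.data.table(annotations)
  bad <- setdiff(unique(a$term_id), dag$terms)
  if (length(bad) > 0) stop("unknown ontology term(s): ",
                            paste(bad, collapse = ", "))
  fams <- split(a$term_id, a$family_id)
  lapply(fams, function(ts) {
    ts <- unique(ts)
    list(assigned = ts,
         closed = unique(c(unlist(dag$ancestors[ts]), dag$root)))
  })
}

#' Information content of ontology terms
#'
#' IC(t) = -ln of the fraction of families whose ancestor-closed term set
#' contains t. The root has IC 0. Terms observed in no family receive the
#' pseudo-frequency 1/(2 N) so their IC is finite.
#'
#' @param families output of [family_phenotypes()].
#' @param dag an [ontology_dag()].
#' @return named numeric vector over all dag terms.
#' @export
information_content <- function(families, dag) {
  n <- length(families)
  stopifnot(n >= 1)
  counts <- table(factor(unlist(lapply(families, `[[`, "closed")),
                         levels = dag$terms))
  freq <- as.numeric(counts) / n
  freq[freq == 0] <- 1 / (2 * n)
  stats::setNames(-log(freq), dag$terms)
}

#' Resnik similarity between two families
#'
#' Term-pair similarity is the maximum information content over common
#' ancestors; family-level similarity is the symmetric best-match average
#' over the two assigned term sets. Families sharing only the root have
#' similarity 0; an empty term set gives 0.
#'
#' @param f1,f2 elements of [family_phenotypes()].
#' @param ic named IC vector from [information_content()].
#' @param dag an [ontology_dag()].
#' @return nonnegative similarity.
#' @export
resnik_similarity <- function(f1, f2, ic, dag) {
  t1 <- f1$assigned; t2 <- f2$assigned
  if (length(t1) == 0 || length(t2) == 0) return(0)
  sim <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      common <- intersect(dag$ancestors[[t1[i]]], dag$ancestors[[t2[j]]])
      sim[i, j] <- max(ic[common])
    }
  }
  (mean(apply(sim, 1, max)) + mean(apply(sim, 2, max))) / 2
}

#' All-pairs family similarity matrix
#'
#' @param families output of [family_phenotypes()].
#' @param dag an [ontology_dag()].
#' @param ic optional precomputed IC vector.
#' @return symmetric numeric matrix.
#' @export
similarity_matrix <- function(families, dag, ic = NULL) {
  if (is.null(ic)) ic <- information_content(families, dag)
  n <- length(families)
  S <- matrix(0, n, n, dimnames = list(names(families), names(families)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      S[i, j] <- S[j, i] <- resnik_similarity(families[[i]], families[[j]],
                                              ic, dag)
    }
  }
  S
}

#' Permutation test for a phenotypically similar family cluster
#'
#' Tests whether k target families are more similar to each other than
#' random k-subsets of the cohort. The statistic is the mean pairwise Resnik
#' similarity among the targets; the null is the same statistic on `n_perm`
#' random subsets, and p = (1 + #(null >= observed)) / (1 + n_perm).
#'
#' @param target_ids family ids of the putative cluster (k >= 2).
#' @param families output of [family_phenotypes()] for the whole cohort.
#' @param dag an [ontology_dag()].
#' @param n_perm permutation count (default 1000).
#' @param seed RNG seed.
#' @param sim optional precomputed [similarity_matrix()].
#' @return list(p_value, observed, n_perm).
#' @export
family_cluster_test <- function(target_ids, families, dag, n_perm = 1000,
                                seed = 1, sim = NULL) {
  k <- length(target_ids)
  n <- length(families)
  if (k < 2) stop("need at least two target families")
  if (k > n) stop("more targets than families")
  stopifnot(all(target_ids %in% names(families)))
  if (is.null(sim)) sim <- similarity_matrix(families, dag)
  mean_pairwise <- function(ids) {
    s <- sim[ids, ids, drop = FALSE]
    mean(s[upper.tri(s)])
  }
  obs <- mean_pairwise(target_ids)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null <- replicate(n_perm, mean_pairwise(sample(names(families), k)))
  list(p_value = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs,
       n_perm = n_perm)
}

fisher_presence_p <- function(in_target, in_other, n_target, n_other,
                              memo = NULL) {
  if (!is.null(memo)) {
    key <- paste(in_target, in_other, sep = "_")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
  }
  p <- stats::fisher.test(matrix(c(in_target, n_target - in_target,
                                   in_other, n_other - in_other),
                                 nrow = 2))$p.value
  if (!is.null(memo)) assign(key, p, envir = memo)
  p
}

enrichment_candidates <- function(closed_sets, target_ids, min_support, dag) {
  targets <- closed_sets[target_ids]
  counts <- table(unlist(targets))
  cand <- names(counts)[counts >= min_support]
  # redundancy rule: drop a term when one of its proper descendants has the
  # same frequency among the targets (the descendant is at least as specific)
  drop <- vapply(cand, function(t) {
    desc <- setdiff(dag$terms[vapply(dag$terms, function(d) {
      t %in% dag$ancestors[[d]] && d != t
    }, logical(1))], t)
    any(desc %in% cand & counts[desc] == counts[[t]])
  }, logical(1))
  cand[!drop]
}

#' Step-down permutation enrichment of ontology terms
#'
#' Compares term prevalence between a small set of target families and the
#' remaining families. Candidate terms are those present (after ancestor
#' closure) in at least `min_support` targets, excluding terms with an
#' equally frequent more specific descendant. Each candidate gets a
#' two-sided Fisher exact p-value for presence-in-family versus target
#' membership, and terms are ranked by p-value. Target labels are then
#' permuted `n_perm` times to build a null distribution of ranked p-value
#' vectors; at each rank the 5th percentile of the null is the significance
#' bound, and a term is significant only if its p-value is strictly below
#' its rank's bound and all better-ranked terms are significant (step-down).
#'
#' @param target_ids family ids of the target group.
#' @param families output of [family_phenotypes()] for the whole cohort.
#' @param dag an [ontology_dag()].
#' @param min_support minimum target families containing a term (default 3).
#' @param n_perm permutation count (default 10000).
#' @param seed RNG seed.
#' @return data.table(term, in_target, in_other, p_value, rank, bound,
#'   significant), ordered by rank.
#' @export
term_enrichment <- function(target_ids, families, dag, min_support = 3,
                            n_perm = 10000, seed = 1) {
  stopifnot(all(target_ids %in% names(families)))
  closed <- lapply(families, `[[`, "closed")
  n_t <- length(target_ids)
  other_ids <- setdiff(names(families), target_ids)
  n_o <- length(other_ids)
  annotated <- sum(vapply(closed[target_ids], length, integer(1)) > 0)
  if (annotated < min_support) {
    return(data.table(term = character(0), in_target = integer(0),
                      in_other = integer(0), p_value = numeric(0),
                      rank = integer(0), bound = numeric(0),
                      significant = logical(0)))
  }
  cand <- enrichment_candidates(closed, target_ids, min_support, dag)
  if (length(cand) == 0) {
    return(data.table(term = character(0), in_target = integer(0),
                      in_other = integer(0), p_value = numeric(0),
                      rank = integer(0), bound = numeric(0),
                      significant = logical(0)))
  }
  # presence matrix over candidate terms only (recomputed under permutation)
  pres <- vapply(cand, function(t) {
    vapply(closed, function(s) t %in% s, logical(1))
  }, logical(length(closed)))
  rownames(pres) <- names(families)
  memo <- new.env(parent = emptyenv())
  pvec <- function(tids) {
    is_t <- rownames(pres) %in% tids
    sort(vapply(seq_along(cand), function(j) {
      fisher_presence_p(sum(pres[is_t, j]), sum(pres[!is_t, j]),
                        sum(is_t), sum(!is_t), memo)
    }, numeric(1)))
  }
  obs_p <- vapply(seq_along(cand), function(j) {
    fisher_presence_p(sum(pres[target_ids, j]), sum(pres[other_ids, j]),
                      n_t, n_o, memo)
  }, numeric(1))
  ord <- order(obs_p, cand)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null <- replicate(n_perm, pvec(sample(names(families), n_t)))
  null <- matrix(null, nrow = length(cand))
  bounds <- apply(null, 1, stats::quantile, probs = 0.05, type = 1)
  sig <- logical(length(cand))
  for (r in seq_along(cand)) {
    # strict comparison: with discrete Fisher p-values an atom sitting on the
    # bound would otherwise inflate the false-positive rate above nominal
    ok <- obs_p[ord[r]] < bounds[r]
    sig[r] <- ok && (r == 1 || sig[r - 1])
  }
  data.table(term = cand[ord],
             in_target = colSums(pres[target_ids, ord, drop = FALSE]),
             in_other = colSums(pres[other_ids, ord, drop = FALSE]),
             p_value = obs_p[ord], rank = seq_along(cand),
             bound = bounds, significant = sig)
}
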