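test_that("information content follows closed-set frequencies", {
  dag <- toy_dag()
  ann <- data.frame(family_id = c("F1", "F2", "F3", "F4"),
                    term_id = c("leaf1", "leaf4", "leaf7", "leaf9"))
  fams <- family_phenotypes(ann, dag)
  ic <- information_content(fams, dag)
  expect_equal(unname(ic["root"]), 0)
  expect_equal(unname(ic["leaf1"]), log(4))  # one family in four
  # monotone non-increasing child -> parent
  for (t in dag$terms) {
    for (p in dag$parents[[t]]) {
      expect_lte(ic[[p]], ic[[t]])
    }
  }
  # unobserved terms take the pseudo-frequency 1/(2N)
  expect_equal(unname(ic["leaf2"]), log(8))
})

test_that("Resnik similarity is a symmetric best-match average", {
  dag <- toy_dag()
  ann <- data.frame(
    family_id = c("F1", "F1", "F2", "F2", "F3", "F4"),
    term_id = c("leaf1", "leaf4", "leaf2", "leaf4", "leaf7", "leaf2"))
  fams <- family_phenotypes(ann, dag)
  ic <- information_content(fams, dag)
  # identical families: average of each term's own IC
  expect_equal(resnik_similarity(fams$F1, fams$F1, ic, dag),
               mean(ic[c("leaf1", "leaf4")]))
  # families whose terms share only the root (leaf7 under mid3, leaf2 mid1)
  expect_equal(resnik_similarity(fams$F3, fams$F4, ic, dag), 0)
  # hand-computed toy instance: best-match table over common ancestors
  # F1 = {leaf1, leaf4}, F2 = {leaf2, leaf4}
  # leaf1 vs leaf2 share mid1 (IC = -ln(2/4)); leaf4 matches itself
  expect_equal(resnik_similarity(fams$F1, fams$F2, ic, dag),
               mean(c(max(ic["mid1"], 0), ic[["leaf4"]])))
  # symmetry on random annotation sets
  rnd <- family_phenotypes(random_family_annotations(10, seed = 4), dag)
  ic2 <- information_content(rnd, dag)
  for (i in 1:5) {
    a <- rnd[[i]]; b <- rnd[[11 - i]]
    expect_identical(resnik_similarity(a, b, ic2, dag),
                     resnik_similarity(b, a, ic2, dag))
  }
})

test_that("family cluster test separates planted clusters from noise", {
  dag <- toy_dag()
  set.seed(10)
  # 20 families: four identical targets, the rest on scattered leaves
  ann <- rbind(
    data.frame(family_id = rep(sprintf("T%d", 1:4), each = 2),
               term_id = rep(c("leaf1", "leaf2"), 4)),
    data.frame(family_id = rep(sprintf("N%02d", 1:16), each = 1),
               term_id = sample(paste0("leaf", 4:9), 16, replace = TRUE)))
  fams <- family_phenotypes(ann, dag)
  r <- family_cluster_test(sprintf("T%d", 1:4), fams, dag, n_perm = 400,
                           seed = 3)
  expect_equal(r$p_value, 1 / 401, tolerance = 1e-12)
  # k = N is degenerate: only one subset exists
  rall <- family_cluster_test(names(fams), fams, dag, n_perm = 50, seed = 3)
  expect_equal(rall$p_value, 1)
  expect_error(family_cluster_test(c("T1"), fams, dag), "at least two")
  expect_error(family_cluster_test(c(names(fams), "ZZ"), fams, dag),
               "more targets")
})

test_that("term enrichment finds planted terms and applies redundancy rule", {
  dag <- toy_dag()
  set.seed(11)
  n_other <- 120
  other <- data.table::rbindlist(lapply(1:n_other, function(i) {
    data.table::data.table(family_id = sprintf("N%03d", i),
                           term_id = sample(paste0("leaf", 4:9), 2))
  }))
  targets <- data.table::data.table(
    family_id = rep(sprintf("T%d", 1:4), each = 2),
    term_id = rep(c("leaf1", "leaf9"), 4))
  fams <- family_phenotypes(rbind(targets, other), dag)
  res <- term_enrichment(sprintf("T%d", 1:4), fams, dag, min_support = 3,
                         n_perm = 500, seed = 7)
  # leaf1 is in 4/4 targets and no others: top-ranked and significant
  expect_equal(res$term[1], "leaf1")
  expect_true(res$significant[1])
  # mid1 has the same target frequency as its descendant leaf1: redundant
  expect_false("mid1" %in% res$term)
  # step-down: significance flags form a prefix of the ranking
  expect_true(all(diff(res$significant) <= 0))
  # fewer than min_support annotated targets: empty result
  empty <- term_enrichment(sprintf("T%d", 1:2), fams, dag, min_support = 3,
                           n_perm = 10, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("the OBO reader reproduces a round-tripped ontology", {
  cfg <- sim_config(seed = 6, n_families = 2)
  ref <- simulate_reference(cfg, file.path(tempdir(), "oboref"))
  cohort_dir <- file.path(tempdir(), "oboann")
  # build just the ontology via simulate_annotations on a tiny cohort
  cohort <- simulate_cohort(sim_config(seed = 6, n_families = 2,
                                       etiologies = list()),
                            ref, cohort_dir)
  ann <- simulate_annotations(sim_config(seed = 6, n_families = 2,
                                         etiologies = list()),
                              ref, cohort, cohort_dir)
  dag <- read_obo(ann$obo)
  expect_s3_class(dag, "ontology_dag")
  expect_equal(dag$root, "SIM:0000")
  expect_equal(length(dag$terms), 21)  # root + 4 systems + 16 leaves
  expect_true(all(vapply(dag$ancestors, function(a) "SIM:0000" %in% a,
                         logical(1))))
})
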