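test_that("default model table carries the documented priors", {
  s <- default_model_specs()
  expect_equal(nrow(s), 7)
  expect_equal(s$prior[s$kind == "baseline"], 0.99)
  expect_equal(sum(s$prior), 1)
  expect_equal(sum(s$prior[s$kind == "association"]), 0.01)
  # dominant and recessive carry equal prior mass
  expect_equal(sum(s$prior[which(s$moi == "dominant")]),
               sum(s$prior[which(s$moi == "recessive")]))
  expect_true(all(s$pmaf_min[which(s$moi == "dominant")] == 2))
  expect_true(all(s$pmaf_min[which(s$moi == "recessive")] == 1))
  expect_true(all(s[variant_class == "high", c(path_a, path_b)] == c(3, 3, 1, 1)))
})

test_that("evidence with no variants equals the baseline evidence", {
  set.seed(2)
  y <- rbinom(30, 1, 0.3)
  r <- model_evidence(matrix(0, 30, 0), y, "dominant")
  expect_equal(r$log_evidence, baseline_evidence(y))
  expect_equal(r$estimator, "exact_enumeration")
})

test_that("exact evidence matches the brute-force integration oracle", {
  for (seed in 1:8) {
    inst <- random_instance(seed, n_max = 15, j_max = 6)
    for (moi in c("dominant", "recessive")) {
      for (pp in list(c(2, 8), c(3, 1))) {
        got <- model_evidence(inst$G, inst$y, moi, path_prior = pp)$log_evidence
        want <- oracle_evidence(inst$G, inst$y, moi, pp)
        expect_equal(got, want, tolerance = 1e-6,
                     info = sprintf("seed %d %s", seed, moi))
      }
    }
  }
})

test_that("Monte Carlo estimator agrees with exact enumeration", {
  set.seed(99)
  inst <- list(G = matrix(stats::rbinom(20 * 8, 2, 0.15), 20, 8),
               y = stats::rbinom(20, 1, 0.4))
  exact <- model_evidence(inst$G, inst$y, "dominant")$log_evidence
  mc <- model_evidence(inst$G, inst$y, "dominant", max_enumeration = 4,
                       mc_draws = 20000, seed = 5)
  expect_equal(mc$estimator, "monte_carlo")
  expect_lt(abs(mc$log_evidence - exact), 3 * mc$std_error + 1e-8)
  # seeded: same seed reproduces, different seed varies
  mc2 <- model_evidence(inst$G, inst$y, "dominant", max_enumeration = 4,
                        mc_draws = 20000, seed = 5)
  expect_identical(mc$log_evidence, mc2$log_evidence)
  expect_error(model_evidence(inst$G, inst$y, "dominant", max_enumeration = 4),
               "seed")
})

test_that("posteriors normalize and return to the prior when data are flat", {
  ev <- rep(-10, 7)
  r <- compute_ppa(ev)
  expect_equal(sum(r$posterior), 1, tolerance = 1e-12)
  expect_equal(r$ppa, 0.01, tolerance = 1e-12)
  # a dominating association model takes the posterior with it
  ev2 <- c(-100, -5, rep(-100, 5))
  r2 <- compute_ppa(ev2)
  expect_gt(r2$ppa, 0.999)
  expect_equal(r2$modal_model$model, 2L)
  # ties break in fixed model order
  ev3 <- c(-100, rep(-5, 6))
  expect_equal(compute_ppa(ev3)$modal_model$model, 2L)
})

test_that("per-variant posteriors follow the enumeration oracle", {
  # J = 1, carried only by cases: posterior above the prior mean
  y <- c(rep(1, 5), rep(0, 20))
  G <- matrix(c(rep(1, 4), rep(0, 21)), ncol = 1)
  post <- variant_pathogenicity(G, y, "dominant", path_prior = c(2, 8))
  expect_gt(post, 2 / 10)
  # J = 1, carried by no one: exactly the prior mean
  G0 <- matrix(0, 25, 1)
  expect_equal(variant_pathogenicity(G0, y, "dominant", path_prior = c(2, 8)),
               2 / 10, tolerance = 1e-10)
  # posteriors bounded in [0, 1] on random instances
  for (seed in 1:5) {
    inst <- random_instance(seed + 50, n_max = 12, j_max = 5)
    p <- variant_pathogenicity(inst$G, inst$y, "recessive")
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("qualifying variants respect class, PMAF, CADD, GQ and LOFTEE", {
  v <- data.frame(
    rsvr_id = c("v1", "v2", "v3", "v4", "v5", "v6"),
    csq = c(encode_csq("stop_gained"), encode_csq("stop_gained"),
            encode_csq("missense_variant"), encode_csq("frameshift_variant"),
            encode_csq("stop_gained"), encode_csq("stop_gained")),
    pmaf = c(3, 3, 3, 3, 1, 3),
    cadd = c(35, 5, 25, NA, 35, 35),
    gq_median = c(99, 99, 99, 99, 99, 20),
    loftee = c(NA, NA, NA, NA, NA, NA),
    is_snv = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  dom_high <- default_model_specs()[2]
  # v2: SNV with CADD < 10; v5: PMAF 1 under a dominant spec; v6: low GQ
  expect_setequal(qualifying_variants(v, dom_high), c("v1", "v4"))
  rec_high <- default_model_specs()[5]
  expect_setequal(qualifying_variants(v, rec_high), c("v1", "v4", "v5"))
  # low-confidence LOFTEE excluded under the high class only
  v$loftee[1] <- "low_confidence"
  expect_setequal(qualifying_variants(v, dom_high), "v4")
  dom_mod <- default_model_specs()[3]
  expect_true("v1" %in% qualifying_variants(v, dom_mod))
  expect_true("v3" %in% qualifying_variants(v, dom_mod))
})

test_that("analysis cohorts take one case per pedigree and honor explained labels", {
  samples <- data.frame(
    sample_id = c("A1", "A2", "B1", "B2", "C1", "D1", "D2", "E1"),
    family_id = c("FA", "FA", "FB", "FB", "FC", "FD", "FD", "FE"),
    unrelated_flag = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  members <- c("A1", "A2", "B2", "C1")  # three pedigrees with cases
  sel <- select_analysis_cohort(samples, members, gene = "G1")
  expect_equal(sort(sel$cases), c("A1", "B2", "C1"))
  # controls: unrelated members of non-case pedigrees only (D2 is a relative)
  expect_equal(sel$controls, c("D1", "E1"))
  # a case explained by a different gene moves to the controls
  sel2 <- select_analysis_cohort(samples, members,
                                 explained = data.frame(sample_id = "C1",
                                                        gene = "G9"),
                                 gene = "G1")
  expect_equal(sort(sel2$cases), c("A1", "B2"))
  expect_true("C1" %in% sel2$controls)
  expect_error(select_analysis_cohort(samples, character(0)), "empty case set")
})
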