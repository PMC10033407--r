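# Shared fixtures built in code. All randomness is seeded locally.

# A one-exon plus-strand coding transcript with CDS "ATG GAA TAA" embedded in
# a short chromosome at offset `cds_at` (1-based).
toy_coding_fixture <- function(cds_at = 11, flank = 30) {
  set.seed(42)
  left <- paste(sample(c("A", "C", "G", "T"), cds_at - 1, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                 collapse = "")
  genome <- c("1" = paste0(left, "ATGGAATAA", right))
  tx <- transcript_model("toy.t1", "TOY", "1", "+",
                         exons = data.frame(start = cds_at, end = cds_at + 8),
                         cds = data.frame(start = cds_at, end = cds_at + 8))
  list(genome = genome, tx = tx, cds_at = cds_at)
}

# Two-exon transcript (either strand) with a 20 bp intron, all-coding exons.
toy_spliced_fixture <- function(strand = "+") {
  set.seed(43)
  n <- 200
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  # CDS pieces: exon1 51..62 (12 bp), exon2 83..97 (15 bp) -> 27 bp, 9 codons
  cds_pos <- c(51:62, 83:97)
  codons <- c("ATG", "GAA", "CCT", "GGA", "TTC", "AAA", "CCC", "GGG", "TAA")
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- rev(comp[strsplit(paste(codons, collapse = ""), "")[[1]]])
    chars[cds_pos] <- rc
  } else {
    chars[cds_pos] <- strsplit(paste(codons, collapse = ""), "")[[1]]
  }
  genome <- c("1" = paste(chars, collapse = ""))
  tx <- transcript_model("sp.t1", "SP", "1", strand,
                         exons = data.frame(start = c(51, 83),
                                            end = c(62, 97)),
                         cds = data.frame(start = c(51, 83),
                                          end = c(62, 97)))
  list(genome = genome, tx = tx)
}

# Random normalized small variants for codec property tests.
random_variants <- function(n, seed = 1, max_alt = 9, max_ref = 63) {
  set.seed(seed)
  nuc <- c("A", "C", "G", "T")
  rand_seq <- function(len) {
    vapply(len, function(l) {
      if (l == 0) "" else paste(sample(nuc, l, replace = TRUE), collapse = "")
    }, character(1))
  }
  repeat {
    chrom <- sample(1:25, n, replace = TRUE)
    pos <- sample.int(2^28 - 1, n, replace = TRUE)
    rl <- sample(0:max_ref, n, replace = TRUE, prob = 1 / (1 + 0:max_ref))
    al <- sample(0:max_alt, n, replace = TRUE, prob = 1 / (1 + 0:max_alt))
    ok <- !(rl == 0 & al == 0)
    chrom <- chrom[ok]; pos <- pos[ok]; rl <- rl[ok]; al <- al[ok]
    if (length(chrom) >= n * 0.9) break
  }
  data.frame(chrom = chrom, pos = pos, ref = rand_seq(rl),
             alt = rand_seq(al), stringsAsFactors = FALSE)
}

# Small association instance generator for oracle tests.
random_instance <- function(seed, n_max = 20, j_max = 10) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  J <- sample(1:j_max, 1)
  G <- matrix(stats::rbinom(n * J, 2, 0.15), n, J)
  y <- stats::rbinom(n, 1, 0.4)
  list(G = G, y = y, n = n, J = J)
}

# Independent brute-force oracle for the model evidence: exhaustive sum over
# latent pathogenicity vectors with numeric (Simpson) integration over the
# risk and pathogenicity probabilities, sharing no code with model_evidence().
oracle_evidence <- function(G, y, moi, path_prior, tau0 = c(1, 9),
                            tau1 = c(4, 2), grid_n = 2001) {
  n <- nrow(G); J <- ncol(G)
  tt <- seq(0, 1, length.out = grid_n)
  simpson <- function(f) {
    w <- c(1, rep(c(4, 2), (grid_n - 3) / 2), 4, 1)
    sum(w * f) * (tt[2] - tt[1]) / 3
  }
  # integral of t^k (1-t)^(m-k) under a Beta(a, b) density; integrals are
  # cached by their counts, which is an algebraic identity, not a shortcut
  # through the implementation under test
  stratum_tab <- function(ab) {
    outer(0:n, 0:n, Vectorize(function(k, m) {
      if (m == 0) return(1)
      if (k > m) return(NA_real_)
      simpson(tt^k * (1 - tt)^(m - k) * stats::dbeta(tt, ab[1], ab[2]))
    }))
  }
  I0 <- stratum_tab(tau0)
  I1 <- stratum_tab(tau1)
  prior_tab <- vapply(0:J, function(s) {
    simpson(tt^s * (1 - tt)^(J - s) * stats::dbeta(tt, path_prior[1],
                                                   path_prior[2]))
  }, numeric(1))
  total <- 0
  for (code in 0:(2^J - 1)) {
    z <- as.integer(intToBits(code))[1:J]
    x <- numeric(n)
    for (i in 1:n) {
      carried <- sum(G[i, ] * z)
      x[i] <- if (moi == "dominant") as.numeric(carried >= 1)
              else as.numeric(carried >= 2)
    }
    k1 <- sum(y[x == 1]); n1 <- sum(x == 1)
    k0 <- sum(y[x == 0]); n0 <- sum(x == 0)
    total <- total + prior_tab[sum(z) + 1] *
      I1[k1 + 1, n1 + 1] * I0[k0 + 1, n0 + 1]
  }
  log(total)
}

# Cohort generator used by the association calibration tests: a population
# sampled to a fixed number of cases and controls with a planted etiology.
planted_cohort <- function(seed, moi, n_cases = 500, n_controls = 5000,
                           n_path = 5, n_benign = 7, penetrance = 0.95,
                           phenocopy = 0.01) {
  set.seed(seed)
  n_pop <- 200000
  path_freq <- if (moi == "dominant") rep(5e-4, n_path) else rep(0.012, n_path)
  ben_freq <- stats::runif(n_benign, 1e-4, 5e-4)
  freq <- c(path_freq, ben_freq)
  G <- vapply(freq, function(q) stats::rbinom(n_pop, 2, q), numeric(n_pop))
  path <- rowSums(G[, seq_len(n_path), drop = FALSE])
  config <- if (moi == "dominant") path >= 1 else path >= 2
  aff <- stats::rbinom(n_pop, 1, ifelse(config, penetrance, phenocopy)) == 1
  case_idx <- sample(which(aff), n_cases)
  ctrl_idx <- sample(which(!aff), n_controls)
  idx <- c(case_idx, ctrl_idx)
  list(G = G[idx, , drop = FALSE],
       y = c(rep(1, n_cases), rep(0, n_controls)),
       path_cols = seq_len(n_path))
}

# Genotype matrix -> the seven-model comparison on one gene where all
# variants belong to the given consequence class.
ppa_for_matrix <- function(G, y, variant_class = "high", seed = 1,
                           max_enumeration = 12, mc_draws = 3000) {
  specs <- default_model_specs()
  ev <- numeric(nrow(specs))
  for (m in seq_len(nrow(specs))) {
    spec <- specs[m]
    if (spec$kind == "baseline") {
      ev[m] <- baseline_evidence(y)
      next
    }
    Gm <- if (spec$variant_class == variant_class) G
          else G[, 0, drop = FALSE]
    ev[m] <- model_evidence(Gm, y, moi = spec$moi,
                            path_prior = c(spec$path_a, spec$path_b),
                            max_enumeration = max_enumeration,
                            mc_draws = mc_draws, seed = seed + m)$log_evidence
  }
  compute_ppa(ev, specs)
}

# Balanced three-level toy ontology for phenotype tests.
toy_dag <- function() {
  terms <- c("root", paste0("mid", 1:3), paste0("leaf", 1:9))
  parents <- c(list(root = character(0)),
               stats::setNames(rep(list("root"), 3), paste0("mid", 1:3)),
               stats::setNames(as.list(paste0("mid", rep(1:3, each = 3))),
                               paste0("leaf", 1:9)))
  ontology_dag(terms, parents)
}

random_family_annotations <- function(n_families, seed = 1, dag = toy_dag()) {
  set.seed(seed)
  leaves <- grep("^leaf", dag$terms, value = TRUE)
  data.table::rbindlist(lapply(seq_len(n_families), function(i) {
    data.table::data.table(family_id = sprintf("F%03d", i),
                           term_id = sample(leaves, sample(2:4, 1)))
  }))
}
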