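small_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_samples = 50, n_true_sites = 2000, n_artifact_sites = 2000,
         genome_length = 1e6, seed = seed),
    list(...))
  do.call(cohort_sim_config, args)
}

test_that("truth simulation is deterministic and respects class counts", {
  cfg <- small_cfg()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  expect_equal(sum(t1$class == "true"), 2000)
  expect_equal(sum(t1$class == "artifact"), 2000)
  expect_false(any(duplicated(t1$pos)))
  expect_true(all(is.na(t1$ac[t1$class == "artifact"])))
  expect_true(all(t1$ac[t1$class == "true"] >= 1))
  # no artifacts requested -> all sites true
  t0 <- simulate_truth(small_cfg(n_artifact_sites = 0))
  expect_true(all(t0$class == "true"))
  # genome capacity is enforced
  expect_error(simulate_truth(cohort_sim_config(
    n_true_sites = 100, n_artifact_sites = 100, genome_length = 150, seed = 1)),
    "capacity")
})

test_that("simulated Ti/Tv tracks the configured class mixture", {
  cfg <- cohort_sim_config(n_samples = 50, n_true_sites = 2e4,
                           n_artifact_sites = 2e4, genome_length = 1e7, seed = 5)
  truth <- simulate_truth(cfg)
  true_cs <- callset(truth[truth$class == "true", c("chrom", "pos", "ref", "alt")], "t")
  art_cs <- callset(truth[truth$class == "artifact", c("chrom", "pos", "ref", "alt")], "a")
  # transition probability 2.1/3.1 (resp. 0.5/1.5); 3 sigma at n = 2e4
  expect_equal(titv(true_cs), 2.1, tolerance = 0.05)
  expect_equal(titv(art_cs), 0.5, tolerance = 0.05)
})

test_that("callset simulation obeys the caller operating characteristics", {
  cfg <- small_cfg()
  truth <- simulate_truth(cfg)
  perfect <- caller_profile("perfect", 1, 0)
  blind <- caller_profile("blind", 0, 0.5)
  css <- simulate_callsets(truth, list(perfect, blind), seed = 9)
  true_keys <- with(truth[truth$class == "true", ],
                    paste(chrom, pos, ref, alt, sep = ":"))
  pk <- paste(css$perfect$chrom, css$perfect$pos, css$perfect$ref,
              css$perfect$alt, sep = ":")
  expect_setequal(pk, true_keys)            # sensitivity 1, artifact 0
  bk <- paste(css$blind$chrom, css$blind$pos, css$blind$ref,
              css$blind$alt, sep = ":")
  expect_length(intersect(bk, true_keys), 0)  # sensitivity 0

  # empirical recall within 3 sigma binomial error
  mid <- simulate_callsets(truth, list(caller_profile("m", 0.7, 0.2)), 11)$m
  rec <- sens_vs_truth(mid, truth)
  expect_lt(abs(rec - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
  expect_gt(fdr_vs_truth(mid, truth), 0)  # artifact pool leaks into the callset

  # allele-count-dependent sensitivity overrides the flat rate
  acs <- simulate_callsets(truth, list(caller_profile(
    "ac", 0.5, 0, ac_sensitivity = function(ac) ifelse(ac >= 3, 1, 0))), 13)$ac
  keys <- paste(acs$chrom, acs$pos, acs$ref, acs$alt, sep = ":")
  hi <- with(truth[truth$class == "true" & truth$ac >= 3, ],
             paste(chrom, pos, ref, alt, sep = ":"))
  expect_setequal(keys, hi)
})

test_that("genotype simulation reproduces the planted error structure", {
  cfg <- cohort_sim_config(n_samples = 40, n_true_sites = 400,
                           n_artifact_sites = 100, genome_length = 1e6,
                           gold_fraction = 0.5, missing_rate = 0,
                           gold_missing_rate = 0, genotype_error = 0, seed = 17)
  truth <- simulate_truth(cfg)
  sim <- simulate_genotypes(truth, cfg)
  # error-free, complete data: perfect concordance in every observed class
  conc <- genotype_concordance(sim$test, sim$gold$genotypes)
  expect_equal(unname(conc[!is.na(conc)]),
               rep(1, sum(!is.na(conc))))
  # artifact sites enter the gold standard as monomorphic negatives
  expect_true(all(truth$pos[truth$class == "artifact"] %in% sim$gold$negatives$pos))

  # planted genotype error 0.2: per-class concordance ~0.8
  cfg_e <- cohort_sim_config(n_samples = 60, n_true_sites = 800,
                             n_artifact_sites = 0, genome_length = 1e6,
                             gold_fraction = 0.5, missing_rate = 0,
                             gold_missing_rate = 0, genotype_error = 0.2, seed = 19)
  sim_e <- simulate_genotypes(simulate_truth(cfg_e), cfg_e)
  conc_e <- genotype_concordance(sim_e$test, sim_e$gold$genotypes)
  n_het <- sum(sim_e$gold$genotypes == 1, na.rm = TRUE)
  expect_lt(abs(conc_e[["RefAlt"]] - 0.8), 3 * sqrt(0.2 * 0.8 / n_het))

  # total missingness: concordance undefined
  cfg_m <- cohort_sim_config(n_samples = 10, n_true_sites = 50,
                             n_artifact_sites = 0, genome_length = 1e4,
                             gold_fraction = 0.5, missing_rate = 1,
                             gold_missing_rate = 0, genotype_error = 0, seed = 23)
  sim_m <- simulate_genotypes(simulate_truth(cfg_m), cfg_m)
  expect_warning(genotype_concordance(sim_m$test, sim_m$gold$genotypes),
                 "missing|shared")
})

test_that("Poisson-binomial tail matches closed forms and brute force", {
  # uniform p: tail equals the binomial closed form
  expect_equal(poisbinom_at_least(rep(0.9, 4), 3),
               4 * 0.9^3 * 0.1 + 0.9^4)
  expect_equal(poisbinom_at_least(rep(0.1, 4), 3),
               4 * 0.1^3 * 0.9 + 0.1^4)
  # k = 1 complement identity
  p <- c(0.3, 0.7, 0.5)
  expect_equal(poisbinom_at_least(p, 1), 1 - prod(1 - p))
  expect_equal(poisbinom_at_least(p, 0), 1)
  # brute-force enumeration over all outcome vectors
  set.seed(41)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    p <- runif(n)
    k <- sample(0:n, 1)
    outcomes <- expand.grid(rep(list(0:1), n))
    probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
    expect_equal(poisbinom_at_least(p, k),
                 sum(probs[rowSums(outcomes) >= k]))
  }
  expect_error(poisbinom_at_least(c(0.5, 1.2), 1), "\\[0, 1\\]")
})

test_that("expected consensus is monotone in k and matches simulation", {
  set.seed(43)
  for (i in 1:10) {
    profiles <- lapply(1:4, function(j)
      caller_profile(paste0("c", j), runif(1, 0.3, 0.95), runif(1, 0.01, 0.4)))
    tab <- expected_consensus_table(profiles)
    expect_true(all(diff(tab$sensitivity) <= 0))
    expect_true(all(diff(tab$artifact_pass) <= 0))
  }
  # simulation agreement at moderate n, all k
  cfg <- cohort_sim_config(n_samples = 50, n_true_sites = 2e4,
                           n_artifact_sites = 2e4, genome_length = 1e7, seed = 47)
  truth <- simulate_truth(cfg)
  profiles <- lapply(1:4, function(j)
    caller_profile(paste0("c", j), c(0.9, 0.7, 0.6, 0.8)[j],
                   c(0.1, 0.25, 0.05, 0.15)[j]))
  css <- simulate_callsets(truth, profiles, cfg$seed + 1L)
  cons <- tally(css)
  for (k in 1:4) {
    kept <- consensus_threshold(cons, k)
    ec <- expected_consensus(profiles, k, 2e4, 2e4)
    sens <- sens_vs_truth(kept, truth)
    expect_lt(abs(sens - ec$sensitivity),
              3 * sqrt(ec$sensitivity * (1 - ec$sensitivity) / 2e4) + 1e-9)
    keys <- paste(kept$chrom, kept$pos, kept$ref, kept$alt, sep = ":")
    art_keys <- with(truth[truth$class == "artifact", ],
                     paste(chrom, pos, ref, alt, sep = ":"))
    pass <- mean(art_keys %in% keys)
    expect_lt(abs(pass - ec$artifact_pass),
              3 * sqrt(ec$artifact_pass * (1 - ec$artifact_pass) / 2e4) + 1e-9)
  }
})

test_that("simulate_cohort is byte-deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 53)
  profiles <- list(caller_profile("a", 0.8, 0.1), caller_profile("b", 0.6, 0.2))
  s1 <- simulate_cohort(cfg, profiles, genotypes = TRUE)
  s2 <- simulate_cohort(cfg, profiles, genotypes = TRUE)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$callsets, s2$callsets)
  expect_identical(unclass(s1$test), unclass(s2$test))
})
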