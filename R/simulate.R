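#' Define a caller's operating characteristics
#'
#' A caller is summarised by two site-level probabilities: the chance it
#' reports a genuine variant site (`sensitivity`, optionally a
#' non-decreasing function of the site's cohort allele count) and the
#' chance it reports a site from the shared artifact pool
#' (`artifact_rate`). Callers act independently given site class; their
#' apparent correlation on false positives comes entirely from sharing the
#' artifact pool.
#'
#' @param caller_id Caller label.
#' @param sensitivity Probability in `[0, 1]` that a true site is called.
#' @param artifact_rate Probability in `[0, 1]` that an artifact-pool site
#'   is called.
#' @param ac_sensitivity Optional function `f(ac) -> probability`
#'   overriding the flat `sensitivity` with an allele-count-dependent one.
#' @return A `caller_profile` list.
#' @export
caller_profile <- function(caller_id, sensitivity, artifact_rate,
                           ac_sensitivity = NULL) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            artifact_rate >= 0, artifact_rate <= 1)
  if (!is.null(ac_sensitivity)) stopifnot(is.function(ac_sensitivity))
  structure(list(caller_id = caller_id, sensitivity = sensitivity,
                 artifact_rate = artifact_rate,
                 ac_sensitivity = ac_sensitivity),
            class = "caller_profile")
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic multi-caller cohort. Defaults emulate the
#' structure of a large low-coverage WGS cohort: 5297 samples of which a
#' deep-assayed subset (fraction 4612/5297) forms the gold standard; true
#' variants with the genome-wide transition/transversion ratio of real
#' human variation (2.1) and a neutral 1/i allele-frequency spectrum;
#' artifact sites with the Ti/Tv of random noise (0.5). Site counts default
#' to 1e5 + 1e5, a desk-scale population for the consensus experiments.
#'
#' @param n_samples Cohort size (default 5297).
#' @param n_true_sites,n_artifact_sites Sizes of the true-variant and
#'   shared artifact-site pools (defaults 1e5 each).
#' @param titv_true,titv_artifact Expected Ti/Tv of each pool
#'   (defaults 2.1 and 0.5).
#' @param ac_cap Truncation of the 1/i allele-count spectrum (default
#'   `2 * n_samples - 1`, i.e. untruncated for polymorphic non-fixed sites).
#' @param gold_fraction Fraction of samples in the gold subset
#'   (default 4612/5297).
#' @param missing_rate Per-cell missingness of the test genotypes
#'   (default 0.02).
#' @param gold_missing_rate Per-cell missingness of the gold genotypes
#'   (default 0.01) — exercises the negative-site missingness filter.
#' @param genotype_error Per-cell probability that a test genotype is
#'   perturbed to a different dosage (default 0.05).
#' @param genome_length Length in bp of the synthetic chromosome sites are
#'   placed on (default 2.5e8).
#' @param chrom Name of the synthetic chromosome (default `"chrS"`).
#' @param seed Integer seed fixing the full simulation stream (mandatory).
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_samples = 5297,
                              n_true_sites = 1e5, n_artifact_sites = 1e5,
                              titv_true = 2.1, titv_artifact = 0.5,
                              ac_cap = NULL,
                              gold_fraction = 4612 / 5297,
                              missing_rate = 0.02,
                              gold_missing_rate = 0.01,
                              genotype_error = 0.05,
                              genome_length = 2.5e8,
                              chrom = "chrS",
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(ac_cap)) ac_cap <- 2 * n_samples - 1
  cfg <- list(n_samples = n_samples, n_true_sites = n_true_sites,
              n_artifact_sites = n_artifact_sites,
              titv_true = titv_true, titv_artifact = titv_artifact,
              ac_cap = ac_cap, gold_fraction = gold_fraction,
              missing_rate = missing_rate,
              gold_missing_rate = gold_missing_rate,
              genotype_error = genotype_error,
              genome_length = genome_length, chrom = chrom,
              seed = as.integer(seed))
  fracs <- unlist(cfg[c("gold_fraction", "missing_rate",
                        "gold_missing_rate", "genotype_error")])
  if (any(fracs < 0 | fracs > 1))
    stop("rates and fractions must be in [0, 1]")
  if (cfg$n_true_sites < 0 || cfg$n_artifact_sites < 0)
    stop("site counts must be >= 0")
  structure(cfg, class = "cohort_sim_config")
}

# draw ref/alt pairs with the requested expected Ti/Tv: a site is a
# transition with probability titv/(1 + titv)
draw_alleles <- function(n, titv) {
  ref <- sample(BASES, n, replace = TRUE)
  is_ti <- stats::runif(n) < titv / (1 + titv)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), C = c("A", "G"),
                      G = c("C", "T"), T = c("A", "G"))
  alt <- character(n)
  alt[is_ti] <- ti_partner[ref[is_ti]]
  if (any(!is_ti)) {
    pick <- stats::runif(sum(!is_ti)) < 0.5
    opts <- do.call(rbind, tv_partners[ref[!is_ti]])
    alt[!is_ti] <- ifelse(pick, opts[, 1], opts[, 2])
  }
  list(ref = ref, alt = alt)
}

#' Simulate the true-site universe
#'
#' Places `n_true_sites` genuine variants and `n_artifact_sites` artifact
#' sites at distinct positions on a synthetic chromosome. Alleles are drawn
#' so the expected Ti/Tv of each class matches its configured value; true
#' sites receive an allele count from the truncated neutral spectrum
#' (P(AC = i) proportional to 1/i over `1..ac_cap`); artifact sites carry no
#' allele count (`NA`) — they are not variants.
#'
#' @param config A [cohort_sim_config()].
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `class`
#'   (`"true"`/`"artifact"`), `ac`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n_total <- config$n_true_sites + config$n_artifact_sites
  if (n_total > config$genome_length)
    stop("site count exceeds genome capacity (", config$genome_length, " bp)")
  set.seed(config$seed)
  pos <- sort(sample.int(config$genome_length, n_total))
  cls <- sample(rep(c("true", "artifact"),
                    c(config$n_true_sites, config$n_artifact_sites)))
  ref <- character(n_total); alt <- character(n_total)
  tr <- cls == "true"
  if (any(tr)) {
    al <- draw_alleles(sum(tr), config$titv_true)
    ref[tr] <- al$ref; alt[tr] <- al$alt
  }
  if (any(!tr)) {
    al <- draw_alleles(sum(!tr), config$titv_artifact)
    ref[!tr] <- al$ref; alt[!tr] <- al$alt
  }
  ac <- rep(NA_integer_, n_total)
  if (any(tr)) {
    i <- seq_len(config$ac_cap)
    ac[tr] <- sample(i, sum(tr), replace = TRUE, prob = 1 / i)
  }
  data.frame(chrom = config$chrom, pos = pos, ref = ref, alt = alt,
             class = cls, ac = ac, stringsAsFactors = FALSE)
}

#' Simulate per-caller callsets over a truth table
#'
#' Each caller reports each true site with its (possibly allele-count
#' dependent) sensitivity and each artifact site with its artifact rate,
#' independently across callers given the site class.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param profiles List of [caller_profile()] objects.
#' @param seed Integer seed for the detection draws.
#' @return Named list of [callset()] objects, one per profile.
#' @export
simulate_callsets <- function(truth, profiles, seed) {
  if (length(profiles) < 1) stop("need at least one caller profile")
  set.seed(as.integer(seed))
  tr <- truth$class == "true"
  out <- lapply(profiles, function(pr) {
    p <- numeric(nrow(truth))
    p[!tr] <- pr$artifact_rate
    p[tr] <- if (is.null(pr$ac_sensitivity)) pr$sensitivity
             else pr$ac_sensitivity(truth$ac[tr])
    hit <- stats::runif(nrow(truth)) < p
    callset(truth[hit, c("chrom", "pos", "ref", "alt")], pr$caller_id)
  })
  names(out) <- vapply(profiles, function(pr) pr$caller_id, character(1))
  out
}

#' Simulate test genotypes and a gold standard
#'
#' True-site genotypes are drawn per sample under Hardy-Weinberg
#' equilibrium at allele frequency `AC / (2 N)`. The test matrix is the
#' cohort-wide genotypes perturbed by `genotype_error` (a wrong dosage,
#' uniform over the other two values) and masked by `missing_rate`. The
#' gold standard covers the gold subset of samples with error-free
#' genotypes at every true site plus the artifact sites as assayed
#' monomorphic-reference negatives; gold cells are masked at
#' `gold_missing_rate`.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param config The [cohort_sim_config()] used to build it.
#' @return list with `test` (a [genotype_matrix()] over all samples at true
#'   sites) and `gold` (a [gold_standard()] over the gold subset at all
#'   truth sites).
#' @export
simulate_genotypes <- function(truth, config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed + 2L)
  N <- config$n_samples
  samples <- sprintf("S%04d", seq_len(N))
  tr <- truth$class == "true"
  true_sites <- truth[tr, c("chrom", "pos", "ref", "alt")]
  n_t <- nrow(true_sites)

  af <- truth$ac[tr] / (2 * N)
  geno <- matrix(stats::rbinom(n_t * N, 2, rep(af, N)), nrow = n_t, ncol = N)

  n_gold <- round(config$gold_fraction * N)
  gold_samples <- samples[seq_len(n_gold)]

  # gold: error-free true-site genotypes on the gold subset, plus artifact
  # sites as assayed monomorphic negatives, with gold-side missingness
  art_sites <- truth[!tr, c("chrom", "pos", "ref", "alt")]
  gold_geno <- rbind(geno[, seq_len(n_gold), drop = FALSE],
                     matrix(0L, nrow = nrow(art_sites), ncol = n_gold))
  if (config$gold_missing_rate > 0)
    gold_geno[stats::runif(length(gold_geno)) < config$gold_missing_rate] <- NA_integer_
  gold_gm <- genotype_matrix(gold_geno, rbind(true_sites, art_sites), gold_samples)

  # test: full cohort at true sites, with genotype error then missingness
  test_geno <- geno
  if (config$genotype_error > 0) {
    err <- which(stats::runif(length(test_geno)) < config$genotype_error)
    if (length(err) > 0) {
      cur <- test_geno[err]
      shift <- 1L + (stats::runif(length(err)) < 0.5)  # +1 or +2 mod 3
      test_geno[err] <- (cur + shift) %% 3L
    }
  }
  if (config$missing_rate > 0)
    test_geno[stats::runif(length(test_geno)) < config$missing_rate] <- NA_integer_
  test_gm <- genotype_matrix(test_geno, true_sites, samples)

  list(test = test_gm, gold = gold_standard(gold_gm))
}

#' Run a full cohort simulation
#'
#' Convenience wrapper: truth, per-caller callsets (seeded at
#' `config$seed + 1`), and optionally genotypes + gold standard.
#'
#' @param config A [cohort_sim_config()].
#' @param profiles List of [caller_profile()] objects.
#' @param genotypes Simulate genotype matrices too? (default FALSE; the
#'   site-level experiments do not need them).
#' @return list with `truth`, `callsets`, and when requested `test` and
#'   `gold`.
#' @export
simulate_cohort <- function(config, profiles, genotypes = FALSE) {
  truth <- simulate_truth(config)
  callsets <- simulate_callsets(truth, profiles, config$seed + 1L)
  out <- list(truth = truth, callsets = callsets)
  if (genotypes) out <- c(out, simulate_genotypes(truth, config))
  out
}
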