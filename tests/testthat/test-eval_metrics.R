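# small hand-built gold standard: 4 polymorphic sites p1..p4, 2 monomorphic
# negatives n1, n2, two gold samples, no missingness
toy_gold <- function() {
  sites <- data.frame(chrom = "c1", pos = c(10, 20, 30, 40, 100, 110),
                      ref = "A", alt = "G")
  geno <- rbind(c(1L, 0L), c(2L, 1L), c(0L, 1L), c(1L, 1L),  # positives
                c(0L, 0L), c(0L, 0L))                        # negatives
  gold_standard(genotype_matrix(geno, sites, c("g1", "g2")))
}

toy_callset <- function(pos) {
  n <- length(pos)
  callset(data.frame(chrom = rep("c1", n), pos = pos,
                     ref = rep("A", n), alt = rep("G", n)), "test")
}

test_that("gold positives/negatives derive from assayed genotypes", {
  g <- toy_gold()
  expect_equal(g$positives$pos, c(10, 20, 30, 40))
  expect_equal(g$negatives$pos, c(100, 110))
})

test_that("gold filters remove missing negatives and high-missing test sites", {
  sites <- data.frame(chrom = "c1", pos = c(10, 100, 110), ref = "A", alt = "G")
  geno <- rbind(c(1L, 0L), c(0L, NA), c(0L, 0L))
  g <- gold_standard(genotype_matrix(geno, sites, c("g1", "g2")))
  gf <- apply_gold_filters(g)
  # negative with a missing gold genotype is removed from the negatives
  expect_equal(gf$negatives$pos, 110)
  expect_equal(gf$positives$pos, 10)

  # test-side missingness > threshold removes the site from the
  # sensitivity universe
  tm <- c("c1:10:A:G" = 0.06)
  gf2 <- apply_gold_filters(g, test_missing = tm, threshold = 0.05)
  expect_equal(nrow(gf2$positives), 0)
  # exactly at the threshold is kept (the rule is strictly greater than)
  gf3 <- apply_gold_filters(g, test_missing = c("c1:10:A:G" = 0.05))
  expect_equal(gf3$positives$pos, 10)

  # threshold 1 with complete gold is the identity
  gi <- apply_gold_filters(toy_gold(), threshold = 1)
  expect_equal(gi$positives$pos, toy_gold()$positives$pos)
  expect_equal(gi$negatives$pos, toy_gold()$negatives$pos)
})

test_that("confusion counts and metrics match hand computation", {
  g <- apply_gold_filters(toy_gold())
  # callset {p1, p2, n1}
  r <- confusion(toy_callset(c(10, 20, 100)), g)
  expect_equal(r$tp, 2); expect_equal(r$fn, 2)
  expect_equal(r$fp, 1); expect_equal(r$tn, 1)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$fdr, 1 / 3)
  expect_equal(r$specificity, 0.5)

  # perfect recovery
  rp <- confusion(toy_callset(c(10, 20, 30, 40)), g)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$fdr, 0)
  expect_equal(rp$specificity, 1)

  # sites outside the assayed universe are ignored, not false positives
  rn <- confusion(toy_callset(c(10, 20, 30, 40, 9999)), g)
  expect_equal(rn$fp, 0)

  # empty callset: sensitivity 0, specificity 1, FDR 0 by convention
  expect_warning(re <- confusion(toy_callset(numeric()), g), "convention")
  expect_equal(re$sensitivity, 0)
  expect_equal(re$specificity, 1)
  expect_equal(re$fdr, 0)

  # conservation: tp + fn and fp + tn are the filtered universe sizes
  set.seed(3)
  for (i in 1:10) {
    r <- confusion(toy_callset(sample(c(10, 20, 30, 40, 100, 110),
                                      sample(0:6, 1))), g)
    expect_equal(r$tp + r$fn, 4)
    expect_equal(r$fp + r$tn, 2)
  }
})

test_that("no gold positives yields NA sensitivity with a warning", {
  sites <- data.frame(chrom = "c1", pos = 100, ref = "A", alt = "G")
  g <- apply_gold_filters(gold_standard(
    genotype_matrix(matrix(0L, 1, 2), sites, c("g1", "g2"))))
  # both the sensitivity and the empty-callset FDR conventions warn
  expect_warning(expect_warning(r <- confusion(toy_callset(numeric()), g),
                                "undefined"), "convention")
  expect_true(is.na(r$sensitivity))
})

test_that("Ti/Tv counts transitions over transversions", {
  cs <- callset(data.frame(chrom = "c1", pos = 1:3,
                           ref = c("A", "C", "A"), alt = c("G", "T", "C")), "x")
  expect_equal(titv(cs), 2)
  allti <- callset(data.frame(chrom = "c1", pos = 1:2,
                              ref = c("A", "C"), alt = c("G", "T")), "x")
  expect_warning(expect_equal(titv(allti), Inf), "transversion")
  expect_warning(expect_true(is.na(titv(toy_callset(numeric())))), "empty")

  # uniformly random ref->alt pairs: 4 transition vs 8 transversion ordered
  # pairs, so Ti/Tv converges to 0.5
  set.seed(9)
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  draw <- pairs[sample(nrow(pairs), 4000, replace = TRUE), ]
  draw$chrom <- "c1"; draw$pos <- seq_len(nrow(draw))
  expect_equal(titv(callset(draw, "rand")), 0.5, tolerance = 0.15)
})

test_that("known-set overlap fraction honours allele vs position matching", {
  cs <- toy_callset(c(10, 20))
  known_same <- toy_callset(c(10, 20, 30))
  expect_equal(pct_known(cs, known_same), 1)
  disjoint <- toy_callset(c(500, 600))
  expect_equal(pct_known(cs, disjoint), 0)
  # half-overlap by construction
  half <- toy_callset(c(10, 999))
  expect_equal(pct_known(half, known_same), 0.5)
  # same position, different alt: position matching accepts, allele rejects
  other_alt <- callset(data.frame(chrom = "c1", pos = 10, ref = "A", alt = "T"), "k")
  expect_equal(pct_known(other_alt, known_same, match = "allele"), 0)
  expect_equal(pct_known(other_alt, known_same, match = "position"), 1)
  expect_warning(pct_known(toy_callset(numeric()), known_same), "empty")
})

test_that("genotype concordance stratifies by gold class", {
  sites <- data.frame(chrom = "c1", pos = c(1, 2, 3, 4), ref = "A", alt = "G")
  gold <- genotype_matrix(matrix(1L, 4, 1), sites, "s1")       # four het cells
  test <- genotype_matrix(matrix(c(1L, 1L, 0L, 2L), 4, 1), sites, "s1")
  conc <- genotype_concordance(test, gold)
  expect_equal(conc[["RefAlt"]], 0.5)
  expect_true(is.na(conc[["RefRef"]]))     # no gold hom-ref cells

  # perfect agreement across all three classes
  g2 <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1),
                        sites[1:3, ], "s1")
  expect_equal(unname(genotype_concordance(g2, g2)), c(1, 1, 1))

  # all test cells missing -> undefined with warning
  gm_na <- genotype_matrix(matrix(NA_integer_, 4, 1), sites, "s1")
  expect_warning(cna <- genotype_concordance(gm_na, gold), "missing")
  expect_true(all(is.na(cna)))
  # nothing shared -> undefined with warning
  other <- genotype_matrix(matrix(1L, 1, 1),
                           data.frame(chrom = "c9", pos = 1, ref = "A", alt = "G"),
                           "sX")
  expect_warning(genotype_concordance(other, gold), "shared")
})

test_that("AC-stratified sensitivity uses gold dosage sums", {
  # 10 samples; site ACs: 1 (singleton), 2, 5 (3 hets + 1 hom-alt), 8
  geno <- matrix(0L, 4, 10)
  geno[1, 1] <- 1L
  geno[2, 1:2] <- 1L
  geno[3, 1:3] <- 1L; geno[3, 4] <- 2L
  geno[4, 1:4] <- 2L
  sites <- data.frame(chrom = "c1", pos = c(10, 20, 30, 40), ref = "A", alt = "G")
  g <- apply_gold_filters(gold_standard(genotype_matrix(geno, sites)))
  expect_equal(rowSums(g$genotypes)[3], c(`c1:30:A:G` = 5))

  # called: the singleton missed, the doubleton and both common sites hit
  ac <- sensitivity_by_ac(toy_callset(c(20, 30, 40)), g, breaks = c(1, 2, 3))
  expect_equal(ac$sensitivity, c(0, 1, 1))
  expect_equal(ac$n_gold, c(1L, 1L, 2L))
  # callset = positives -> sensitivity 1 in every non-empty bin
  full <- sensitivity_by_ac(toy_callset(c(10, 20, 30, 40)), g, breaks = c(1, 2, 3))
  expect_equal(full$sensitivity, c(1, 1, 1))
  # empty bin reported NA
  sp <- sensitivity_by_ac(toy_callset(10), g, breaks = c(1, 2, 3, 6, 100))
  expect_true(is.na(sp$sensitivity[sp$bin == "100+"]))
})

test_that("evaluate_callset bundles the full report and writes TSV", {
  g <- toy_gold()
  cs <- toy_callset(c(10, 20, 100))
  # the all-transition toy callset flags its infinite Ti/Tv
  expect_warning(
    rep <- evaluate_callset(cs, g, known = list(k1 = toy_callset(c(10, 999)))),
    "transversion")
  expect_equal(rep$n_snvs, 3)
  expect_equal(rep$fdr, 1 / 3)
  expect_equal(unname(rep$pct_known["k1"]), 1 / 3)
  path <- tempfile(fileext = ".tsv")
  write_eval_report(rep, path)
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(as.numeric(tab$value[tab$metric == "fdr"]), 1 / 3, tolerance = 1e-10)
  expect_true("sensitivity:AC1" %in% tab$metric)
})
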