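#' Build a gold standard from assayed genotypes
#'
#' A gold standard is a set of independently assayed sites with
#' high-confidence genotypes (deep exome sequencing or a genotyping array)
#' over a subset of the cohort. Positive sites are those polymorphic in the
#' gold genotypes (at least one non-reference allele); negative sites are
#' assayed but monomorphic reference. Sites outside the assayed footprint
#' are unlabeled — callset sites there are neither true nor false
#' positives.
#'
#' @param genotypes A [genotype_matrix()] of gold genotypes (all assayed
#'   sites x gold samples).
#' @return A `gold_standard`: list with `genotypes`, `positives` and
#'   `negatives` (site-key data.frames), and a `filtered` flag.
#' @export
gold_standard <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ac <- rowSums(genotypes, na.rm = TRUE)
  sites <- gm_sites(genotypes)
  structure(list(genotypes = genotypes,
                 positives = sites[ac >= 1, , drop = FALSE],
                 negatives = sites[ac == 0, , drop = FALSE],
                 filtered = FALSE),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard:", nrow(x$positives), "positive /", nrow(x$negatives),
      "negative site(s) over", ncol(x$genotypes), "sample(s)",
      if (x$filtered) "(filtered)" else "(unfiltered)", "\n")
  invisible(x)
}

gold_keys <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Apply the gold-standard filtering rules
#'
#' Two rules precede any metric: (1) negative (monomorphic reference) sites
#' with any missing gold genotype are removed — an uncalled gold cell could
#' hide a real variant; (2) sites whose *test-side* missingness exceeds
#' `threshold` are removed from the sensitivity universe (the positives),
#' since sensitivity at a site the test barely genotyped is not
#' interpretable. The default threshold is 5 % missing genotypes.
#'
#' @param gold A [gold_standard()].
#' @param test_missing Per-site missing fraction on the test side: a named
#'   numeric vector keyed by `"chrom:pos:ref:alt"`, or a
#'   [genotype_matrix()] from which row-wise missingness is computed.
#'   `NULL` skips rule (2).
#' @param threshold Missingness cutoff in `[0, 1]` (default 0.05).
#' @return The filtered `gold_standard`.
#' @export
apply_gold_filters <- function(gold, test_missing = NULL, threshold = 0.05) {
  stopifnot(inherits(gold, "gold_standard"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")

  # rule 1: drop negatives with missing gold genotypes
  neg_keys <- gold_keys(gold$negatives)
  n_missing <- rowSums(is.na(gold$genotypes))
  miss_by_key <- n_missing[match(neg_keys, rownames(gold$genotypes))]
  gold$negatives <- gold$negatives[miss_by_key == 0, , drop = FALSE]

  # rule 2: drop high-missingness test sites from the sensitivity universe
  if (!is.null(test_missing)) {
    if (inherits(test_missing, "genotype_matrix"))
      test_missing <- stats::setNames(rowMeans(is.na(test_missing)),
                                      rownames(test_missing))
    pos_keys <- gold_keys(gold$positives)
    frac <- test_missing[pos_keys]
    drop <- !is.na(frac) & frac > threshold
    gold$positives <- gold$positives[!drop, , drop = FALSE]
  }
  gold$filtered <- TRUE
  gold
}

#' Confusion counts and headline metrics against a gold standard
#'
#' Intersects a callset with the filtered gold positives and negatives:
#' `tp` = called positives, `fn` = missed positives, `fp` = called
#' negatives, `tn` = uncalled negatives. Callset sites outside the assayed
#' universe are ignored, not penalised. Sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, FDR `fp/(fp+tp)`. With no positives,
#' sensitivity is `NA` with a warning; an empty callset reports FDR 0 by
#' convention, with a warning.
#'
#' @param x A [callset()].
#' @param gold A filtered [gold_standard()].
#' @return An `eval_report` list: counts `tp`, `fp`, `fn`, `tn` and
#'   fractions `sensitivity`, `specificity`, `fdr`.
#' @export
confusion <- function(x, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  if (!gold$filtered)
    warning("gold standard has not been filtered; call apply_gold_filters()")
  called <- site_keys(x)
  pos <- gold_keys(gold$positives)
  neg <- gold_keys(gold$negatives)
  tp <- sum(pos %in% called); fn <- length(pos) - tp
  fp <- sum(neg %in% called); tn <- length(neg) - fp

  sens <- if (tp + fn == 0) {
    warning("no gold positives: sensitivity undefined"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  fdr <- if (tp + fp == 0) {
    warning("empty callset intersection: FDR reported as 0 by convention"); 0
  } else fp / (fp + tp)

  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec, fdr = fdr),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  FDR %.4f\n",
              x$sensitivity, x$specificity, x$fdr))
  invisible(x)
}

#' Transition/transversion ratio of a callset
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (A<->G, C<->T); all other ref->alt pairs are transversions. Real human
#' variation sits near 2.0-2.1 genome-wide; random artifacts near 0.5
#' (4 transition vs 8 transversion ordered pairs), so Ti/Tv is a cheap
#' callset quality signal.
#'
#' @param x A [callset()].
#' @return Transitions / transversions; `Inf` with a warning when there are
#'   no transversions, `NA` with a warning on an empty callset.
#' @export
titv <- function(x) {
  if (nrow(x) == 0) {
    warning("empty callset: Ti/Tv undefined")
    return(NA_real_)
  }
  ti <- is_transition(x$ref, x$alt)
  n_tv <- sum(!ti)
  if (n_tv == 0) {
    warning("no transversions: Ti/Tv is infinite")
    return(Inf)
  }
  sum(ti) / n_tv
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Fraction of a callset present in a known-sites list
#'
#' Overlap with a catalogue of previously reported variants (a
#' 1000-Genomes- or dbSNP-style list). Matching is allele-aware by default,
#' consistent with site-key identity; position-only matching is available.
#'
#' @param x A [callset()].
#' @param known A [callset()] or data.frame of known sites.
#' @param match `"allele"` (chrom, pos, ref, alt) or `"position"`
#'   (chrom, pos).
#' @return Fraction of callset sites found in `known`; `NA` with a warning
#'   for an empty callset.
#' @export
pct_known <- function(x, known, match = c("allele", "position")) {
  match <- match.arg(match)
  if (nrow(x) == 0) {
    warning("empty callset: %-known undefined")
    return(NA_real_)
  }
  if (match == "allele") {
    mean(site_keys(x) %in% gold_keys(known))
  } else {
    mean(paste(x$chrom, x$pos) %in% paste(known$chrom, known$pos))
  }
}

#' Genotype concordance by gold genotype class
#'
#' Compares test and gold genotypes on their shared (site, sample) cells,
#' excluding cells missing on either side, and stratifies by the *gold*
#' genotype: hom-ref (0), het (1), hom-alt (2). Concordance per class is
#' the fraction of cells where the test genotype equals the gold genotype.
#'
#' @param test,gold [genotype_matrix()] objects; shared sites are matched
#'   by site key, shared samples by label.
#' @return Named numeric `c(RefRef, RefAlt, AltAlt)`; `NA` for a class with
#'   no comparable cells, all-`NA` with a warning when nothing is shared.
#' @export
genotype_concordance <- function(test, gold) {
  stopifnot(inherits(test, "genotype_matrix"), inherits(gold, "genotype_matrix"))
  sites <- intersect(rownames(test), rownames(gold))
  samples <- intersect(colnames(test), colnames(gold))
  out <- c(RefRef = NA_real_, RefAlt = NA_real_, AltAlt = NA_real_)
  if (length(sites) == 0 || length(samples) == 0) {
    warning("no shared (site, sample) cells: concordance undefined")
    return(out)
  }
  tv <- test[sites, samples, drop = FALSE]
  gv <- gold[sites, samples, drop = FALSE]
  ok <- !is.na(tv) & !is.na(gv)
  if (!any(ok)) {
    warning("all shared cells missing on one side: concordance undefined")
    return(out)
  }
  for (class in 0:2) {
    cells <- ok & gv == class
    cells[is.na(cells)] <- FALSE
    if (any(cells)) out[class + 1] <- mean(tv[cells] == gv[cells])
  }
  out
}

#' Allele-count-stratified sensitivity
#'
#' Sensitivity computed separately per gold allele-count (AC) bin. AC at a
#' site is the dosage sum over gold samples, so rare variants (singletons,
#' doubletons) get their own — typically much lower — recall estimate,
#' which is the regime where low-coverage calling struggles.
#'
#' @param x A [callset()].
#' @param gold A filtered [gold_standard()].
#' @param breaks Increasing integer lower bounds of the AC bins
#'   (default `c(1, 2, 3, 6)`: singletons, doubletons, AC 3-5, AC 6+).
#' @return data.frame with `bin`, `ac_min`, `ac_max`, `n_gold`, `n_called`,
#'   `sensitivity` (`NA` for empty bins).
#' @export
sensitivity_by_ac <- function(x, gold, breaks = c(1, 2, 3, 6)) {
  stopifnot(inherits(gold, "gold_standard"))
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] < 1)
    stop("breaks must be strictly increasing and start at >= 1")
  ac_all <- rowSums(gold$genotypes, na.rm = TRUE)
  pos_keys <- gold_keys(gold$positives)
  ac <- ac_all[match(pos_keys, rownames(gold$genotypes))]
  called <- pos_keys %in% site_keys(x)

  upper <- c(breaks[-1] - 1, Inf)
  labels <- ifelse(is.finite(upper) & upper == breaks, as.character(breaks),
                   ifelse(is.finite(upper), paste0(breaks, "-", upper),
                          paste0(breaks, "+")))
  bin <- findInterval(ac, breaks)
  out <- data.frame(bin = labels, ac_min = breaks, ac_max = upper,
                    n_gold = 0L, n_called = 0L, sensitivity = NA_real_,
                    stringsAsFactors = FALSE)
  for (b in seq_along(breaks)) {
    sel <- bin == b
    out$n_gold[b] <- sum(sel)
    out$n_called[b] <- sum(called[sel])
    if (out$n_gold[b] > 0) out$sensitivity[b] <- out$n_called[b] / out$n_gold[b]
  }
  out
}

#' Full evaluation of a callset against a gold standard
#'
#' One-stop wrapper: applies the gold filters, then computes the confusion
#' metrics, Ti/Tv, known-set overlap fractions, AC-stratified sensitivity,
#' and (when test genotypes are supplied) the genotype-concordance triple.
#'
#' @param x A [callset()].
#' @param gold A [gold_standard()] (unfiltered; filters are applied here).
#' @param known Named list of known-site callsets/data.frames.
#' @param test_genotypes Optional test-side [genotype_matrix()]; also feeds
#'   the test-missingness filter.
#' @param missing_threshold Test-missingness cutoff (default 0.05).
#' @param ac_breaks Passed to [sensitivity_by_ac()].
#' @return An `eval_report` extended with `n_snvs`, `titv`, `pct_known`
#'   (named vector), `ac_sensitivity` and `concordance`.
#' @export
evaluate_callset <- function(x, gold, known = list(), test_genotypes = NULL,
                             missing_threshold = 0.05, ac_breaks = c(1, 2, 3, 6)) {
  gold_f <- apply_gold_filters(gold, test_missing = test_genotypes,
                               threshold = missing_threshold)
  rep <- confusion(x, gold_f)
  rep$n_snvs <- nrow(x)
  rep$titv <- titv(x)
  rep$pct_known <- vapply(known, function(kn) pct_known(x, kn), numeric(1))
  rep$ac_sensitivity <- sensitivity_by_ac(x, gold_f, breaks = ac_breaks)
  rep$concordance <- if (!is.null(test_genotypes))
    genotype_concordance(test_genotypes, gold_f$genotypes)
  else c(RefRef = NA_real_, RefAlt = NA_real_, AltAlt = NA_real_)
  rep
}

#' Write an evaluation report as flat TSV
#'
#' @param report An `eval_report` from [evaluate_callset()] or [confusion()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  rows <- list(
    c("n_snvs", report$n_snvs %||% NA),
    c("tp", report$tp), c("fp", report$fp),
    c("fn", report$fn), c("tn", report$tn),
    c("sensitivity", report$sensitivity),
    c("specificity", report$specificity),
    c("fdr", report$fdr),
    c("titv", report$titv %||% NA))
  for (nm in names(report$pct_known))
    rows <- c(rows, list(c(paste0("pct_known:", nm), report$pct_known[[nm]])))
  for (nm in names(report$concordance))
    rows <- c(rows, list(c(paste0("concordance:", nm), report$concordance[[nm]])))
  if (!is.null(report$ac_sensitivity))
    for (i in seq_len(nrow(report$ac_sensitivity)))
      rows <- c(rows, list(c(paste0("sensitivity:AC", report$ac_sensitivity$bin[i]),
                             report$ac_sensitivity$sensitivity[i])))
  tab <- data.frame(metric = vapply(rows, `[`, "", 1),
                    value = vapply(rows, `[`, "", 2))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
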