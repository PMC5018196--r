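# fixture builders and independent oracles shared across test files

# write a minimal VCF from raw record fields (no validation on purpose,
# so malformed/indel/multi-allelic records can be planted)
write_test_vcf <- function(path, chrom, pos, ref, alt, info = ".") {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(chrom, pos, ".", ref, alt, ".", ".", info, sep = "\t")
  writeLines(c(header, body), path)
  path
}

random_callset <- function(universe, caller, p = 0.5) {
  keep <- runif(nrow(universe)) < p
  callset(universe[keep, , drop = FALSE], caller)
}

site_universe <- function(n, chrom = "chr1") {
  data.frame(chrom = rep(chrom, n), pos = seq_len(n) * 10,
             ref = rep("A", n), alt = rep("G", n), stringsAsFactors = FALSE)
}

# set-theoretic consensus oracle, independent of tally(): membership
# counting over key strings
oracle_support <- function(callsets) {
  keysets <- lapply(callsets, function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"))
  union_keys <- sort(unique(unlist(keysets)))
  counts <- vapply(union_keys, function(k)
    sum(vapply(keysets, function(ks) k %in% ks, logical(1))), 0L)
  stats::setNames(counts, union_keys)
}

# brute-force imputation window enumerator: walk starts step by step,
# anchor the final window at n - size
bf_impute_windows <- function(n, size, overlap) {
  if (n == 0) return(data.frame(snv_start = integer(), snv_end = integer()))
  if (n <= size) return(data.frame(snv_start = 0L, snv_end = as.integer(n)))
  step <- size - overlap
  starts <- integer(); s <- 0
  while (s + size < n) { starts <- c(starts, s); s <- s + step }
  starts <- c(starts, n - size)
  data.frame(snv_start = as.integer(starts), snv_end = as.integer(starts + size))
}

# empirical FDR of a callset against a simulation truth table
fdr_vs_truth <- function(cs, truth) {
  keys <- paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = ":")
  tkeys <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  cls <- truth$class[match(keys, tkeys)]
  mean(cls == "artifact")
}

sens_vs_truth <- function(cs, truth) {
  keys <- paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = ":")
  tkeys <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  true_keys <- tkeys[truth$class == "true"]
  mean(true_keys %in% keys)
}

# operating points shaped like four real single-caller (sensitivity, FDR)
# columns; artifact rates back-solved from FDR at equal pool sizes
table_shaped_profiles <- function() {
  sens <- c(HC = 0.6851, UG = 0.6999, GC = 0.6417, ST = 0.5126)
  fdr <- c(HC = 0.2291, UG = 0.1616, GC = 0.0612, ST = 0.3311)
  art <- sens * fdr / (1 - fdr)
  lapply(names(sens), function(nm)
    caller_profile(nm, sens[[nm]], art[[nm]]))
}
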