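#' Construct a genotype matrix
#'
#' Alt-allele dosage genotypes for a set of SNV sites and samples: integer
#' values 0 (hom ref), 1 (het), 2 (hom alt), with `NA` for missing calls —
#' missingness is distinct from dosage 0.
#'
#' @param geno Integer matrix (or coercible), sites in rows, samples in
#'   columns; values in `{0, 1, 2, NA}`.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`, one row per
#'   matrix row.
#' @param samples Character vector of sample labels, one per column.
#' @return A `genotype_matrix`: the integer matrix with `sites` attached as
#'   an attribute and site keys as rownames.
#' @export
genotype_matrix <- function(geno, sites, samples = colnames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites))
    stop("genotype matrix has ", nrow(geno), " rows but ", nrow(sites), " sites")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  if (ncol(geno) != length(samples))
    stop("genotype matrix has ", ncol(geno), " columns but ", length(samples), " samples")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be alt-allele dosages in {0, 1, 2} or NA")
  sites <- as.data.frame(sites)[, c("chrom", "pos", "ref", "alt")]
  rownames(geno) <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  colnames(geno) <- samples
  structure(geno, sites = sites, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "site(s) x", ncol(x), "sample(s); ",
      sum(is.na(x)), "missing cell(s)\n")
  invisible(x)
}

#' Sites of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return data.frame of site keys (`chrom`, `pos`, `ref`, `alt`).
#' @export
gm_sites <- function(x) attr(x, "sites")

#' Read genotypes from TSV or VCF
#'
#' TSV dialect (array-style): header `chrom`, `pos`, `ref`, `alt`, then one
#' column per sample with dosage values `0/1/2` and `.` (or `NA`) for
#' missing. VCF input converts diploid `GT` fields to dosages (any
#' unphased/phased separator; missing `./.` becomes `NA`).
#'
#' @param path Input file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (is_vcf(path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    alleles <- gsub("[|/]", "", gt)
    dos[alleles == "00"] <- 0L
    dos[alleles %in% c("01", "10")] <- 1L
    dos[alleles == "11"] <- 2L
    sites <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.numeric(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
    return(genotype_matrix(dos, sites, colnames(gt)))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", "."),
                           check.names = FALSE)
  key_cols <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(key_cols, names(tab))
  if (length(miss) > 0)
    stop("genotype TSV missing column(s): ", paste(miss, collapse = ", "))
  samples <- setdiff(names(tab), key_cols)
  genotype_matrix(as.matrix(tab[, samples, drop = FALSE]),
                  tab[, key_cols], samples)
}

#' Write a genotype matrix as TSV
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- cbind(gm_sites(gm), as.data.frame(unclass(gm)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}
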