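BASES <- c("A", "C", "G", "T")

# natural chromosome ordering: chr1..chr22, chrX, chrY, chrMT, then others
chrom_natural_order <- function(chroms) {
  u <- unique(chroms)
  core <- sub("^chr", "", u)
  num <- suppressWarnings(as.numeric(core))
  sex <- match(core, c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(num), num, ifelse(!is.na(sex), 100 + sex, NA))
  u[order(is.na(key), key, u)]
}

#' Construct a caller callset
#'
#' A callset is the site-level output of one variant caller: a set of
#' bi-allelic SNV site keys `(chrom, pos, ref, alt)` with `pos` 1-based.
#' Sites are deduplicated and sorted by chromosome order then position,
#' ref, alt; site identity is allele-aware, so two callers reporting
#' different alt alleles at one position do not corroborate each other.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (additional columns such as `support` are carried through).
#' @param caller_id Label for the caller that produced the set.
#' @param chrom_order Character vector fixing chromosome sort order
#'   (e.g. `grch37_autosomes()$name`). Defaults to natural order
#'   (chr1..chr22, chrX, chrY).
#' @return An object of class `callset` (a sorted data.frame with
#'   attributes `caller_id` and `chrom_order`).
#' @export
callset <- function(sites, caller_id = "caller", chrom_order = NULL) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) stop("sites missing column(s): ", paste(miss, collapse = ", "))
  sites$chrom <- as.character(sites$chrom)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  bad <- !(sites$ref %in% BASES) | !(sites$alt %in% BASES)
  if (any(bad))
    stop("non-SNV or invalid alleles at record(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(sites$ref == sites$alt))
    stop("ref equals alt at record(s): ",
         paste(utils::head(which(sites$ref == sites$alt), 5), collapse = ", "))
  sites <- sites[!duplicated(sites[, need]), , drop = FALSE]
  if (is.null(chrom_order)) chrom_order <- chrom_natural_order(sites$chrom)
  sites <- sites[order(chrom_rank(sites$chrom, chrom_order),
                       sites$pos, sites$ref, sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("callset", "data.frame"),
            caller_id = caller_id, chrom_order = chrom_order)
}

#' @export
print.callset <- function(x, ...) {
  cat("callset '", attr(x, "caller_id"), "': ", nrow(x), " bi-allelic SNV site(s)\n",
      sep = "")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Caller id of a callset
#' @param x A `callset`.
#' @return The caller label.
#' @export
caller_id <- function(x) attr(x, "caller_id")

# canonical "chrom:pos:ref:alt" strings used for set operations
site_keys <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Number of sites in a callset
#' @param x A `callset`.
#' @return Integer site count.
#' @export
n_sites <- function(x) nrow(x)
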