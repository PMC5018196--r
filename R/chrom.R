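#' Read a chromosome-length table
#'
#' Reads genome geometry from either a two-column TSV (`name`, `length`,
#' header optional) or a FASTA index (`.fai`), whose first two columns carry
#' the same information. Chromosome order in the file defines the canonical
#' chromosome order used for sorting callsets and bin plans.
#'
#' @param path Path to a TSV or `.fai` file.
#' @return A `data.frame` with columns `name` (character) and `length`
#'   (integer bp), one row per chromosome, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t1000000", "chr2\t500000"), tf)
#' read_chrom_lengths(tf)
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) stop("chromosome length table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("expected at least 2 columns (name, length) in ", path)
  # tolerate a header row ("name  length")
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
  out <- data.frame(name = as.character(tab[[1]]),
                    length = as.numeric(tab[[2]]),
                    stringsAsFactors = FALSE)
  validate_chrom_lengths(out)
  out
}

validate_chrom_lengths <- function(chrom_lengths) {
  if (!is.data.frame(chrom_lengths) ||
      !all(c("name", "length") %in% names(chrom_lengths)))
    stop("chromosome table must be a data.frame with columns 'name' and 'length'")
  if (nrow(chrom_lengths) == 0)
    stop("chromosome table is empty: nothing to plan windows over")
  if (anyDuplicated(chrom_lengths$name))
    stop("duplicate chromosome names in genome table")
  if (any(!is.finite(chrom_lengths$length)) || any(chrom_lengths$length <= 0))
    stop("all chromosome lengths must be positive")
  invisible(chrom_lengths)
}

#' Bundled GRCh37 autosome lengths
#'
#' Convenience loader for the GRCh37 (hg19) chromosome 1-22 length table
#' shipped with the package. These are the standard reference lengths; at a
#' 1 Mbp window size they tile into 2897 windows.
#'
#' @return A `data.frame` with columns `name` and `length`.
#' @export
grch37_autosomes <- function() {
  read_chrom_lengths(system.file("extdata", "grch37_autosomes.tsv",
                                 package = "snvensemble", mustWork = TRUE))
}

#' Synthetic empty-window exclusion list for the GRCh37 autosome plan
#'
#' In a real cohort, windows intersecting centromere and telomere gaps
#' carry no reads and are dropped before joint calling; which windows those
#' are is a property of the data. This bundled list is a *synthetic*
#' stand-in: 163 window ids of the 1 Mbp GRCh37 autosome plan chosen
#' deterministically around approximate centromere/heterochromatin spans,
#' acrocentric p-arms and chromosome ends. Its cardinality matches the
#' empty-window count observed in large real cohorts; the specific ids are
#' illustrative only.
#'
#' @return Character vector of 163 `"chrom:index"` window ids.
#' @export
grch37_empty_windows_synthetic <- function() {
  readLines(system.file("extdata", "grch37_empty_windows_synthetic.tsv",
                        package = "snvensemble", mustWork = TRUE))
}

# integer chromosome rank under a genome-table order; errors on unknowns
chrom_rank <- function(chrom, chrom_order) {
  r <- match(chrom, chrom_order)
  if (anyNA(r)) {
    bad <- unique(chrom[is.na(r)])
    stop("chromosome(s) absent from genome table: ", paste(bad, collapse = ", "))
  }
  r
}
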