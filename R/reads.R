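#' Read-inclusion predicate for slicing a flanked window
#'
#' Decides, for every read in a toy read table, whether it belongs in the
#' slice of one flanked window, and reports the mates that must be pulled in
#' with it. A read is included when its aligned span overlaps
#' `[flank_start, flank_end)`. For included reads, mapped mates anywhere in
#' the genome and unmapped mates are reported for pulling, so downstream
#' callers see complete pairs.
#'
#' Read tables are plain data.frames (or TSVs via [read_read_table()]) with
#' columns `name`, `chrom`, `pos` (0-based), `aligned_end` (exclusive),
#' `mapped`, `mate_chrom`, `mate_pos`, `mate_mapped`.
#'
#' @param reads Read table.
#' @param window One row of a flanked `bin_plan`'s `windows` (or any list
#'   with `chrom`, `flank_start`, `flank_end`).
#' @return Logical vector, one element per read: overlaps the flanked
#'   window. See [slice_reads()] for the full slice with mate closure.
#' @export
read_in_window <- function(reads, window) {
  stopifnot(all(c("chrom", "pos", "aligned_end", "mapped") %in% names(reads)))
  if (is.null(window$flank_start) || is.null(window$flank_end))
    stop("window has no flanks computed: run add_flanks() on the plan")
  as.logical(reads$mapped) &
    reads$chrom == window$chrom &
    reads$pos < window$flank_end &
    reads$aligned_end > window$flank_start
}

#' Slice a read table against one flanked window
#'
#' Two-pass slicing: pass 1 applies the overlap predicate
#' ([read_in_window()]); pass 2 closes over mates, adding the mate of every
#' included read (mapped mates wherever they align, and unmapped mates) to
#' the pull set.
#'
#' @inheritParams read_in_window
#' @return List with `included` (rows of `reads` overlapping the window)
#'   and `mate_pulls` (data.frame `name`, `mate_chrom`, `mate_pos`,
#'   `mate_mapped` of mates not already in the slice).
#' @export
slice_reads <- function(reads, window) {
  inc <- read_in_window(reads, window)
  included <- reads[inc, , drop = FALSE]
  if (nrow(included) == 0)
    return(list(included = included,
                mate_pulls = included[, c("name", "mate_chrom", "mate_pos", "mate_mapped")]))
  # a mate is already present if the same read name occurs twice in the slice
  dup <- included$name %in% included$name[duplicated(included$name)]
  pulls <- included[!dup, c("name", "mate_chrom", "mate_pos", "mate_mapped"), drop = FALSE]
  # mates of included reads are pulled whether mapped elsewhere or unmapped
  rownames(pulls) <- NULL
  list(included = included, mate_pulls = pulls)
}

#' Read a toy read table from TSV
#'
#' @param path TSV with header columns `name`, `chrom`, `pos`,
#'   `aligned_end`, `mapped`, `mate_chrom`, `mate_pos`, `mate_mapped`.
#' @return data.frame with those columns; `mapped`/`mate_mapped` logical.
#' @export
read_read_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("name", "chrom", "pos", "aligned_end", "mapped",
            "mate_chrom", "mate_pos", "mate_mapped")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("read table missing column(s): ", paste(miss, collapse = ", "))
  tab$mapped <- as.logical(tab$mapped)
  tab$mate_mapped <- as.logical(tab$mate_mapped)
  if (any(tab$mapped & tab$pos >= tab$aligned_end))
    stop("mapped reads must have pos < aligned_end")
  tab
}
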