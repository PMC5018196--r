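#' Export a bin plan as BED
#'
#' Core window extents in BED (0-based half-open) with the window id in the
#' name column.
#'
#' @param plan A `bin_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
plan_to_bed <- function(plan, path) {
  stopifnot(inherits(plan, "bin_plan"))
  w <- plan$windows
  utils::write.table(
    data.frame(w$chrom, format(w$start, scientific = FALSE, trim = TRUE),
               format(w$end, scientific = FALSE, trim = TRUE),
               window_ids(plan)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render windows as 1-based inclusive region strings
#'
#' The `chrom:start-end` dialect used by indexed-alignment region queries
#' (samtools convention). Flanked extents are rendered, since slicing pulls
#' the buffer too; with `flank = 0` these equal the core extents.
#'
#' @param plan A `bin_plan`.
#' @return Character vector of region strings, one per window.
#' @export
plan_to_regions <- function(plan) {
  stopifnot(inherits(plan, "bin_plan"))
  w <- plan$windows
  paste0(w$chrom, ":",
         format(w$flank_start + 1, scientific = FALSE, trim = TRUE), "-",
         format(w$flank_end, scientific = FALSE, trim = TRUE))
}

#' Export the group manifest as TSV
#'
#' @param plan A grouped `bin_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
groups_to_tsv <- function(plan, path) {
  stopifnot(inherits(plan, "bin_plan"))
  if (is.null(plan$groups)) stop("plan has no groups: call group_windows() first")
  utils::write.table(plan$groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
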