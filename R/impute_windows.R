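#' Partition an ordered SNV list into overlapping imputation windows
#'
#' Imputation and phasing operate on blocks of consecutive SNVs rather than
#' fixed genomic spans: each window holds `size` SNVs and shares `overlap`
#' SNVs with its neighbour, so haplotype context carries across window
#' boundaries. Windows start at multiples of `step = size - overlap`; the
#' final window is anchored to the end of the list (`[n - size, n)`), so
#' every window sees a full `size`-SNV context; a chromosome with at most
#' `size` SNVs gets the single window `[0, n)`. The defaults (512 SNVs,
#' 256 overlap) are an operating point suited to relatively homogeneous
#' cohorts; the MCMC schedule metadata carried alongside (56 iterations,
#' 55 burn-in) describes the downstream sampler and is not executed here.
#'
#' @param n_snvs Number of SNVs on the chromosome (>= 0).
#' @param size Window size in SNVs (default 512).
#' @param overlap SNVs shared between adjacent windows
#'   (default 256; `0 <= overlap < size`).
#' @return data.frame with 0-based half-open index columns `snv_start`,
#'   `snv_end` (zero rows when `n_snvs == 0`).
#' @examples
#' make_impute_windows(1024)          # [0,512), [256,768), [512,1024)
#' @export
make_impute_windows <- function(n_snvs, size = 512, overlap = 256) {
  if (n_snvs < 0) stop("n_snvs must be >= 0")
  if (overlap >= size || overlap < 0) stop("require 0 <= overlap < size")
  if (n_snvs == 0)
    return(data.frame(snv_start = integer(), snv_end = integer()))
  if (n_snvs <= size)
    return(data.frame(snv_start = 0L, snv_end = as.integer(n_snvs)))
  step <- size - overlap
  n_win <- 1 + ceiling((n_snvs - size) / step)
  starts <- (seq_len(n_win) - 1) * step
  starts[n_win] <- n_snvs - size  # anchor the last window to the end
  data.frame(snv_start = as.integer(starts),
             snv_end = as.integer(starts + size))
}

#' Core-ownership map for stitching overlapped windows
#'
#' After per-window imputation, overlapped outputs must be merged without
#' double-counting: each window owns a disjoint core of the SNV index
#' range, with each overlap bisected at its midpoint (symmetric, so both
#' windows contribute equally near the boundary). Cores partition
#' `[0, n_snvs)` exactly.
#'
#' @param windows data.frame from [make_impute_windows()].
#' @return The windows with `core_start`, `core_end` columns added.
#' @export
core_map <- function(windows) {
  n <- nrow(windows)
  if (n == 0) {
    windows$core_start <- integer()
    windows$core_end <- integer()
    return(windows)
  }
  # boundary between window i and i+1 = midpoint of their intersection
  bounds <- integer(n + 1)
  bounds[1] <- windows$snv_start[1]
  bounds[n + 1] <- windows$snv_end[n]
  if (n > 1) {
    lo <- windows$snv_start[-1]
    hi <- windows$snv_end[-n]
    bounds[2:n] <- as.integer(floor((lo + hi) / 2))
  }
  windows$core_start <- bounds[-(n + 1)]
  windows$core_end <- bounds[-1]
  windows
}

#' Total imputation-window count over a genome
#'
#' Sums per-chromosome window counts: roughly `n_snvs / (size - overlap)`
#' genome-wide, plus an O(#chromosomes) correction. For a 73-million-SNV
#' autosomal callset at (512, 256) this is approximately 285,000 windows.
#'
#' @param n_snvs_per_chrom Named (or plain) numeric vector of per-chromosome
#'   SNV counts.
#' @param size,overlap As in [make_impute_windows()].
#' @return Total window count (integer).
#' @export
window_budget <- function(n_snvs_per_chrom, size = 512, overlap = 256) {
  sum(vapply(n_snvs_per_chrom, function(n)
    nrow(make_impute_windows(n, size, overlap)), 0L))
}

#' Imputation window schedule for a callset
#'
#' Runs [make_impute_windows()] and [core_map()] per chromosome of a site
#' list, translating SNV indices back to genomic positions.
#'
#' @param x A [callset()] (the union site list).
#' @param size,overlap As in [make_impute_windows()].
#' @return data.frame with `chrom`, `snv_start`, `snv_end`, `pos_start`,
#'   `pos_end` (1-based positions of the first/last SNV in the window),
#'   `core_start`, `core_end`.
#' @export
impute_schedule <- function(x, size = 512, overlap = 256) {
  chroms <- unique(x$chrom)
  out <- lapply(chroms, function(ch) {
    pos <- x$pos[x$chrom == ch]
    w <- core_map(make_impute_windows(length(pos), size, overlap))
    if (nrow(w) == 0) return(NULL)
    data.frame(chrom = ch, w[, c("snv_start", "snv_end")],
               pos_start = pos[w$snv_start + 1],
               pos_end = pos[w$snv_end],
               core_start = w$core_start, core_end = w$core_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' MCMC schedule metadata carried with imputation windows
#'
#' The downstream imputation engine's per-window sampler schedule: total
#' iterations and burn-in. Metadata only — the sampler itself is outside
#' this package's scope.
#'
#' @return list with `iterations` (56) and `burn_in` (55).
#' @export
imputation_mcmc_schedule <- function() list(iterations = 56L, burn_in = 55L)
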