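#' Tally per-site caller support across callsets
#'
#' The core of site-level consensus filtering: every distinct bi-allelic
#' SNV site key reported by any caller is counted with the number of
#' callers that reported it. No site-quality weighting is applied —
#' consensus is purely presence-based, which is what lets it replace
#' tool-specific filters.
#'
#' @param callsets List of [callset()] objects with distinct caller ids.
#' @return A `consensus_result`: list with `sites` (data.frame `chrom`,
#'   `pos`, `ref`, `alt`, `support`, `callers`), `n_callers`, `caller_ids`
#'   and the chromosome order.
#' @examples
#' a <- callset(data.frame(chrom = "1", pos = c(10, 20), ref = "A", alt = "G"), "A")
#' b <- callset(data.frame(chrom = "1", pos = 20, ref = "A", alt = "G"), "B")
#' tally(list(a, b))$sites
#' @export
tally <- function(callsets) {
  if (length(callsets) < 1) stop("need at least one callset")
  ids <- vapply(callsets, caller_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate caller_id: ", ids[duplicated(ids)][1])
  chrom_order <- Reduce(union, lapply(callsets, function(x) attr(x, "chrom_order")))

  dt <- data.table::rbindlist(lapply(seq_along(callsets), function(i) {
    x <- callsets[[i]]
    data.table::data.table(chrom = x$chrom, pos = x$pos,
                           ref = x$ref, alt = x$alt, caller = ids[i])
  }))
  if (nrow(dt) == 0) {
    sites <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                        alt = character(), support = integer(), callers = character())
  } else {
    agg <- dt[, list(support = .N,
                     callers = paste(sort(caller), collapse = ",")),
              by = c("chrom", "pos", "ref", "alt")]
    agg <- agg[order(chrom_rank(agg$chrom, chrom_order), pos, ref, alt)]
    sites <- as.data.frame(agg)
  }
  stopifnot(all(sites$support >= 1), all(sites$support <= length(callsets)))
  structure(list(sites = sites, n_callers = length(callsets),
                 caller_ids = ids, chrom_order = chrom_order),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus over", x$n_callers, "caller(s) [",
      paste(x$caller_ids, collapse = ", "), "]:",
      nrow(x$sites), "distinct site(s)\n")
  tab <- table(factor(x$sites$support, levels = seq_len(x$n_callers)))
  for (k in seq_len(x$n_callers))
    cat("  support ", k, ": ", tab[[k]], "\n", sep = "")
  invisible(x)
}

#' Threshold a consensus tally at k-of-n
#'
#' Retains the sites reported by at least `k` of the `n` callers — the
#' "k-of-n" consensus callset. `k = 1` is the union, `k = n` the
#' intersection; raising `k` trades sensitivity for a lower false discovery
#' rate, with 3-of-4 the operating point used for large low-coverage
#' cohorts.
#'
#' @param consensus A `consensus_result` from [tally()].
#' @param k Minimum caller support, `1 <= k <= n_callers`.
#' @return A [callset()] (caller id `"kofn"`) with a `support` column.
#' @export
consensus_threshold <- function(consensus, k) {
  stopifnot(inherits(consensus, "consensus_result"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > consensus$n_callers)
    stop("k must be in [1, ", consensus$n_callers, "]")
  keep <- consensus$sites$support >= k
  callset(consensus$sites[keep, c("chrom", "pos", "ref", "alt", "support")],
          caller_id = paste0(k, "of", consensus$n_callers),
          chrom_order = consensus$chrom_order)
}

#' Sites unique to one caller
#'
#' Sites with support 1 contributed by the named caller — the caller's
#' private variants relative to the rest of the ensemble.
#'
#' @param consensus A `consensus_result` from [tally()].
#' @param caller One of the tallied caller ids.
#' @return A [callset()] of the caller's unique sites.
#' @export
unique_sites <- function(consensus, caller) {
  stopifnot(inherits(consensus, "consensus_result"))
  if (!caller %in% consensus$caller_ids)
    stop("unknown caller_id: ", caller)
  keep <- consensus$sites$support == 1 & consensus$sites$callers == caller
  callset(consensus$sites[keep, c("chrom", "pos", "ref", "alt")],
          caller_id = paste0(caller, ".unique"),
          chrom_order = consensus$chrom_order)
}

#' Support-stratum report
#'
#' Per-support site counts (how many sites were seen by exactly k callers)
#' and per-caller unique-site counts.
#'
#' @param consensus A `consensus_result` from [tally()].
#' @return data.frame with columns `stratum` and `n_sites`: rows
#'   `support=k` for each k, `union`, and `unique:<caller>` per caller.
#' @export
strata_report <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_result"))
  tab <- table(factor(consensus$sites$support, levels = seq_len(consensus$n_callers)))
  uniq <- vapply(consensus$caller_ids, function(cid)
    sum(consensus$sites$support == 1 & consensus$sites$callers == cid), 0L)
  data.frame(
    stratum = c(paste0("support=", seq_len(consensus$n_callers)), "union",
                paste0("unique:", consensus$caller_ids)),
    n_sites = c(as.integer(tab), nrow(consensus$sites), as.integer(uniq)),
    stringsAsFactors = FALSE)
}
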