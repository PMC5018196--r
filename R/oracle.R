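#' Poisson-binomial tail probability
#'
#' Probability of at least `k` successes among independent Bernoulli trials
#' with (possibly unequal) success probabilities `p`, computed by the exact
#' dynamic-programming convolution. This is the detection model for k-of-n
#' consensus: with per-caller detection probabilities `p`, it is the chance
#' a site reaches consensus support `k`.
#'
#' @param p Numeric vector of per-trial success probabilities in `[0, 1]`.
#' @param k Required minimum number of successes, `0 <= k <= length(p)`.
#' @return `P(X >= k)` where `X` is the number of successes.
#' @examples
#' poisbinom_at_least(rep(0.9, 4), 3)  # 4 * 0.9^3 * 0.1 + 0.9^4
#' @export
poisbinom_at_least <- function(p, k) {
  n <- length(p)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (k < 0 || k > n) stop("k must be in [0, ", n, "]")
  if (k == 0) return(1)
  # dist[j+1] = P(j successes after the trials seen so far)
  dist <- c(1, numeric(n))
  for (pi in p) {
    shifted <- c(0, dist[-(n + 1)]) * pi
    dist <- dist * (1 - pi) + shifted
  }
  sum(dist[(k + 1):(n + 1)])
}

#' Expected k-of-n consensus operating characteristics
#'
#' Closed-form oracle for the consensus filter under the two-population
#' site model: every true site is detected by caller `c` with probability
#' `sensitivity_c`, every artifact-pool site with probability
#' `artifact_rate_c`, independently across callers given site class. The
#' expected consensus sensitivity and artifact pass-rate are Poisson-
#' binomial tails; the expected FDR is the ratio of expectations
#' `E[FP] / (E[FP] + E[TP])`, accurate to O(1/sqrt(n)) at the site counts
#' considered here.
#'
#' @param profiles List of [caller_profile()] objects (or a list of lists
#'   with `sensitivity` and `artifact_rate`).
#' @param k Consensus threshold, `1 <= k <= length(profiles)`.
#' @param n_true,n_artifact True and artifact-pool site counts.
#' @return list with `sensitivity`, `artifact_pass`, `e_tp`, `e_fp`, `fdr`.
#' @export
expected_consensus <- function(profiles, k, n_true = 1e5, n_artifact = 1e5) {
  if (length(profiles) < 1) stop("need at least one caller profile")
  if (k < 1 || k > length(profiles))
    stop("k must be in [1, ", length(profiles), "]")
  s <- vapply(profiles, function(pr) pr$sensitivity, numeric(1))
  e <- vapply(profiles, function(pr) pr$artifact_rate, numeric(1))
  sens <- poisbinom_at_least(s, k)
  pass <- poisbinom_at_least(e, k)
  e_tp <- n_true * sens
  e_fp <- n_artifact * pass
  list(sensitivity = sens, artifact_pass = pass,
       e_tp = e_tp, e_fp = e_fp,
       fdr = if (e_tp + e_fp == 0) NA_real_ else e_fp / (e_fp + e_tp))
}

#' Expected consensus table over all thresholds
#'
#' Convenience sweep of [expected_consensus()] over `k = 1..n`.
#'
#' @inheritParams expected_consensus
#' @return data.frame with one row per `k`.
#' @export
expected_consensus_table <- function(profiles, n_true = 1e5, n_artifact = 1e5) {
  n <- length(profiles)
  rows <- lapply(seq_len(n), function(k) {
    ec <- expected_consensus(profiles, k, n_true, n_artifact)
    data.frame(k = k, sensitivity = ec$sensitivity,
               artifact_pass = ec$artifact_pass, fdr = ec$fdr)
  })
  do.call(rbind, rows)
}
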