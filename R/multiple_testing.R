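## Benjamini-Hochberg false-discovery-rate control over a family of
## p-values (here: the CpGs tested for one outcome in one sample).

#' Benjamini-Hochberg step-up q-values
#'
#' With p sorted ascending, `q(i) = min_{j >= i} p(j) * m / j`, mapped
#' back to the input order (stable in ties). The q-value is the smallest
#' FDR at which the corresponding hypothesis would be rejected.
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @examples
#' bh_qvalues(c(0.01, 0.04, 0.03, 0.5))
#' @export
bh_qvalues <- function(p) {
  if (length(p) < 1L) stop2("need at least one p-value")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop2("p-values must lie in [0, 1] and be non-missing")
  m <- length(p)
  ord <- order(p)               # stable
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
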