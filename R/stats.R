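## Shared statistical primitives: the Benjamini-Hochberg step-up rule in the
## exact form used throughout the pipeline, and paired t statistics.

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up rule: p-values are ranked ascending and compared with the
#' critical values `p* = (i_r / m) * Q`, where `i_r` is the rank, `m` the
#' number of tests, and `Q` the false discovery rate. All hypotheses with
#' rank up to the largest `i` satisfying `p_(i) <= (i/m) Q` are rejected;
#' `critical_p` is that largest passing p-value (the adapted level of
#' significance), or 0 if none passes. Ties keep their original order
#' (stable sort).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q false discovery rate in `(0, 1)`.
#' @return list with `mask` (logical rejection indicator in the original
#'   order), `critical_p`, and `n_rejected`.
#' @export
bh_correct <- function(pvals, q) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  m <- length(pvals)
  if (m == 0L) return(list(mask = logical(0), critical_p = 0, n_rejected = 0L))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  o <- order(pvals)                      # stable in R
  ps <- pvals[o]
  pass <- which(ps <= seq_len(m) / m * q)
  mask <- logical(m)
  if (length(pass) == 0L)
    return(list(mask = mask, critical_p = 0, n_rejected = 0L))
  i_star <- max(pass)
  mask[o[seq_len(i_star)]] <- TRUE
  list(mask = mask, critical_p = ps[i_star], n_rejected = i_star)
}

#' Paired Student's t-test
#'
#' Standard paired t statistic on matched per-subject values with
#' `df = n - 1` and a two-sided p-value. Zero-variance nonzero differences
#' are flagged rather than producing an infinite statistic; identical
#' inputs give `t = 0, p = 1`.
#'
#' @param a,b matched numeric vectors of equal length >= 3.
#' @return list with `t`, `p`, `df`, `mean_diff`, and `zero_variance`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (any(!is.finite(d))) stop("non-finite differences", call. = FALSE)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                            zero_variance = TRUE))
    return(list(t = NA_real_, p = NA_real_, df = n - 1L, mean_diff = m,
                zero_variance = TRUE))
  }
  tval <- m / (s / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1L), df = n - 1L,
       mean_diff = m, zero_variance = FALSE)
}
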