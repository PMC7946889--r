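## Multitaper spectral estimation of layer CSD traces and per-frequency-bin
## group statistics.
##
## Spectra use K orthonormal discrete prolate spheroidal (Slepian) tapers of
## epoch length T with time-bandwidth product NW (defaults: 600-ms epochs,
## NW = 3, K = 5, no padding), giving a half-bandwidth W = NW / T = 5 Hz and
## a frequency grid spacing of 1 / T = 1.667 Hz.

# cache DPSS computations (the eigendecomposition is the expensive part)
.lamcsd_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n_samples` with
#' time-bandwidth product `nw`, as eigenvectors of the standard symmetric
#' tridiagonal commuting matrix. Tapers are orthonormal; the polarity
#' convention makes each taper's leading lobe positive. Requires
#' `k <= 2 nw - 1` (tapers beyond that are poorly concentrated).
#'
#' @param n_samples epoch length in samples (> k).
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return `n_samples x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n_samples, nw = 3, k = 5) {
  if (k > 2 * nw - 1)
    stop("k must be <= 2*nw - 1 for well-concentrated tapers", call. = FALSE)
  if (n_samples <= k) stop("n_samples must exceed k", call. = FALSE)
  key <- paste0("dpss_", n_samples, "_", nw, "_", k)
  if (!is.null(.lamcsd_cache[[key]])) return(.lamcsd_cache[[key]])
  w <- nw / n_samples
  t0 <- seq_len(n_samples) - 1
  dg <- ((n_samples - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  od <- t0[-1] * (n_samples - t0[-1]) / 2
  A <- matrix(0, n_samples, n_samples)
  A[cbind(seq_len(n_samples), seq_len(n_samples))] <- dg
  A[cbind(seq_len(n_samples - 1), seq_len(n_samples - 1) + 1L)] <- od
  A[cbind(seq_len(n_samples - 1) + 1L, seq_len(n_samples - 1))] <- od
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) v[, j] <- -v[, j]
    } else {
      # antisymmetric taper: make the leading lobe positive
      lead <- v[which(abs(v[, j]) > max(abs(v[, j])) / 2)[1L], j]
      if (lead < 0) v[, j] <- -v[, j]
    }
  }
  .lamcsd_cache[[key]] <- v
  v
}

#' In-band energy concentration of tapers
#'
#' Concentration eigenvalues `lambda_j = v_j' S v_j` with the sinc kernel
#' `S_ij = sin(2 pi W (i - j)) / (pi (i - j))`, `S_ii = 2W`: the fraction
#' of each taper's energy inside the design band. Decreases with taper
#' order.
#'
#' @param tapers matrix from [dpss_tapers()].
#' @param nw time-bandwidth product used to build the tapers.
#' @return Numeric vector of concentrations in `(0, 1)`, one per taper.
#' @export
dpss_concentration <- function(tapers, nw = 3) {
  n <- nrow(tapers)
  w <- nw / n
  d <- outer(seq_len(n), seq_len(n), "-")
  S <- sin(2 * pi * w * d) / (pi * d)
  S[d == 0] <- 2 * w
  vapply(seq_len(ncol(tapers)), function(j)
    drop(crossprod(tapers[, j], S %*% tapers[, j])), numeric(1))
}

# Multitaper complex spectra: list with one freq x trials complex matrix per
# taper, and the frequency grid.
.mt_spectra <- function(trials, fs, nw, k) {
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = 1L)
  n <- ncol(trials)
  v <- dpss_tapers(n, nw, k)
  freq <- (seq_len(n) - 1) * fs / n
  z <- vector("list", k)
  for (j in seq_len(k)) {
    tapered <- t(trials) * v[, j]       # samples x trials
    z[[j]] <- stats::mvfft(tapered)     # freq x trials, complex
  }
  list(z = z, freq = freq)
}

.retain_normalize <- function(freq, power, fmin, fmax, normalize) {
  keep <- freq >= fmin & freq <= fmax
  freq <- freq[keep]; power <- power[keep]
  if (normalize) power <- power / sum(power)
  list(freq = freq, power = power)
}

#' Evoked (phase-locked) multitaper power spectrum
#'
#' Per taper, the complex-valued spectra are averaged across trials before
#' the power is taken as the squared magnitude of the average; powers are
#' then averaged across tapers. Non-phase-locked components cancel in the
#' complex average, so this is the evoked (stimulus-locked) spectrum. The
#' spectrum is restricted to `[fmin, fmax]` (1-100 Hz by default) and
#' normalized to sum 1 over the retained bins. No padding is applied, so
#' the grid spacing is `fs / n_samples`.
#'
#' @param trials numeric matrix `trials x samples` for one layer and
#'   condition (>= 2 trials; e.g. 600-ms epochs from stimulus onset).
#' @param fs sampling rate in Hz.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5).
#' @param fmin,fmax retained frequency range in Hz.
#' @param normalize divide by the sum over retained bins (default TRUE).
#' @return An object of class `mt_spectrum`: list with `freq`, `power`,
#'   `kind = "evoked"`, and the taper spec.
#' @export
evoked_spectrum <- function(trials, fs, nw = 3, k = 5, fmin = 1, fmax = 100,
                            normalize = TRUE) {
  if (is.null(dim(trials)) || nrow(trials) < 2L)
    stop("need at least 2 trials for an evoked spectrum", call. = FALSE)
  sp <- .mt_spectra(trials, fs, nw, k)
  pw <- rowMeans(vapply(sp$z, function(zj) Mod(rowMeans(zj))^2,
                        numeric(length(sp$freq))))
  rn <- .retain_normalize(sp$freq, pw, fmin, fmax, normalize)
  structure(list(freq = rn$freq, power = rn$power, kind = "evoked",
                 nw = nw, k = k, epoch_s = ncol(trials) / fs),
            class = "mt_spectrum")
}

#' Spontaneous (total-power) multitaper spectrum
#'
#' Power is computed per trial and per taper and then averaged, so both
#' phase-locked and induced energy are retained. Restriction and
#' normalization as in [evoked_spectrum()].
#'
#' @inheritParams evoked_spectrum
#' @return An `mt_spectrum` with `kind = "spontaneous"`.
#' @export
spontaneous_spectrum <- function(trials, fs, nw = 3, k = 5, fmin = 1,
                                 fmax = 100, normalize = TRUE) {
  sp <- .mt_spectra(trials, fs, nw, k)
  pw <- rowMeans(vapply(sp$z, function(zj) rowMeans(Mod(zj)^2),
                        numeric(length(sp$freq))))
  rn <- .retain_normalize(sp$freq, pw, fmin, fmax, normalize)
  structure(list(freq = rn$freq, power = rn$power, kind = "spontaneous",
                 nw = nw, k = k,
                 epoch_s = if (is.null(dim(trials))) length(trials) / fs
                           else ncol(trials) / fs),
            class = "mt_spectrum")
}

#' @export
print.mt_spectrum <- function(x, ...) {
  cat("<mt_spectrum> ", x$kind, ", ", length(x$freq), " bins ",
      round(min(x$freq), 2), "-", round(max(x$freq), 2), " Hz (NW = ", x$nw,
      ", K = ", x$k, ", T = ", x$epoch_s, " s)\n", sep = "")
  invisible(x)
}

#' Per-bin spectral comparison between conditions
#'
#' For each frequency bin, a paired t statistic across subjects on the
#' normalized power (pre minus post, so negative t means higher power after
#' treatment), with two-sided p-values corrected by the Benjamini-Hochberg
#' step-up rule ([bh_correct()]) at rate `fdr_q` (default 0.1).
#'
#' @param pre,post numeric matrices `subjects x frequency bins` of
#'   normalized power, matched by row (subject) and column (bin).
#' @param freq frequency grid (Hz), one value per column.
#' @param fdr_q false discovery rate.
#' @return An object of class `spectral_comparison`:
#'   `data.frame(freq, t, p, significant)` with attributes `critical_p` and
#'   `fdr_q`.
#' @export
compare_spectra <- function(pre, post, freq, fdr_q = 0.1) {
  if (!all(dim(pre) == dim(post)))
    stop("pre and post must be matched subjects x bins matrices", call. = FALSE)
  if (nrow(pre) < 3L)
    stop("need at least 3 matched subjects", call. = FALSE)
  if (length(freq) != ncol(pre))
    stop("freq length must match the number of bins", call. = FALSE)
  nb <- ncol(pre)
  tv <- numeric(nb); pv <- numeric(nb)
  for (b in seq_len(nb)) {
    r <- paired_t(pre[, b], post[, b])
    tv[b] <- if (r$zero_variance && is.na(r$t)) NA_real_ else r$t
    pv[b] <- if (is.na(r$p)) 1 else r$p
  }
  bh <- bh_correct(pv, fdr_q)
  out <- data.frame(freq = freq, t = tv, p = pv, significant = bh$mask)
  attr(out, "critical_p") <- bh$critical_p
  attr(out, "fdr_q") <- fdr_q
  class(out) <- c("spectral_comparison", "data.frame")
  out
}
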