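# Canonical haemodynamic response function and causal convolution.

#' Double-gamma HRF specification
#'
#' Canonical parameters (peak delay 6 s, undershoot delay 16 s, unit
#' dispersions, peak:undershoot ratio 6) in the convention where the
#' response is the difference of two gamma densities with shape
#' `delay/dispersion` and rate `1/dispersion`.
#'
#' @param peak_delay,undershoot_delay delays in seconds.
#' @param peak_disp,undershoot_disp dispersions (must be positive).
#' @param ratio peak:undershoot amplitude ratio.
#' @return object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1, ratio = 6) {
  if (peak_disp <= 0 || undershoot_disp <= 0)
    stop("dispersions must be positive")
  if (ratio <= 0) stop("ratio must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio), class = "hrf_spec")
}

#' Sampled HRF kernel
#'
#' @param spec an [hrf_spec()].
#' @param duration kernel length in seconds (>= 20 s so the undershoot is
#'   captured).
#' @param tr sampling interval, s.
#' @return numeric kernel sampled at `0, tr, 2 tr, ...`, peak normalised
#'   to 1; causal (`kernel[1]` corresponds to t = 0 and is ~0).
#' @export
hrf_kernel <- function(spec = hrf_spec(), duration = 32, tr = 1) {
  stopifnot(inherits(spec, "hrf_spec"))
  if (duration < 20) stop("duration must be >= 20 s")
  t <- seq(0, duration, by = tr)
  h <- dgamma(t, shape = spec$peak_delay / spec$peak_disp,
              rate = 1 / spec$peak_disp) -
    dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
           rate = 1 / spec$undershoot_disp) / spec$ratio
  h / max(h)
}

#' Causal convolution truncated to the input length
#'
#' @param x input series.
#' @param kernel HRF kernel (first element = lag 0).
#' @return series of `length(x)` where
#'   `y[t] = sum_k kernel[k] * x[t - k + 1]`.
#' @export
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

# T x T causal convolution operator restricted to selected output rows;
# premultiplying the (time x n) neural matrix by this applies the HRF to
# every column at once.
convolution_operator <- function(kernel, n_time, rows = seq_len(n_time)) {
  K <- matrix(0, n_time, n_time)
  for (k in seq_along(kernel)) {
    idx <- seq_len(n_time - k + 1)
    K[cbind(idx + k - 1, idx)] <- kernel[k]
  }
  K[rows, , drop = FALSE]
}
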