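# Simulated 2AFC observer for the SF-judgment task.

#' Observer model for the SF comparison task
#'
#' The adapter shifts the perceived SF of the reference (shown in the
#' adapted hemifield) by `pse_shift[condition]` in log-SF units, so the
#' point of subjective equality of the test sits at
#' `log(reference) + shift`. Decision noise is Gaussian in log SF; on a
#' lapse the response is a coin flip.
#'
#' @param pse_shift named log-SF shifts per condition. Defaults are the
#'   aftereffect magnitudes reported for this paradigm: perceived SF 7%
#'   higher after low-SF adaptation, 13% lower after high-SF adaptation,
#'   unbiased without adaptation.
#' @param noise_sd internal noise SD, log-SF units (> 0).
#' @param lapse lapse rate in \[0, 0.1\].
#' @return object of class `observer_model`.
#' @export
observer_model <- function(pse_shift = c(low_adapt = log(1.07),
                                         high_adapt = -log(1.15),
                                         none = 0),
                           noise_sd = 0.25, lapse = 0.02) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (lapse < 0 || lapse > 0.1) stop("lapse must be in [0, 0.1]")
  structure(list(pse_shift = pse_shift, noise_sd = noise_sd, lapse = lapse),
            class = "observer_model")
}

#' One simulated 2AFC response
#'
#' @param test_log_sf,ref_log_sf log SF (natural log of cpd) of test and
#'   reference.
#' @param condition condition name indexing `observer$pse_shift`.
#' @param observer an [observer_model()].
#' @return `"test_higher"` or `"ref_higher"`.
#' @export
simulate_observer_response <- function(test_log_sf, ref_log_sf, condition,
                                       observer = observer_model()) {
  stopifnot(is.finite(test_log_sf), is.finite(ref_log_sf))
  if (runif(1) < observer$lapse)
    return(sample(c("test_higher", "ref_higher"), 1))
  shift <- observer$pse_shift[[condition]]
  d <- test_log_sf - (ref_log_sf + shift) + rnorm(1, 0, observer$noise_sd)
  if (d > 0) "test_higher" else "ref_higher"
}
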