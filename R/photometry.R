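#' Treat a photometry recording as a one-neuron session
#'
#' Applies the isosbestic correction and wraps the bulk dF/F signal as a
#' single-neuron `session_bundle`, so the encoding model, decoding and
#' modulation paths run unchanged on afferent recordings.
#'
#' @param rec `photometry_recording`.
#' @param correct apply [isosbestic_correct()] (TRUE) or use the raw 465
#'   channel.
#' @param smooth_sd_s,detrend forwarded to [isosbestic_correct()].
#' @return `session_bundle` with one neuron named after the region.
#' @export
photometry_as_session <- function(rec, correct = TRUE, smooth_sd_s = 0.1,
                                  detrend = TRUE) {
  sig <- if (correct) {
    # shift both channels to a positive baseline so the dF/F division is
    # defined for zero-mean synthetic signals
    off <- max(1, 4 * stats::sd(rec$sig405)) - min(rec$sig465, rec$sig405)
    isosbestic_correct(rec$sig465 + off, rec$sig405 + off,
                       rate_hz = rec$rate_hz, smooth_sd_s = smooth_sd_s,
                       detrend = detrend)
  } else rec$sig465
  neurons <- data.frame(neuron_id = rec$region, ap_mm = NA_real_,
                        ml_mm = NA_real_, dv_mm = NA_real_,
                        subtype = "none", stringsAsFactors = FALSE)
  session_bundle(matrix(sig, nrow = 1), rec$rate_hz, rec$events,
                 neurons = neurons, animal_id = rec$region,
                 session_id = "photometry")
}

#' Encoding model for a photometry afferent
#'
#' Identical to the single-neuron path with the bulk signal as the one
#' "neuron".
#'
#' @param rec `photometry_recording`.
#' @param ... forwarded to [fit_session_glms()] and
#'   [photometry_as_session()].
#' @param correct apply isosbestic correction first.
#' @return one-row data.frame of encoding-model results.
#' @export
fit_photometry_glm <- function(rec, correct = TRUE, ...) {
  s <- photometry_as_session(rec, correct = correct)
  fit_session_glms(s, ...)
}
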