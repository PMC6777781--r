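#' Echolocation click template
#'
#' A parametric stand-in for a loudspeaker-generated echolocation click: a
#' raised-cosine (Hann) gated sinusoid a few milliseconds long with dominant
#' spectral energy in the 3--4 kHz region.
#'
#' @param duration_ms Click duration in milliseconds.
#' @param center_frequency_khz Carrier frequency in kHz (must be below the
#'   Nyquist frequency).
#' @param amplitude Peak linear amplitude of the envelope.
#' @param sample_rate Sampling frequency in Hz.
#' @param envelope Envelope shape; only `"raised_cosine"` is implemented.
#' @return An object of class `click_template`.
#' @seealso [make_click()]
#' @export
click_template <- function(duration_ms = 3, center_frequency_khz = 3.5,
                           amplitude = 1, sample_rate = 48000L,
                           envelope = "raised_cosine") {
  stopifnot(duration_ms > 0, center_frequency_khz > 0, sample_rate > 0,
            amplitude >= 0)
  envelope <- match.arg(envelope, "raised_cosine")
  if (center_frequency_khz * 1000 >= sample_rate / 2) {
    stop("`center_frequency_khz` must be below the Nyquist frequency")
  }
  n <- round(duration_ms / 1000 * sample_rate)
  if (n < 8L) {
    stop("click duration is too short for the sample rate")
  }
  structure(
    list(duration_ms = duration_ms,
         center_frequency_khz = center_frequency_khz,
         amplitude = amplitude, sample_rate = sample_rate,
         envelope = envelope, n_samples = as.integer(n)),
    class = "click_template"
  )
}

#' Generate a click waveform
#'
#' @param template A [click_template()].
#' @return Numeric waveform of `template$n_samples` samples.
#' @examples
#' ck <- make_click(click_template())
#' length(ck)  # 144 samples at 48 kHz for a 3 ms click
#' @export
make_click <- function(template = click_template()) {
  stopifnot(inherits(template, "click_template"))
  n <- template$n_samples
  t <- (seq_len(n) - 1) / template$sample_rate
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
  template$amplitude * env *
    sin(2 * pi * template$center_frequency_khz * 1000 * t)
}

#' Frequency of the spectral peak of a waveform
#'
#' Helper for checking click templates: zero-pads the waveform and returns
#' the frequency of the largest FFT magnitude.
#'
#' @param x Numeric waveform.
#' @param sample_rate Sampling frequency in Hz.
#' @return Peak frequency in Hz.
#' @export
spectral_peak <- function(x, sample_rate = 48000L) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  nfft <- 2^ceiling(log2(max(length(x) * 8L, 1024L)))
  spec <- abs(stats::fft(c(x, numeric(nfft - length(x)))))[1:(nfft %/% 2)]
  (which.max(spec) - 1L) * sample_rate / nfft
}
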