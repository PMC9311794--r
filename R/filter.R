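#' Low-pass filter parameters
#'
#' Settings for the zero-phase Butterworth smoothing applied to NIRS
#' channels: a 10th-order low-pass design with a 0.1 Hz cut-off, applied
#' forward and backward so the net phase response is zero. The order refers
#' to the designed filter; the two passes square its magnitude response
#' (effective magnitude order 20).
#'
#' @param order Filter order, even, >= 2. Default 10.
#' @param cutoff_hz Cut-off frequency in Hz, must be below the Nyquist
#'   frequency of the trace it is applied to. Default 0.1.
#' @return A `filter_params` list.
#' @export
filter_params <- function(order = 10L, cutoff_hz = 0.1) {
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L) {
    abort("filter order must be an even integer >= 2")
  }
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) {
    abort("cutoff_hz must be positive")
  }
  structure(list(order = order, cutoff_hz = cutoff_hz, mode = "zero-phase"),
            class = "filter_params")
}

# Butterworth low-pass as second-order sections. The order-10 designs this
# pipeline uses have all poles crowded near z = 1, where the expanded
# transfer-function polynomial loses ~8 digits; the zero-pole-gain route
# with a biquad cascade keeps the DC gain exact to machine precision.
# Analog prototype poles exp(i*pi*(2k + n - 1)/(2n)), bilinear transform,
# conjugate pairs per section, two zeros at Nyquist, DC-normalised gain.
butter_sos <- function(order, wn) {
  if (order %% 2L != 0L) abort("SOS Butterworth design needs an even order")
  # wn is the cutoff as a fraction of Nyquist; prewarp for the bilinear map
  warped <- tan(pi * wn / 2)  # analog cutoff in units of 2*fs
  k <- seq_len(order / 2)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) * warped
  zp <- (1 + p) / (1 - p)
  lapply(seq_along(zp), function(i) {
    a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
    g <- sum(a) / 4
    list(b = g * c(1, 2, 1), a = a)
  })
}

# Forward-backward filtering of a biquad cascade with odd-reflection
# padding and exact steady-state initialisation per section. The padding
# must outlast the slowest pole's transient (time constant -1/log(r)), or
# edge transients leak into the signal and break the zero-phase symmetry.
filtfilt_zero_phase <- function(sos, x) {
  order <- 2L * length(sos)
  rmax <- max(vapply(sos, function(sec) {
    max(Mod(polyroot(rev(sec$a))))
  }, numeric(1)))
  padlen <- if (rmax >= 1) length(x) - 1L else
    min(length(x) - 1L,
        max(3L * order, ceiling(log(1e-13) / log(rmax))))
  minlen <- 3L * order
  if (length(x) <= minlen) {
    abort(sprintf(
      "trace too short for zero-phase filtering: need > %d samples, got %d",
      minlen, length(x)))
  }
  ext <- c(2 * x[1] - rev(x[2:(padlen + 1)]),
           x,
           2 * x[length(x)] - rev(x[(length(x) - padlen):(length(x) - 1)]))
  for (sec in sos) ext <- iir_steady(sec$b, sec$a, ext)
  ext <- rev(ext)
  for (sec in sos) ext <- iir_steady(sec$b, sec$a, ext)
  ext <- rev(ext)
  ext[(padlen + 1):(padlen + length(x))]
}

# One causal pass of the direct-form filter b/a with initial conditions set
# to the steady-state response to a constant input x[1].
iir_steady <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  lead <- max(nb, na)
  x0 <- x[1]
  x_aug <- c(rep(x0, lead), x)
  u <- stats::filter(x_aug, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[(lead + 1):length(x_aug)]
  if (na > 1) {
    y <- stats::filter(u, -a[-1], method = "recursive",
                       init = rep(x0 * sum(b) / sum(a), na - 1))
    as.numeric(y)
  } else {
    u
  }
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Smooths a uniformly sampled trace with a low-pass Butterworth filter
#' applied forward and backward (zero net phase, unit DC gain). Edge
#' transients are suppressed by odd-reflection padding of three times the
#' filter's state length plus exact steady-state initial conditions.
#'
#' @param trace A [signal_trace()] with a finite sampling rate.
#' @param params A [filter_params()] object.
#' @return A `signal_trace` on the same time grid with filtered values.
#' @export
lowpass_zero_phase <- function(trace, params = filter_params()) {
  fs <- trace_fs(trace)
  if (!is.finite(fs)) {
    abort("lowpass_zero_phase() needs a uniformly sampled trace")
  }
  if (params$cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff %g Hz is at or above the Nyquist frequency %g Hz",
                  params$cutoff_hz, fs / 2))
  }
  minlen <- 3L * params$order + 1L
  if (nrow(trace) <= minlen) {
    abort(sprintf(
      "trace has %d samples; zero-phase filtering at order %d needs more than %d",
      nrow(trace), params$order, minlen))
  }
  sos <- butter_sos(params$order, params$cutoff_hz / (fs / 2))
  with_values(trace, filtfilt_zero_phase(sos, trace$value))
}
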