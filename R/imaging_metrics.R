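#' Compute dF/F from a raw fluorescence trace
#'
#' Preprocessing mirrors the standard widefield pipeline: an optional Gaussian
#' low-pass filter (sigma in frames, default 1), an optional exponential
#' bleach correction (a single exponential fitted to the pre-onset frames plus
#' the final second, divided out and re-anchored at the trace start), then
#' `F0` = mean fluorescence over the 2 s immediately before odor onset and
#' `dF/F = (F - F0) / F0`.
#'
#' @param trace an `al_fluorescence_trace` (needs >= 2 s of pre-onset frames).
#' @param sigma Gaussian smoothing sigma in frames; 0 disables smoothing.
#' @param bleach_correct divide out a fitted exponential bleach (default
#'   FALSE).
#' @return an object of class `al_response` with fields `trace`, `values`
#'   (preprocessed), `f0`, `dff`, `frame_rate`, `onset_frame`.
#' @export
compute_dff <- function(trace, sigma = 1, bleach_correct = FALSE) {
  al_assert(inherits(trace, "al_fluorescence_trace"), "al_input_error",
            "compute_dff expects a fluorescence_trace()")
  fr <- trace$frame_rate
  onset <- trace$onset_frame
  n2s <- floor(2 * fr)
  al_assert(onset - 1 >= n2s, "al_input_error",
            "need at least 2 s of pre-onset frames (%d), have %d",
            n2s, onset - 1)
  v <- trace$values
  if (sigma > 0) v <- gaussian_smooth(v, sigma)
  if (bleach_correct) v <- bleach_correct_exp(v, fr, onset)
  f0 <- mean(v[(onset - n2s):(onset - 1)])
  al_assert(f0 > 0, "al_input_error", "non-positive baseline F0 (%.4g)", f0)
  structure(list(trace = trace, values = v, f0 = f0, dff = (v - f0) / f0,
                 frame_rate = fr, onset_frame = onset),
            class = "al_response")
}

#' @export
print.al_response <- function(x, ...) {
  cat(sprintf("<al_response> F0 = %.4g, %d frames @ %.3g Hz\n",
              x$f0, length(x$dff), x$frame_rate))
  invisible(x)
}

# Gaussian kernel smoothing with edge renormalization.
gaussian_smooth <- function(v, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  w <- exp(-x^2 / (2 * sigma^2))
  n <- length(v)
  vapply(seq_len(n), function(i) {
    j <- pmax(1L, pmin(n, i + x))
    keep <- (i + x) >= 1L & (i + x) <= n
    sum(v[j[keep]] * w[keep]) / sum(w[keep])
  }, numeric(1))
}

# Fit F(t) = A exp(-t / tau) to the frames unaffected by the response
# (pre-onset plus the final second) and divide it out, re-anchored so the
# corrected trace keeps the fitted level at t = 0.
bleach_correct_exp <- function(v, frame_rate, onset_frame) {
  n <- length(v)
  t_s <- (seq_len(n) - 1) / frame_rate
  tail_n <- max(2L, floor(frame_rate))
  idx <- unique(c(seq_len(onset_frame - 1L), (n - tail_n + 1L):n))
  vv <- v[idx]
  al_assert(all(vv > 0), "al_input_error",
            "bleach correction requires positive fluorescence")
  # log-linear initialization, refined by nonlinear least squares
  fit0 <- stats::lm(log(vv) ~ t_s[idx])
  a0 <- exp(stats::coef(fit0)[1])
  rate0 <- -stats::coef(fit0)[2]
  if (rate0 <= 1e-12) return(v) # no measurable bleach
  fit <- tryCatch(
    stats::nls(vv ~ a * exp(-t_s[idx] / tau),
               start = list(a = a0, tau = 1 / rate0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- a0; tau <- 1 / rate0
  } else {
    cf <- stats::coef(fit)
    a <- cf[["a"]]; tau <- cf[["tau"]]
  }
  v / exp(-t_s / tau)
}

#' Composite Simpson's-rule integral of a sampled series
#'
#' Even-interval pairs integrate by Simpson's rule (exact for cubics); an odd
#' final interval is closed with a trapezoid.
#'
#' @param y sampled values.
#' @param dx sample spacing.
#' @return the integral.
#' @export
simpson_integral <- function(y, dx) {
  n <- length(y)
  al_assert(n >= 2, "al_input_error", "simpson_integral needs >= 2 samples")
  n_int <- n - 1L
  total <- 0
  n_pairs <- n_int %/% 2L
  if (n_pairs > 0) {
    i0 <- 2L * seq_len(n_pairs) - 1L
    total <- sum((y[i0] + 4 * y[i0 + 1L] + y[i0 + 2L]) * dx / 3)
  }
  if (n_int %% 2L == 1L) total <- total + (y[n - 1L] + y[n]) * dx / 2
  total
}

#' Peak and AUC response metrics
#'
#' Peak is the maximum dF/F from odor onset to `window` seconds after onset.
#' AUC is the composite-Simpson integral of the dF/F trace over the same
#' window after subtracting the mean dF/F of the 1 s immediately before onset
#' (the AUC baseline). `origin = "trace_start"` integrates from the first
#' frame instead of onset.
#'
#' @param resp an `al_response` from [compute_dff()].
#' @param window response window length in seconds (default 1).
#' @param origin `"onset"` (default) or `"trace_start"` for the AUC window
#'   start.
#' @return an object of class `al_response_metrics` with `peak`, `auc`,
#'   `window` and `origin`.
#' @export
response_metrics <- function(resp, window = 1, origin = c("onset",
                                                          "trace_start")) {
  origin <- match.arg(origin)
  al_assert(inherits(resp, "al_response"), "al_input_error",
            "response_metrics expects compute_dff() output")
  fr <- resp$frame_rate
  onset <- resp$onset_frame
  dff <- resp$dff
  wn <- round(window * fr)
  al_assert(onset + wn <= length(dff), "al_input_error",
            "response window extends past the end of the trace")
  win_idx <- onset:(onset + wn)
  n1s <- max(1L, floor(fr))
  base_idx <- (onset - n1s):(onset - 1L)
  auc_baseline <- mean(dff[base_idx])
  start <- if (origin == "onset") onset else 1L
  y <- dff[start:(onset + wn)] - auc_baseline
  structure(list(peak = max(dff[win_idx]),
                 auc = simpson_integral(y, 1 / fr),
                 window = window, origin = origin,
                 auc_baseline = auc_baseline),
            class = "al_response_metrics")
}

#' @export
print.al_response_metrics <- function(x, ...) {
  cat(sprintf("<al_response_metrics> peak %.4f dF/F, AUC %.4f dF/F*s (%s)\n",
              x$peak, x$auc, x$origin))
  invisible(x)
}

#' Within-indicator max normalization of marker densities
#'
#' Normalizes per-glomerulus signal densities so that, within each indicator,
#' the densest glomerulus has value 1 (each brain/indicator then contributes
#' equally when pooling).
#'
#' @param densities data.frame with columns `indicator`, `glomerulus`, `raw`.
#' @return the input with an added `normalized` column.
#' @export
normalize_density <- function(densities) {
  al_assert(all(c("indicator", "glomerulus", "raw") %in% names(densities)),
            "al_input_error",
            "normalize_density needs indicator, glomerulus, raw columns")
  out <- densities
  out$normalized <- NA_real_
  for (ind in unique(out$indicator)) {
    sel <- out$indicator == ind
    mx <- max(out$raw[sel])
    al_assert(mx > 0, "al_input_error",
              "indicator %s has no positive density", ind)
    out$normalized[sel] <- out$raw[sel] / mx
  }
  out
}
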