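## Synthetic single-channel EEG: seeded ictal / interictal epoch generator.
## Interictal epochs are a stationary stochastic background (AR(2) with an
## alpha-band spectral peak, or spectrally shaped 1/f "pink" noise). Ictal
## epochs add a rhythmic spike-wave train: a 3 Hz fundamental with decaying
## harmonics, sharpened by one narrow Gaussian transient per cycle and gently
## amplitude-modulated, scaled relative to the background standard deviation.

#' SynthConfig: parameters of the synthetic EEG generator
#'
#' @slot fs sampling rate in Hz.
#' @slot epoch_len_s epoch duration in seconds.
#' @slot background_model \code{"ar2"} or \code{"pink"}.
#' @slot ar_coeffs AR(2) coefficients (ignored for \code{"pink"}).
#' @slot background_sd background standard deviation (unitless amplitude).
#' @slot ictal_freq_hz spike-wave fundamental frequency in Hz.
#' @slot ictal_amp burst amplitude multiplier relative to background_sd.
#' @slot ictal_duty fraction of the epoch occupied by the burst, in (0, 1].
#' @slot seed integer RNG seed.
#' @seealso \code{\link{synthConfig}}
#' @name SynthConfig-class
#' @exportClass SynthConfig
setClass("SynthConfig",
    representation(fs = "numeric", epoch_len_s = "numeric",
                   background_model = "character", ar_coeffs = "numeric",
                   background_sd = "numeric", ictal_freq_hz = "numeric",
                   ictal_amp = "numeric", ictal_duty = "numeric",
                   seed = "integer"))

setValidity("SynthConfig", function(object) {
    msg <- NULL
    if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
    if (object@epoch_len_s <= 0) msg <- c(msg, "epoch_len_s must be > 0")
    if (!object@background_model %in% c("ar2", "pink"))
        msg <- c(msg, "background_model must be 'ar2' or 'pink'")
    if (object@background_model == "ar2" && length(object@ar_coeffs) != 2L)
        msg <- c(msg, "ar_coeffs must have length 2")
    if (object@background_sd <= 0) msg <- c(msg, "background_sd must be > 0")
    if (object@ictal_amp < 0) msg <- c(msg, "ictal_amp must be >= 0")
    if (object@ictal_duty <= 0 || object@ictal_duty > 1)
        msg <- c(msg, "ictal_duty must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

# Default AR(2) coefficients placing the background spectral peak near
# `peak_hz` with pole radius r (bandwidth control): x_t = a1 x_{t-1} +
# a2 x_{t-2} + e_t with a1 = 2 r cos(2 pi f0 / fs), a2 = -r^2.
.ar2ForPeak <- function(fs, peak_hz = 10, r = 0.95) {
    c(2 * r * cos(2 * pi * peak_hz / fs), -r^2)
}

#' Configure the synthetic EEG generator
#'
#' Defaults emulate 1-s epochs of 256 Hz single-channel EEG: an AR(2)
#' background with a ~10 Hz spectral peak, and ictal bursts of 3 Hz
#' spike-wave activity at five times the background amplitude spanning the
#' whole epoch. Amplitudes are unitless (no microvolt calibration).
#'
#' @param fs sampling rate in Hz (default 256).
#' @param epoch_len_s epoch duration in seconds (default 1).
#' @param background_model \code{"ar2"} (default) or \code{"pink"}.
#' @param ar_coeffs AR(2) coefficients; default gives a ~10 Hz peak at
#'   pole radius 0.95.
#' @param background_sd background standard deviation (default 1).
#' @param ictal_freq_hz spike-wave fundamental in Hz (default 3).
#' @param ictal_amp burst amplitude as a multiple of \code{background_sd}
#'   (default 5); 0 makes the ictal class identical to the background.
#' @param ictal_duty fraction of the epoch covered by the burst (default 1).
#' @param seed integer RNG seed (default 1).
#' @return a \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig()
#' x <- generateEpoch(cfg, "ictal")
#' length(x)  # 256
#' @export
synthConfig <- function(fs = 256, epoch_len_s = 1, background_model = "ar2",
                        ar_coeffs = NULL, background_sd = 1,
                        ictal_freq_hz = 3, ictal_amp = 5, ictal_duty = 1,
                        seed = 1L) {
    .assertScalar(fs, "fs", 0, strict = TRUE)
    if (is.null(ar_coeffs)) ar_coeffs <- .ar2ForPeak(fs)
    new("SynthConfig", fs = fs,
        epoch_len_s = .assertScalar(epoch_len_s, "epoch_len_s", 0,
                                    strict = TRUE),
        background_model = background_model,
        ar_coeffs = as.numeric(ar_coeffs),
        background_sd = .assertScalar(background_sd, "background_sd", 0,
                                      strict = TRUE),
        ictal_freq_hz = .assertScalar(ictal_freq_hz, "ictal_freq_hz", 0,
                                      strict = TRUE),
        ictal_amp = .assertScalar(ictal_amp, "ictal_amp", 0),
        ictal_duty = ictal_duty, seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig:", object@fs, "Hz x", object@epoch_len_s, "s;",
        object@background_model, "background (sd", object@background_sd,
        ");", object@ictal_freq_hz, "Hz spike-wave, amp",
        object@ictal_amp, "x, duty", object@ictal_duty, "; seed",
        object@seed, "\n")
})

# Stationary sd of the AR(2) process with unit innovation variance.
.ar2Sd <- function(a) {
    a1 <- a[1]; a2 <- a[2]
    v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
    if (!is.finite(v) || v <= 0)
        stop("ar_coeffs do not define a stationary AR(2) process")
    sqrt(v)
}

.background <- function(cfg, n) {
    if (cfg@background_model == "ar2") {
        burn <- 512L
        e <- stats::rnorm(n + burn)
        x <- stats::filter(e, cfg@ar_coeffs, method = "recursive")
        as.numeric(x[(burn + 1):(burn + n)]) / .ar2Sd(cfg@ar_coeffs) *
            cfg@background_sd
    } else {
        # pink: shape white noise by 1/sqrt(f) in the frequency domain
        w <- stats::rnorm(n)
        F <- stats::fft(w)
        f <- c(1, seq_len(n - 1))          # guard DC
        f <- pmin(f, n - f + 1)            # fold to two-sided frequencies
        F <- F / sqrt(f)
        x <- Re(stats::fft(F, inverse = TRUE)) / n
        x / stats::sd(x) * cfg@background_sd
    }
}

# Deterministic spike-wave template over time points t (seconds): fundamental
# plus two decaying harmonics, one narrow Gaussian spike per cycle, and a slow
# sinusoidal amplitude modulation. Unit-free; scaled by the caller.
.spikeWave <- function(t, f0) {
    wave <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t) +
        0.25 * sin(2 * pi * 3 * f0 * t)
    # spike transient at the start of each cycle, sd = 1% of the cycle
    phase <- (t * f0) %% 1
    d <- pmin(phase, 1 - phase) / f0        # time distance to cycle onset, s
    spike <- 1.5 * exp(-0.5 * (d / (0.01 / f0))^2)
    env <- 1 + 0.3 * sin(2 * pi * 1.0 * t)
    (wave + spike) * env
}

#' Generate one synthetic EEG epoch
#'
#' @param cfg a \linkS4class{SynthConfig}; \code{cfg@seed} fixes the epoch.
#' @param cls \code{"ictal"} or \code{"interictal"}.
#' @return numeric vector of \code{fs * epoch_len_s} samples.
#' @examples
#' x <- generateEpoch(synthConfig(seed = 7), "interictal")
#' @export
generateEpoch <- function(cfg, cls = c("interictal", "ictal")) {
    stopifnot(is(cfg, "SynthConfig"))
    validObject(cfg)
    cls <- match.arg(cls)
    n <- round(cfg@fs * cfg@epoch_len_s)
    x <- .withSeed(cfg@seed, .background(cfg, n))
    if (cls == "ictal" && cfg@ictal_amp > 0) {
        t <- (seq_len(n) - 1) / cfg@fs
        burst_len <- round(n * cfg@ictal_duty)
        start <- floor((n - burst_len) / 2) + 1L
        idx <- seq(start, length.out = burst_len)
        s <- .spikeWave(t[idx], cfg@ictal_freq_hz)
        s <- s / stats::sd(s)
        x[idx] <- x[idx] + cfg@ictal_amp * cfg@background_sd * s
    }
    x
}

#' Generate a labeled dataset of synthetic epochs
#'
#' Per-epoch seeds are derived deterministically from \code{seed}, so the
#' same call always yields the same \linkS4class{EpochSet}. Ictal epochs come
#' first, then interictal.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param nIctal,nInterictal epoch counts per class (both >= 0, not both 0).
#' @param seed master seed; defaults to \code{cfg@seed}.
#' @param channelId channel tag recorded in the output.
#' @return an \linkS4class{EpochSet}.
#' @examples
#' es <- generateDataset(synthConfig(), nIctal = 40, nInterictal = 60, seed = 3)
#' table(epochLabels(es))
#' @export
generateDataset <- function(cfg, nIctal, nInterictal, seed = cfg@seed,
                            channelId = "synthetic") {
    stopifnot(is(cfg, "SynthConfig"))
    nIctal <- .assertCount(nIctal, "nIctal")
    nInterictal <- .assertCount(nInterictal, "nInterictal")
    if (nIctal + nInterictal == 0L)
        stop("empty request: at least one epoch must be generated")
    labels <- c(rep("ictal", nIctal), rep("interictal", nInterictal))
    n <- round(cfg@fs * cfg@epoch_len_s)
    sig <- matrix(0, nrow = n, ncol = length(labels))
    for (i in seq_along(labels)) {
        ecfg <- cfg
        ecfg@seed <- .deriveSeed(seed, i)
        sig[, i] <- generateEpoch(ecfg, labels[i])
    }
    EpochSet(sig, labels = labels, fs = cfg@fs, channelId = channelId)
}
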