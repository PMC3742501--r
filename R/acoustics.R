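# Acoustic front-end: whole-call average spectra, per-window spectra at the
# 11-window scheme (9 retained), and the 8 features used for repertoire
# analysis: pf, q50, ent, q50start, q50end, q50min, dur, q50maxloc.

#' Spectrogram analysis parameters
#'
#' Settings used for all spectral measurements: window taper, FFT length,
#' frame overlap and sampling rate. Defaults give a 43 Hz frequency grid and
#' a roughly 3 ms hop at 44.1 kHz (23 ms analysis window).
#'
#' @param sample_rate sampling rate in Hz.
#' @param fft_length FFT length in samples; must be a power of two.
#' @param overlap fractional overlap between frames, in [0, 1).
#' @param window taper name; only \code{"hamming"} is implemented.
#' @return list of class \code{"spectro_params"} with derived \code{hop}
#'   (samples), \code{bin_width} (Hz) and \code{window_dur} (s).
#' @export
spectro_params <- function(sample_rate = 44100, fft_length = 1024,
                           overlap = 0.875, window = "hamming") {
  if (fft_length < 2 || bitwAnd(fft_length, fft_length - 1L) != 0)
    stop("fft_length must be a power of two")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  window <- match.arg(window, "hamming")
  structure(list(
    sample_rate = sample_rate, fft_length = as.integer(fft_length),
    overlap = overlap, window = window,
    hop = max(1L, as.integer(round(fft_length * (1 - overlap)))),
    bin_width = sample_rate / fft_length,
    window_dur = fft_length / sample_rate
  ), class = "spectro_params")
}

hamming_taper <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

magnitude_spectrum <- function(frame) {
  n <- length(frame)
  Mod(stats::fft(frame * hamming_taper(n)))[seq_len(n / 2 + 1)]
}

#' Average amplitude spectrum of a call
#'
#' Computes magnitude spectra of all analysis frames lying fully inside the
#' annotated segment and averages them, giving the whole-call spectrum from
#' which pf, q50 and entropy are measured.
#'
#' @param wave numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param start,end call bounds in seconds from the start of \code{wave},
#'   half-open \code{[start, end)}.
#' @param params a [spectro_params()] object.
#' @return list of class \code{"call_spectrum"} with \code{freq} (Hz, bin
#'   centres \code{k * sample_rate / fft_length}), \code{amp} (mean
#'   magnitude) and \code{n_frames}.
#' @export
call_spectrum <- function(wave, sample_rate, start, end,
                          params = spectro_params(sample_rate)) {
  stopifnot(end > start)
  n <- params$fft_length
  s0 <- round(start * sample_rate)
  s1 <- round(end * sample_rate)
  if (s0 < 0 || s1 > length(wave)) stop("segment outside waveform bounds")
  offs <- seq(s0, s1 - n, by = params$hop)
  if (s1 - s0 < n || length(offs) == 0)
    stop("segment shorter than one analysis window (",
         signif(params$window_dur * 1000, 3), " ms)")
  amp <- numeric(n / 2 + 1)
  for (o in offs) amp <- amp + magnitude_spectrum(wave[o + seq_len(n)])
  structure(list(freq = (0:(n / 2)) * sample_rate / n,
                 amp = amp / length(offs), n_frames = length(offs)),
            class = "call_spectrum")
}

# single windowed frame centred at time `centre`, clamped to the waveform
frame_spectrum <- function(wave, sample_rate, centre,
                           params = spectro_params(sample_rate)) {
  n <- params$fft_length
  i0 <- round(centre * sample_rate) - n %/% 2
  i0 <- max(0, min(i0, length(wave) - n))
  if (length(wave) < n) stop("waveform shorter than one analysis window")
  structure(list(freq = (0:(n / 2)) * sample_rate / n,
                 amp = magnitude_spectrum(wave[i0 + seq_len(n)]),
                 n_frames = 1L),
            class = "call_spectrum")
}

spec_parts <- function(spectrum, freq = NULL) {
  if (inherits(spectrum, "call_spectrum")) {
    list(amp = spectrum$amp, freq = spectrum$freq)
  } else {
    amp <- as.numeric(spectrum)
    if (is.null(freq)) freq <- seq_along(amp)
    stopifnot(length(freq) == length(amp))
    list(amp = amp, freq = freq)
  }
}

#' Median frequency (q50) of a spectrum
#'
#' The frequency dividing the spectrum into two halves of equal energy:
#' centre frequency of the lowest bin at which cumulative energy (squared
#' amplitude) first reaches half the total. No interpolation is applied, so
#' the value is always an existing bin centre.
#'
#' @param spectrum a \code{"call_spectrum"} or a bare numeric amplitude
#'   vector.
#' @param freq optional bin centre frequencies for bare vectors (defaults to
#'   bin indices).
#' @return frequency in the units of \code{freq}.
#' @export
q50_of_spectrum <- function(spectrum, freq = NULL) {
  p <- spec_parts(spectrum, freq)
  e <- p$amp^2
  tot <- sum(e)
  if (tot <= 0) stop("spectrum has no energy; q50 undefined")
  p$freq[which(cumsum(e) >= tot / 2)[1]]
}

#' Peak frequency of a spectrum
#'
#' Centre frequency of the maximum-amplitude bin; ties are broken toward the
#' lowest frequency.
#'
#' @inheritParams q50_of_spectrum
#' @return frequency in the units of \code{freq}.
#' @export
peak_frequency <- function(spectrum, freq = NULL) {
  p <- spec_parts(spectrum, freq)
  if (sum(p$amp^2) <= 0) stop("spectrum has no energy; peak undefined")
  p$freq[which.max(p$amp)]
}

#' Wiener entropy of a spectrum
#'
#' Ratio of the geometric to the arithmetic mean of the amplitude spectrum:
#' 0 for a single spectral component, 1 for a flat spectrum. Because the raw
#' value grows with analysed bandwidth, the scaled variant restricts the
#' computation to the band up to twice the spectrum's q50 before taking the
#' ratio, removing the bandwidth dependence using only in-call quantities.
#'
#' @inheritParams q50_of_spectrum
#' @param scale_to_q50 logical; if TRUE, truncate the spectrum at
#'   \code{2 * q50} first.
#' @return unitless value in [0, 1].
#' @export
wiener_entropy <- function(spectrum, freq = NULL, scale_to_q50 = FALSE) {
  p <- spec_parts(spectrum, freq)
  if (sum(p$amp^2) <= 0) stop("spectrum has no energy; entropy undefined")
  amp <- p$amp
  if (scale_to_q50) {
    q50 <- q50_of_spectrum(spectrum, freq)
    keep <- p$freq <= 2 * q50
    amp <- amp[keep]
  }
  if (any(amp == 0)) return(0)
  exp(mean(log(amp))) / mean(amp)
}

#' Measurement-window positions within a call
#'
#' Eleven positions are spaced regularly over the call: the call start and
#' then steps of one tenth of the call length. The first and last positions
#' are discarded and the remaining nine, indexed 1..9, are retained for
#' per-window q50 measurements. Retained offsets are symmetric about the
#' call midpoint.
#'
#' @param start,end call bounds in seconds.
#' @param params a [spectro_params()]; the call must be at least one
#'   analysis window long.
#' @return data.frame with columns \code{index} (1..9) and \code{time}
#'   (seconds from the start of the waveform).
#' @export
measurement_windows <- function(start, end, params = spectro_params()) {
  dur <- end - start
  if (dur <= 0) stop("call must have positive duration")
  if (dur < params$window_dur - 1e-9)
    stop("call shorter than one analysis window (",
         signif(params$window_dur * 1000, 3), " ms)")
  data.frame(index = 1:9, time = start + (1:9) * dur / 10)
}

#' Extract the 8 acoustic features of one call
#'
#' Measures, from the whole-call average spectrum: peak frequency
#' \code{pf}, median frequency \code{q50} and Wiener entropy \code{ent}
#' (scaled to the 2*q50 band; the raw full-band value is kept as
#' \code{ent_raw}); and from single-frame spectra at the nine retained
#' measurement windows: \code{q50start}, \code{q50end}, \code{q50min} and
#' \code{q50maxloc} (index 1..9 of the maximum per-window q50, ties to the
#' earliest window). \code{dur} is the annotated duration.
#'
#' @param wave numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param start,end call bounds in seconds, half-open.
#' @param params a [spectro_params()].
#' @return one-row data.frame with the 8 features plus \code{ent_raw}.
#' @export
extract_features <- function(wave, sample_rate, start, end,
                             params = spectro_params(sample_rate)) {
  spec <- call_spectrum(wave, sample_rate, start, end, params)
  win <- measurement_windows(start, end, params)
  wq50 <- vapply(win$time, function(tc)
    q50_of_spectrum(frame_spectrum(wave, sample_rate, tc, params)),
    numeric(1))
  data.frame(
    pf = peak_frequency(spec),
    q50 = q50_of_spectrum(spec),
    ent = wiener_entropy(spec, scale_to_q50 = TRUE),
    q50start = wq50[1],
    q50end = wq50[9],
    q50min = min(wq50),
    dur = end - start,
    q50maxloc = win$index[which.max(wq50)],
    ent_raw = wiener_entropy(spec)
  )
}

#' Load a call-annotation table
#'
#' Reads a delimited text table of manually cut calls. Required columns:
#' \code{call_id}, \code{file}, \code{start_s}, \code{end_s},
#' \code{situation}, \code{piglet}, \code{litter}. Rows are validated
#' (positive duration of at least one analysis window; known situation
#' codes) and returned ordered by file then start time. Overlapping or
#' abutting segments within a file are legitimate and kept.
#'
#' @param path path to a tab- or comma-separated file with a header.
#' @param valid_situations character vector of allowed situation codes;
#'   defaults to the 11 codes of [piglet_situations()]. Use \code{NULL} to
#'   skip the check.
#' @param min_dur minimum call duration in seconds (one analysis window).
#' @return data.frame of validated call segments.
#' @export
load_annotations <- function(path,
                             valid_situations = piglet_situations()$situation,
                             min_dur = 1024 / 44100) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(ann) == 0) {
    warning("annotation file is empty: ", path)
    return(ann)
  }
  need <- c("call_id", "file", "start_s", "end_s", "situation",
            "piglet", "litter")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(ann$end_s > ann$start_s) |
                 (ann$end_s - ann$start_s) < min_dur - 1e-9)
  if (length(bad))
    stop("invalid segment(s) at row(s) ", paste(bad, collapse = ", "),
         ": end must exceed start by at least ",
         signif(min_dur * 1000, 3), " ms")
  if (!is.null(valid_situations)) {
    unk <- setdiff(unique(ann$situation), valid_situations)
    if (length(unk))
      stop("unknown situation code(s): ", paste(unk, collapse = ", "),
           "; valid codes: ", paste(valid_situations, collapse = ", "))
  }
  ann[order(ann$file, ann$start_s), , drop = FALSE]
}

#' Extract features for every annotated call in a set of recordings
#'
#' @param audio either a directory containing the WAV files named in the
#'   annotation table, or a named list of waveform objects (as returned by
#'   [read_wav()] or [synth_call_wave()]) keyed by file name.
#' @param annotations data.frame from [load_annotations()].
#' @param params a [spectro_params()].
#' @return data.frame: the annotation columns followed by the extracted
#'   feature columns.
#' @export
extract_feature_table <- function(audio, annotations,
                                  params = spectro_params()) {
  get_wave <- if (is.character(audio)) {
    cache <- new.env(parent = emptyenv())
    function(f) {
      if (is.null(cache[[f]]))
        cache[[f]] <- read_wav(file.path(audio, f))
      cache[[f]]
    }
  } else {
    function(f) {
      w <- audio[[f]]
      if (is.null(w)) stop("no waveform provided for file: ", f)
      w
    }
  }
  feats <- lapply(seq_len(nrow(annotations)), function(i) {
    w <- get_wave(annotations$file[i])
    extract_features(w$wave, w$sample_rate,
                     annotations$start_s[i], annotations$end_s[i], params)
  })
  cbind(annotations, do.call(rbind, feats))
}

#' Centre and standardize a feature table
#'
#' Scales every variable to mean 0 and variance 1 (sample standard
#' deviation, n-1 denominator) and stores the transform so held-out calls
#' can be projected onto the same scale and values back-transformed.
#'
#' @param x numeric matrix or data.frame of features (>= 2 rows).
#' @return object of class \code{"feature_scaling"} with \code{z} (the
#'   standardized matrix), \code{center} and \code{scale}.
#' @seealso [apply_scaling()], [unstandardize()]
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 calls to standardize")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  z <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  structure(list(z = z, center = ctr, scale = sds),
            class = "feature_scaling")
}

#' Apply a stored standardization to new calls
#' @param scaling a \code{"feature_scaling"} object.
#' @param x new feature matrix/data.frame with the same columns.
#' @return standardized matrix.
#' @export
apply_scaling <- function(scaling, x) {
  stopifnot(inherits(scaling, "feature_scaling"))
  x <- as.matrix(x)[, names(scaling$center), drop = FALSE]
  sweep(sweep(x, 2, scaling$center), 2, scaling$scale, "/")
}

#' Back-transform standardized features to natural units
#' @param scaling a \code{"feature_scaling"} object.
#' @param z standardized matrix.
#' @return matrix in original units.
#' @export
unstandardize <- function(scaling, z) {
  stopifnot(inherits(scaling, "feature_scaling"))
  sweep(sweep(as.matrix(z), 2, scaling$scale, "*"), 2, scaling$center, "+")
}

#' Screen out highly correlated variables
#'
#' Greedy removal: while any retained pair has absolute correlation above
#' the threshold, the later-listed member of the first offending pair (in
#' column order) is dropped.
#'
#' @param x numeric matrix or data.frame (>= 3 rows).
#' @param threshold absolute-correlation cutoff; default 0.9.
#' @return character vector of retained column names, with the dropped
#'   pairs recorded in attribute \code{"dropped"} (data.frame kept/dropped/r).
#' @export
screen_variables <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 calls to screen correlations")
  keep <- colnames(x)
  if (is.null(keep)) keep <- paste0("V", seq_len(ncol(x)))
  colnames(x) <- keep
  dropped <- data.frame(kept = character(), dropped = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    r <- stats::cor(x[, keep, drop = FALSE])
    diag(r) <- 0
    hit <- which(abs(r) > threshold, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) == 0) break
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    dropped <- rbind(dropped, data.frame(
      kept = keep[i], dropped = keep[j], r = r[i, j],
      stringsAsFactors = FALSE))
    keep <- keep[-j]
  }
  attr(keep, "dropped") <- dropped
  keep
}
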