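# Beat-level preprocessing: downsample to 250 Hz, wavelet-denoise, detect
# R-peaks, cut 256-sample windows (127 left + R + 128 right), z-score each
# lead. All sample indices are 1-based (R convention); the 256-sample window
# for an R-peak at index r is r-127 .. r+128 inclusive.

#' Downsample an ECG record
#'
#' Resamples every lead to `target_fs` using polyphase filtering
#' ([signal::decimate()] for integer factors, [signal::resample()]
#' otherwise). Only downsampling is supported. Planted R-peak indices are
#' rescaled to the new rate.
#'
#' @param record an `ecg_record`.
#' @param target_fs target sampling frequency in Hz; must satisfy
#'   `0 < target_fs <= record$fs`.
#' @return The record resampled to `target_fs`, with
#'   `round(T * target_fs / fs)` samples per lead.
#' @export
resample_record <- function(record, target_fs = 250) {
  stopifnot(inherits(record, "ecg_record"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > record$fs) {
    stop("upsampling is not supported (target_fs > record fs)")
  }
  if (target_fs == record$fs) return(record)
  n_in <- ncol(record$signal)
  n_out <- round(n_in * target_fs / record$fs)
  ratio <- target_fs / record$fs
  out <- matrix(0, nrow = nrow(record$signal), ncol = n_out,
                dimnames = list(rownames(record$signal), NULL))
  int_factor <- record$fs / target_fs
  for (i in seq_len(nrow(out))) {
    if (abs(int_factor - round(int_factor)) < 1e-9) {
      y <- signal::decimate(record$signal[i, ], round(int_factor))
    } else {
      frac <- .reduce_fraction(target_fs, record$fs)
      y <- signal::resample(record$signal[i, ], frac[1], frac[2])
    }
    if (length(y) >= n_out) {
      out[i, ] <- y[seq_len(n_out)]
    } else {
      out[i, seq_along(y)] <- y
      out[i, (length(y) + 1L):n_out] <- y[length(y)]
    }
  }
  rp <- record$rpeak_truth
  if (length(rp)) {
    rp <- pmin(pmax(as.integer(round((rp - 1L) * ratio)) + 1L, 1L), n_out)
  }
  record$signal <- out
  record$fs <- target_fs
  record$rpeak_truth <- rp
  record
}

.reduce_fraction <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  # tolerate non-integer rates by scaling up
  s <- 1
  while (abs(p * s - round(p * s)) > 1e-9 || abs(q * s - round(q * s)) > 1e-9) {
    s <- s * 10
  }
  p <- round(p * s); q <- round(q * s)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Detect R-peaks in a single-lead signal
#'
#' Built-in QRS detector following the classical derivative -> squaring ->
#' moving-window integration -> adaptive threshold recipe. Candidate regions
#' where the integrated energy exceeds 30% of its maximum are refined to the
#' sample of maximum amplitude, with a 250 ms refractory period. A flat
#' signal yields an empty result. External detectors with the same contract
#' (signal + fs -> strictly increasing indices) can be substituted anywhere
#' the package takes a `detector` argument.
#'
#' @param x numeric vector, one lead's samples (conventionally lead II).
#' @param fs sampling frequency in Hz.
#' @return Strictly increasing integer vector of 1-based R-peak indices.
#' @export
detect_rpeaks <- function(x, fs = 250) {
  if (fs <= 0) stop("fs must be positive")
  n <- length(x)
  if (n < 3L || max(x) - min(x) < 1e-12) return(integer(0))
  en <- c(0, diff(x))^2
  w <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(en, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.3 * max(integ)
  if (thr <= 0) return(integer(0))
  above <- integ > thr
  # contiguous supra-threshold regions
  starts <- which(above & !c(FALSE, above[-n]))
  ends <- which(above & !c(above[-1], FALSE))
  half <- round(0.1 * fs)
  peaks <- integer(0)
  for (k in seq_along(starts)) {
    lo <- max(1L, starts[k] - half)
    hi <- min(n, ends[k] + half)
    peaks <- c(peaks, lo + which.max(x[lo:hi]) - 1L)
  }
  peaks <- sort(unique(peaks))
  # refractory merge: keep the larger-amplitude peak of any pair < 250 ms apart
  refr <- round(0.25 * fs)
  i <- 1L
  while (i < length(peaks)) {
    if (peaks[i + 1L] - peaks[i] < refr) {
      drop <- if (x[peaks[i]] >= x[peaks[i + 1L]]) i + 1L else i
      peaks <- peaks[-drop]
    } else {
      i <- i + 1L
    }
  }
  as.integer(peaks)
}

#' Segment a record into 256-sample beats
#'
#' For each R-peak index `r` with `r - 127 >= 1` and `r + 128 <= T`, emits
#' the 12 x 256 slice of samples `r-127 .. r+128` (inclusive); peaks whose
#' window would cross a record boundary are silently dropped (padding would
#' distort the subsequent z-scoring). The record is expected to be at 250 Hz,
#' the rate at which 256 samples cover one P-QRS-T cycle.
#'
#' @param record an `ecg_record` at 250 Hz.
#' @param rpeaks integer vector of R-peak indices (1-based).
#' @return List of 12 x 256 matrices, with the source R index attached as
#'   attribute `r_index`.
#' @export
segment_beats <- function(record, rpeaks) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs != 250) {
    stop("segment_beats expects a 250 Hz record; resample first")
  }
  n <- ncol(record$signal)
  out <- list()
  for (r in rpeaks) {
    if (r - 127L >= 1L && r + 128L <= n) {
      b <- record$signal[, (r - 127L):(r + 128L), drop = FALSE]
      attr(b, "r_index") <- as.integer(r)
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

#' Z-score normalize a beat per lead
#'
#' Applies `z = (x - mu) / delta` to each lead row, where `mu` and `delta`
#' are that row's mean and population standard deviation. Removes baseline
#' offset and amplitude scaling so beats are comparable across leads and
#' records.
#'
#' @param beat numeric matrix, leads x samples.
#' @param eps degeneracy threshold: a lead with `delta <= eps` raises an
#'   error naming the lead.
#' @return Matrix of the same shape with per-lead mean 0 and standard
#'   deviation 1.
#' @export
#' @examples
#' zscore_beat(matrix(c(1, 2, 3), nrow = 1))  # -1.2247, 0, 1.2247
zscore_beat <- function(beat, eps = 1e-8) {
  beat <- as.matrix(beat)
  mu <- rowMeans(beat)
  delta <- sqrt(rowMeans((beat - mu)^2))
  if (any(delta <= eps)) {
    lead <- which(delta <= eps)[1]
    nm <- rownames(beat)[lead]
    if (is.null(nm)) nm <- as.character(lead)
    stop("degenerate beat: lead ", nm, " is (near-)constant, cannot z-score")
  }
  (beat - mu) / delta
}

#' Full preprocessing chain for one record
#'
#' Resample to 250 Hz, denoise every lead ([denoise_signal()]), detect
#' R-peaks on denoised lead II (the conventional rhythm lead), segment into
#' 256-sample beats, and z-score each beat per lead.
#'
#' @param record an `ecg_record`.
#' @param target_fs target rate, 250 Hz by default.
#' @param detector R-peak detector `function(x, fs)`; defaults to
#'   [detect_rpeaks()].
#' @param detection_lead lead used for peak detection (default `"II"`).
#' @param wavelet_levels decomposition depth for [denoise_signal()].
#' @return A `beat_dataset` whose beats carry the record's class label and
#'   patient id.
#' @export
preprocess_record <- function(record, target_fs = 250,
                              detector = detect_rpeaks,
                              detection_lead = "II", wavelet_levels = 8L) {
  record <- resample_record(record, target_fs)
  den <- record
  for (i in seq_len(nrow(record$signal))) {
    den$signal[i, ] <- denoise_signal(record$signal[i, ], fs = record$fs,
                                      levels = wavelet_levels)
  }
  lead_row <- match(detection_lead, rownames(den$signal))
  if (is.na(lead_row)) lead_row <- 2L
  rpeaks <- detector(den$signal[lead_row, ], den$fs)
  beats <- segment_beats(den, rpeaks)
  beats <- lapply(beats, zscore_beat)
  n <- length(beats)
  x <- array(0, dim = c(nrow(record$signal), 256L, n),
             dimnames = list(rownames(record$signal), NULL, NULL))
  for (k in seq_len(n)) x[, , k] <- beats[[k]]
  cls <- if (is.null(record$class_label)) "HC" else record$class_label
  structure(
    list(x = x, labels = factor(rep(cls, n), levels = unique(cls)),
         patient_id = rep(record$patient_id, n),
         lead_order = rownames(record$signal) %||% ecg_lead_names(),
         class_set = unique(cls), fs = 250),
    class = "beat_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine beat datasets
#'
#' Concatenates several `beat_dataset` objects (e.g. one per preprocessed
#' record) into one, unioning their class sets.
#'
#' @param ... `beat_dataset` objects, or a single list of them.
#' @return A combined `beat_dataset`.
#' @export
bind_beat_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1]], "beat_dataset")) dss <- dss[[1]]
  dss <- Filter(function(d) dim(d$x)[3] > 0, dss)
  stopifnot(length(dss) > 0)
  classes <- unique(unlist(lapply(dss, function(d) as.character(d$class_set))))
  n <- sum(vapply(dss, function(d) dim(d$x)[3], integer(1)))
  x <- array(0, dim = c(12L, dim(dss[[1]]$x)[2], n),
             dimnames = list(dss[[1]]$lead_order, NULL, NULL))
  labels <- character(n); pid <- character(n)
  k <- 0L
  for (d in dss) {
    m <- dim(d$x)[3]
    if (m > 0) {
      x[, , k + seq_len(m)] <- d$x
      labels[k + seq_len(m)] <- as.character(d$labels)
      pid[k + seq_len(m)] <- d$patient_id
      k <- k + m
    }
  }
  structure(
    list(x = x, labels = factor(labels, levels = classes), patient_id = pid,
         lead_order = dss[[1]]$lead_order, class_set = classes, fs = 250),
    class = "beat_dataset"
  )
}
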