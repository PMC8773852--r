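# Synthetic 12-lead ECG generator. Beats are sums of Gaussian bumps (P, T)
# and a narrow biphasic Q-R-S complex; per-lead gains make leads
# distinguishable, and MI classes perturb only the leads over their infarct
# territory, so attention-recovery and localization are testable end to end.

# Per-lead polarity/gain profile (R-wave scale, arbitrary mV-like units).
.lead_gains <- c(
  I = 0.7, II = 1.0, III = 0.5, aVR = -0.6, aVL = 0.4, aVF = 0.8,
  V1 = -0.5, V2 = 0.9, V3 = 1.1, V4 = 1.2, V5 = 1.0, V6 = 0.8
)

.gauss <- function(tt, mu, s) exp(-((tt - mu)^2) / (2 * s^2))

# One lead's noiseless beat as a function of time (seconds, 0 at the R apex).
# sig: NULL or list(perturbation, magnitude) applied to this lead.
.lead_beat <- function(tt, gain, sig = NULL) {
  g <- abs(gain)
  t_amp <- 0.35 * gain
  x <- 0.10 * g * .gauss(tt, -0.18, 0.022) -     # P wave
    0.06 * g * .gauss(tt, -0.025, 0.008) +       # Q dip
    gain * .gauss(tt, 0, 0.008) -                # R spike
    0.25 * g * .gauss(tt, 0.025, 0.008)          # S dip
  tw <- t_amp * .gauss(tt, 0.25, 0.05)           # T wave
  if (!is.null(sig)) {
    m <- sig$magnitude * g
    x <- x + switch(sig$perturbation,
      ST_elevation = m * .gauss(tt, 0.10, 0.05),
      Q_deepening  = -m * .gauss(tt, -0.025, 0.010),
      T_inversion  = 0,
      stop("unknown perturbation: ", sig$perturbation)
    )
    if (sig$perturbation == "T_inversion") tw <- -tw
  }
  x + tw
}

#' Class signature: which leads a diagnostic class perturbs, and how
#'
#' Describes the morphology change a synthetic MI class plants and the lead
#' subset carrying it. MI classes perturb (by default with an ST elevation of
#' 0.3 x the lead's QRS amplitude) exactly the leads over their anatomical
#' territory; HC perturbs nothing. OMI, a catch-all category without a fixed
#' territory, receives a milder perturbation on a random 2-lead subset drawn
#' from the supplied RNG state.
#'
#' @param class_label one of [mi_class_labels()].
#' @param magnitude perturbation size as a fraction of the lead's QRS
#'   amplitude (default 0.3; 0.15 for OMI).
#' @param perturbation one of `"ST_elevation"`, `"Q_deepening"`,
#'   `"T_inversion"`.
#' @return A `class_signature` list with `class_label`, `affected_leads`,
#'   `perturbation`, `magnitude`.
#' @export
#' @examples
#' class_signature("IMI")$affected_leads
class_signature <- function(class_label, magnitude = NULL,
                            perturbation = "ST_elevation") {
  if (!class_label %in% mi_class_labels()) {
    stop("unknown class label: ", class_label)
  }
  leads <- mi_lead_map()[[class_label]]
  if (class_label == "OMI") {
    leads <- sort(sample(ecg_lead_names(), 2L))
    if (is.null(magnitude)) magnitude <- 0.15
  }
  if (is.null(magnitude)) magnitude <- 0.3
  structure(
    list(class_label = class_label, affected_leads = leads,
         perturbation = perturbation, magnitude = magnitude),
    class = "class_signature"
  )
}

# 12 x n noiseless beat template centered at sample r0 (1-based).
.beat_template <- function(fs, n, r0, signature = NULL) {
  tt <- (seq_len(n) - r0) / fs
  leads <- ecg_lead_names()
  out <- matrix(0, nrow = 12L, ncol = n, dimnames = list(leads, NULL))
  for (i in seq_along(leads)) {
    sig <- NULL
    if (!is.null(signature) && leads[i] %in% signature$affected_leads) {
      sig <- signature
    }
    out[i, ] <- .lead_beat(tt, .lead_gains[[leads[i]]], sig)
  }
  out
}

#' Generate a continuous synthetic 12-lead ECG record
#'
#' Plants identical beats at a fixed rate, optionally adds a baseline-wander
#' sinusoid and white noise, and records the exact planted R-apex indices in
#' `rpeak_truth` so detector accuracy can be measured against ground truth.
#'
#' @param fs sampling frequency in Hz (>= 100).
#' @param duration record length in seconds.
#' @param bpm heart rate in beats per minute.
#' @param seed integer RNG seed; identical seeds give bit-identical records.
#' @param class_label diagnostic class whose signature perturbs the beats
#'   (default `"HC"` = none).
#' @param noise_sd standard deviation of additive white noise.
#' @param baseline_amp,baseline_freq amplitude and frequency (Hz) of the
#'   baseline-wander sinusoid; set `baseline_amp = 0` to disable.
#' @param patient_id opaque identifier stored on the record.
#' @param signature optional pre-built [class_signature()] overriding
#'   `class_label`.
#' @return An `ecg_record`: list with `signal` (12 x T matrix), `fs`,
#'   `rpeak_truth` (1-based sample indices), `patient_id`, `class_label`.
#' @export
#' @examples
#' rec <- generate_record(fs = 250, duration = 10, bpm = 60, seed = 1)
#' length(rec$rpeak_truth)  # 10 beats
generate_record <- function(fs = 250, duration = 10, bpm = 60, seed = 1,
                            class_label = "HC", noise_sd = 0.02,
                            baseline_amp = 0.1, baseline_freq = 0.3,
                            patient_id = "synthetic", signature = NULL) {
  if (duration <= 0 || bpm <= 0) stop("duration and bpm must be positive")
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (duration * bpm / 60 < 1) stop("record too short to hold one beat")
  set.seed(seed)
  if (is.null(signature)) signature <- class_signature(class_label)
  n <- round(fs * duration)
  step <- round(fs * 60 / bpm)
  rpeaks <- seq.int(from = round(step / 2), to = n, by = step)
  rpeaks <- rpeaks[rpeaks >= 1 & rpeaks <= n]
  # one beat template spanning -0.35 s .. +0.45 s around the R apex
  left <- round(0.35 * fs); right <- round(0.45 * fs)
  tpl <- .beat_template(fs, left + right + 1L, left + 1L, signature)
  sig <- matrix(0, nrow = 12L, ncol = n,
                dimnames = list(ecg_lead_names(), NULL))
  for (r in rpeaks) {
    lo <- r - left; hi <- r + right
    src <- seq_len(ncol(tpl))
    keep <- (lo:hi) >= 1 & (lo:hi) <= n
    sig[, (lo:hi)[keep]] <- sig[, (lo:hi)[keep]] + tpl[, src[keep]]
  }
  if (baseline_amp > 0) {
    t_s <- (seq_len(n) - 1) / fs
    phase <- runif(12L, 0, 2 * pi)
    for (i in 1:12) {
      sig[i, ] <- sig[i, ] + baseline_amp *
        sin(2 * pi * baseline_freq * t_s + phase[i])
    }
  }
  if (noise_sd > 0) {
    sig <- sig + matrix(rnorm(12L * n, sd = noise_sd), nrow = 12L)
  }
  structure(
    list(signal = sig, fs = fs, rpeak_truth = as.integer(rpeaks),
         patient_id = patient_id, class_label = signature$class_label),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz, %d planted R-peaks, class %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              length(x$rpeak_truth), x$class_label))
  invisible(x)
}

#' Generate a labeled synthetic beat dataset
#'
#' Builds z-scored 12 x 256 beats (250 Hz convention) for the requested
#' classes. Each MI class's perturbation is applied only on that class's
#' signature leads; patients are assigned so that every patient carries
#' exactly one class, which makes inter-patient splitting well defined.
#'
#' @param n_per_class beats per class.
#' @param classes character vector of class labels (subset of
#'   [mi_class_labels()]).
#' @param n_patients total number of patients (>= `length(classes)`),
#'   divided as evenly as possible across classes.
#' @param noise_sd white-noise standard deviation added before z-scoring.
#' @param seed integer RNG seed.
#' @param perturb_scale perturbation magnitude passed to [class_signature()].
#' @return A `beat_dataset`: list with `x` (array 12 x 256 x n), `labels`
#'   (factor), `patient_id` (character), `lead_order`, `class_set`, `fs`.
#' @export
#' @examples
#' ds <- generate_beat_dataset(10, c("HC", "IMI"), n_patients = 4, seed = 1)
#' dim(ds$x)
generate_beat_dataset <- function(n_per_class, classes, n_patients,
                                  noise_sd = 0.05, seed = 1,
                                  perturb_scale = 0.3) {
  bad <- setdiff(classes, mi_class_labels())
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (n_patients < length(classes)) {
    stop("n_patients must be >= number of classes")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  n_beat <- 256L
  r0 <- 128L
  # patients per class: as even as possible
  per_cls <- rep(n_patients %/% length(classes), length(classes))
  extra <- n_patients %% length(classes)
  if (extra > 0) per_cls[seq_len(extra)] <- per_cls[seq_len(extra)] + 1L
  x <- array(0, dim = c(12L, n_beat, n_per_class * length(classes)),
             dimnames = list(ecg_lead_names(), NULL, NULL))
  labels <- character(dim(x)[3])
  pid <- character(dim(x)[3])
  k <- 0L; pat_counter <- 0L
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    mag <- if (cls == "OMI") NULL else perturb_scale
    sig <- class_signature(cls, magnitude = mag)
    tpl <- .beat_template(250, n_beat, r0, sig)
    pats <- sprintf("P%03d", pat_counter + seq_len(per_cls[ci]))
    pat_counter <- pat_counter + per_cls[ci]
    for (j in seq_len(n_per_class)) {
      beat <- tpl
      if (noise_sd > 0) {
        beat <- beat + matrix(rnorm(12L * n_beat, sd = noise_sd), nrow = 12L)
      }
      k <- k + 1L
      x[, , k] <- zscore_beat(beat)
      labels[k] <- cls
      pid[k] <- pats[((j - 1L) %% length(pats)) + 1L]
    }
  }
  structure(
    list(x = x, labels = factor(labels, levels = classes),
         patient_id = pid, lead_order = ecg_lead_names(),
         class_set = classes, fs = 250),
    class = "beat_dataset"
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats (12 x %d), %d patients, classes: %s\n",
              dim(x$x)[3], dim(x$x)[2], length(unique(x$patient_id)),
              paste(x$class_set, collapse = ", ")))
  invisible(x)
}

#' Write / read a beat dataset as CSV
#'
#' One row per beat: `patient_id`, `class`, then the 12 x 256 samples
#' flattened lead-major (`I_1 ... I_256, II_1, ...`).
#'
#' @param dataset a `beat_dataset`.
#' @param path file path.
#' @return `write_beats_csv` returns `path` invisibly; `read_beats_csv`
#'   returns a `beat_dataset`.
#' @export
write_beats_csv <- function(dataset, path) {
  n <- dim(dataset$x)[3]
  flat <- t(vapply(seq_len(n), function(k) as.vector(t(dataset$x[, , k])),
                   numeric(12L * dim(dataset$x)[2])))
  colnames(flat) <- as.vector(vapply(
    dataset$lead_order,
    function(l) paste0(l, "_", seq_len(dim(dataset$x)[2])),
    character(dim(dataset$x)[2])
  ))
  df <- data.frame(patient_id = dataset$patient_id,
                   class = as.character(dataset$labels),
                   flat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  n <- nrow(df)
  n_samp <- (ncol(df) - 2L) / 12L
  x <- array(0, dim = c(12L, n_samp, n),
             dimnames = list(ecg_lead_names(), NULL, NULL))
  mat <- as.matrix(df[, -(1:2)])
  for (k in seq_len(n)) {
    x[, , k] <- matrix(mat[k, ], nrow = 12L, ncol = n_samp, byrow = TRUE)
  }
  classes <- unique(df$class)
  structure(
    list(x = x, labels = factor(df$class, levels = classes),
         patient_id = as.character(df$patient_id),
         lead_order = ecg_lead_names(), class_set = classes, fs = 250),
    class = "beat_dataset"
  )
}
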