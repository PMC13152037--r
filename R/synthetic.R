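# Synthetic cough-like audio. Each class is a set of spectral resonances;
# a clip is a train of exponentially decaying bursts of resonance-filtered
# white noise over a broadband noise floor. The contract is correct formats
# and class-separable spectra, not clinical realism.

#' Spectral specification of a synthetic cough class
#'
#' @param name Class label.
#' @param resonance_hz Center frequencies of the second-order resonators.
#' @param bandwidth_hz Bandwidth per resonance (recycled).
#' @param burst_count_range Inclusive range of bursts per 3 s clip.
#' @param decay_s Envelope decay time constant of each burst (seconds).
#' @param noise_floor_db Broadband noise level relative to the peak (dB).
#' @return A `class_spec` list.
#' @export
class_spec <- function(name, resonance_hz, bandwidth_hz = 150,
                       burst_count_range = c(2, 5), decay_s = 0.2,
                       noise_floor_db = -25) {
  if (any(burst_count_range < 1)) stopf("burst_count_range must be >= 1")
  structure(list(name = name, resonance_hz = resonance_hz,
                 bandwidth_hz = rep_len(bandwidth_hz, length(resonance_hz)),
                 burst_count_range = as.integer(burst_count_range),
                 decay_s = decay_s, noise_floor_db = noise_floor_db),
            class = "class_spec")
}

#' Default synthetic class specifications
#'
#' "default": five classes with well-separated resonances (every pair of
#' classes differs by at least 300 Hz in its primary resonance), so the
#' classes are separable by construction. "hard": resonances pushed close
#' together with a louder noise floor, for non-saturating comparisons.
#'
#' @param preset "default" or "hard".
#' @return Named list of five [class_spec()]s, in [cough_classes()] order.
#' @export
default_class_specs <- function(preset = c("default", "hard")) {
  preset <- match.arg(preset)
  if (preset == "default") {
    primaries <- c(400, 900, 1500, 2200, 3000)
    seconds <- c(1000, 2100, 3200, 4300, 5400)
    bw <- c(120, 150, 180, 200, 220)
    decay <- c(0.25, 0.18, 0.22, 0.15, 0.20)
    floor_db <- c(-28, -24, -26, -22, -25)
    bursts <- list(c(2, 4), c(3, 6), c(2, 5), c(3, 6), c(2, 5))
  } else {
    primaries <- c(1400, 1600, 1800, 2000, 2200)
    seconds <- primaries + 900
    bw <- rep(260, 5)
    decay <- rep(0.18, 5)
    floor_db <- rep(-12, 5)
    bursts <- rep(list(c(2, 5)), 5)
  }
  specs <- lapply(seq_along(COUGH_CLASSES), function(i)
    class_spec(COUGH_CLASSES[i], c(primaries[i], seconds[i]), bw[i],
               bursts[[i]], decay[i], floor_db[i]))
  setNames(specs, COUGH_CLASSES)
}

# Second-order all-pole resonator applied to a signal.
resonate <- function(x, f_hz, bw_hz, rate) {
  r <- exp(-pi * bw_hz / rate)
  a <- c(1, -2 * r * cos(2 * pi * f_hz / rate), r^2)
  as.numeric(signal::filter(1 - r, a, x))
}

#' Synthesize one cough-like clip
#'
#' Draws a burst count from the spec's range; each burst is an exponentially
#' decaying envelope (5 ms attack) applied to white noise filtered through
#' the spec's resonators, summed over bursts, plus a broadband noise floor,
#' then peak-normalized. Deterministic for a fixed seed.
#'
#' @param spec A [class_spec()].
#' @param sample_rate Rate in Hz (default 16000).
#' @param duration_s Clip duration in seconds (default 3).
#' @param seed RNG seed.
#' @return A [waveform()] of exactly `round(duration_s * sample_rate)`
#'   samples.
#' @export
synth_cough <- function(spec, sample_rate = 16000, duration_s = 3.0, seed = 1) {
  stopifnot(inherits(spec, "class_spec"))
  if (any(spec$resonance_hz >= sample_rate / 2))
    stopf("resonance at or above Nyquist (%g Hz)", sample_rate / 2)
  n <- round(duration_s * sample_rate)
  with_local_seed(seed, {
    excitation <- rnorm(n)
    colored <- Reduce(`+`, lapply(seq_along(spec$resonance_hz), function(i)
      resonate(excitation, spec$resonance_hz[i], spec$bandwidth_hz[i], sample_rate)))
    k <- sample(spec$burst_count_range[1]:spec$burst_count_range[2], 1)
    t <- (seq_len(n) - 1) / sample_rate
    env <- numeric(n)
    onsets <- runif(k, 0, max(duration_s - 2 * spec$decay_s, 0.1))
    attack <- 0.005
    for (o in onsets) {
      seg <- t >= o
      e <- numeric(n)
      e[seg] <- exp(-(t[seg] - o) / spec$decay_s) * pmin((t[seg] - o) / attack, 1)
      env <- env + e
    }
    sig <- colored * env
    pk <- max(abs(sig))
    if (pk > 0) sig <- sig / pk
    sig <- sig + 10^(spec$noise_floor_db / 20) * rnorm(n)
    peak_normalize(waveform(sig, sample_rate))
  })
}

# Per-sample seed derived from the master seed; any file is regenerable
# in isolation.
sample_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647 + 1)
}

#' Generate a labelled corpus of synthetic coughs in memory
#'
#' @param per_class Samples per class: a single count or a named vector over
#'   [cough_classes()].
#' @param specs Class specifications (default [default_class_specs()]).
#' @param seed Master seed.
#' @param sample_rate,duration_s Clip format.
#' @return List with `waveforms` (list), `labels` (character),
#'   `seeds` (integer per-sample seeds).
#' @export
simulate_corpus <- function(per_class = 522, specs = default_class_specs(),
                            seed = 1, sample_rate = 16000, duration_s = 3.0) {
  counts <- if (length(per_class) == 1) setNames(rep(per_class, length(specs)),
                                                 names(specs))
            else per_class[names(specs)]
  if (any(counts < 1)) stopf("per-class counts must be positive")
  labels <- rep(names(counts), counts)
  seeds <- vapply(seq_along(labels), function(i) sample_seed(seed, i), integer(1))
  waveforms <- lapply(seq_along(labels), function(i)
    synth_cough(specs[[labels[i]]], sample_rate, duration_s, seed = seeds[i]))
  list(waveforms = waveforms, labels = labels, seeds = seeds)
}

#' Generate a synthetic cough dataset on disk
#'
#' Writes one 16-bit PCM WAV per sample, a manifest CSV
#' (file,label,subject_id,seed) and a YAML snapshot of the generator
#' configuration. Default counts are 522 per class (2610 total, the size of
#' the study corpus); `emulate_table1 = TRUE` uses per-class counts
#' 420/435/413/398/425 instead.
#'
#' @param out_dir Output directory (created if needed).
#' @param per_class Samples per class (default 522).
#' @param specs Class specifications.
#' @param seed Master seed.
#' @param sample_rate,duration_s Clip format.
#' @param emulate_table1 Use the published training-set class counts.
#' @return The manifest data.frame (invisibly carries attribute
#'   `config_hash`, the md5 of the config snapshot).
#' @export
generate_dataset <- function(out_dir, per_class = 522,
                             specs = default_class_specs(), seed = 1,
                             sample_rate = 16000, duration_s = 3.0,
                             emulate_table1 = FALSE) {
  if (emulate_table1)
    per_class <- setNames(c(420, 435, 413, 398, 425), COUGH_CLASSES)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  corpus <- simulate_corpus(per_class, specs, seed, sample_rate, duration_s)
  n <- length(corpus$labels)
  files <- sprintf("%s_%05d.wav", corpus$labels, seq_len(n))
  for (i in seq_len(n))
    write_wav(corpus$waveforms[[i]], file.path(out_dir, files[i]))
  manifest <- data.frame(file = files, label = corpus$labels,
                         subject_id = sprintf("subj%05d", seq_len(n)),
                         seed = corpus$seeds)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  cfg <- list(seed = seed, sample_rate = sample_rate, duration_s = duration_s,
              counts = as.list(table(corpus$labels)),
              specs = lapply(specs, unclass))
  cfg_path <- file.path(out_dir, "generator-config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  attr(manifest, "config_hash") <- unname(tools::md5sum(cfg_path))
  invisible(manifest)
}
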