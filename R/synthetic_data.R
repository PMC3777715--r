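#' Specify a synthetic two-group EEG cohort
#'
#' Defines the generative conditions for a cohort of resting eyes-closed
#' recordings: a patient and a control group whose channels are convex
#' mixtures of shared band-limited latent sources and private noise,
#' `x = c * s_shared + (1 - c) * s_private`, with the coupling `c` set per
#' band and per group. The patient coupling map applies only on
#' `effect_channels`, which plants a localized connectivity deficit
#' (default: reduced alpha coupling over the fronto-central / centro-parietal
#' set F4, FC3, FC4, Cz, CPz) while all other channels follow the control map.
#'
#' @param n_patients,n_controls Group sizes (defaults 57 and 87).
#' @param n_channels Number of EEG channels; must match the montage (29).
#' @param fs Sampling rate in Hz (default 1000). Must exceed twice the
#'   highest band edge (50 Hz).
#' @param duration Recording length in seconds (default 120).
#' @param band_coupling List with elements `control` and `patient`, each a
#'   named numeric vector over the bands of [eeg_bands()] with entries in
#'   `[0, 1]`.
#' @param band_weights Relative RMS amplitude of each band in the mixture.
#'   The default is alpha-dominant, as in eyes-closed rest.
#' @param effect_channels Channel labels carrying the patient-specific
#'   coupling; must be a subset of [eeg_montage()].
#' @param n_sources Number of regional latent generators per band
#'   (default 9, Gaussian-kernel mixed by electrode distance, which gives
#'   the connectivity matrix its distance structure; 1 collapses to a
#'   single global source shared identically by all channels).
#' @param artifact_rate Expected high-amplitude artifact epochs per
#'   recording.
#' @param score_coupling Target correlation between a supplied network
#'   metric and the synthetic MADRS-like score (see [generate_scores()]).
#' @param target_rms_uV Per-channel RMS amplitude in microvolts. 30 uV keeps
#'   clean data well inside the +/-150 uV rejection rule.
#' @param eog_leak Propagation coefficients `c(veog, heog)` of the ocular
#'   channels into every EEG channel.
#' @param seed Master seed; per-subject streams are derived from it.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 57L, n_controls = 87L,
                        n_channels = 29L, fs = 1000, duration = 120,
                        band_coupling = NULL,
                        band_weights = c(delta = 1, theta = 1, alpha = 2,
                                         beta = 0.7, gamma = 0.3),
                        effect_channels = c("F4", "FC3", "FC4", "Cz", "CPz"),
                        n_sources = 9L,
                        artifact_rate = 2,
                        score_coupling = 0.35,
                        target_rms_uV = 30,
                        eog_leak = c(veog = 0.10, heog = 0.05),
                        seed = 1L) {
  bands <- names(eeg_bands())
  if (is.null(band_coupling)) {
    # calibrated so band-limited pairwise SL of retained edges sits near
    # 0.4, the scale implied by clinically reported nodal strengths at 30%
    # density; the patient alpha value plants a clear fronto-central deficit
    ctrl <- c(delta = 0.90, theta = 0.90, alpha = 0.90, beta = 0.90,
              gamma = 0.90)
    pat <- ctrl
    pat["alpha"] <- 0.80
    band_coupling <- list(control = ctrl, patient = pat)
  }
  for (g in c("control", "patient")) {
    bc <- band_coupling[[g]]
    if (is.null(bc) || !all(bands %in% names(bc)))
      stop("band_coupling$", g, " must name every band: ",
           paste(bands, collapse = ", "))
    if (any(bc < 0 | bc > 1)) stop("coupling strengths must lie in [0, 1]")
  }
  if (n_channels != length(eeg_montage()))
    stop("n_channels (", n_channels, ") must equal the montage size (",
         length(eeg_montage()), ")")
  if (!all(effect_channels %in% eeg_montage()))
    stop("effect_channels outside montage: ",
         paste(setdiff(effect_channels, eeg_montage()), collapse = ", "))
  hi <- max(vapply(eeg_bands(), `[`, numeric(1), 2L))
  if (fs <= 2 * hi)
    stop("fs must exceed twice the highest band edge (", 2 * hi, " Hz)")
  if (!all(names(band_weights) == bands))
    stop("band_weights must be named over the five bands in order")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    band_coupling = band_coupling, band_weights = band_weights,
    effect_channels = effect_channels, n_sources = as.integer(n_sources),
    artifact_rate = artifact_rate,
    score_coupling = score_coupling, target_rms_uV = target_rms_uV,
    eog_leak = eog_leak, seed = as.integer(seed)), class = "cohort_spec")
}

# band-limited unit-RMS Gaussian noise (spectral mask: exact edges, stable
# at arbitrarily low normalized frequencies)
band_noise <- function(n, band, fs) {
  x <- stats::rnorm(n)
  y <- fft_bandpass(x, band[1], band[2], fs)
  r <- sqrt(mean(y^2))
  if (r < .Machine$double.eps) return(y)
  y / r
}

#' Approximate 10-20 scalp coordinates of the montage
#'
#' Two-dimensional head-surface projections (x: left to right, y: back to
#' front, unit head radius) used by the synthetic generator to give
#' connectivity its characteristic distance structure.
#'
#' @return A 29 x 2 matrix with montage labels as row names.
#' @export
montage_coords <- function() {
  m <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95), AFz = c(0, 0.85),
    Fz = c(0, 0.72), F4 = c(0.36, 0.70), F8 = c(0.79, 0.59),
    F3 = c(-0.36, 0.70), F7 = c(-0.79, 0.59),
    FCz = c(0, 0.36), FC4 = c(0.40, 0.35), FT8 = c(0.95, 0.31),
    FC3 = c(-0.40, 0.35), FT7 = c(-0.95, 0.31),
    Cz = c(0, 0), C4 = c(0.41, 0), T8 = c(1, 0),
    C3 = c(-0.41, 0), T7 = c(-1, 0),
    CPz = c(0, -0.36), CP4 = c(0.40, -0.35), CP3 = c(-0.40, -0.35),
    Pz = c(0, -0.72), P4 = c(0.36, -0.70), P8 = c(0.79, -0.59),
    P3 = c(-0.36, -0.70), P7 = c(-0.79, -0.59),
    Oz = c(0, -1), O2 = c(0.31, -0.95), O1 = c(-0.31, -0.95))
  colnames(m) <- c("x", "y")
  m[eeg_montage(), ]
}

# loadings of each channel on one global plus n_sources regional
# generators: Gaussian kernel in electrode distance (rows unit-norm), so
# neighbouring channels share most of their latent drive while distant
# pairs keep only the global component; with n_sources = 1 every channel
# loads identically on a single latent
source_loadings <- function(n_sources, sigma = 0.6, global_weight = 0.55) {
  if (n_sources == 1) return(matrix(1, nrow(montage_coords()), 1))
  sites <- montage_coords()[c("Fz", "F3", "F4", "Cz", "C3", "C4",
                              "Pz", "P3", "P4")[seq_len(n_sources)], ,
                            drop = FALSE]
  xy <- montage_coords()
  K <- exp(-outer(seq_len(nrow(xy)), seq_len(nrow(sites)),
                  Vectorize(function(i, k)
                    sum((xy[i, ] - sites[k, ])^2))) / (2 * sigma^2))
  K <- K / sqrt(rowSums(K^2))
  W <- cbind(global_weight, (1 - global_weight) * K)
  W / sqrt(rowSums(W^2))
}

simulate_subject <- function(spec, group, subject_seed) {
  set.seed(subject_seed)
  n <- round(spec$duration * spec$fs)
  bands <- eeg_bands()
  labels <- eeg_montage()
  effect <- labels %in% spec$effect_channels
  w <- spec$band_weights
  W <- source_loadings(spec$n_sources)
  x <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (b in names(bands)) {
    if (w[[b]] == 0) next
    S <- t(vapply(seq_len(ncol(W)),
                  function(k) band_noise(n, bands[[b]], spec$fs),
                  numeric(n)))
    shared <- W %*% S                 # unit-variance regional field per row
    for (ch in seq_len(spec$n_channels)) {
      cc <- if (group == "patient" && effect[ch])
        spec$band_coupling$patient[[b]] else spec$band_coupling$control[[b]]
      priv <- if (cc < 1) band_noise(n, bands[[b]], spec$fs) else 0
      x[ch, ] <- x[ch, ] + w[[b]] * (cc * shared[ch, ] + (1 - cc) * priv)
    }
  }
  for (ch in seq_len(spec$n_channels)) {
    r <- sqrt(mean(x[ch, ]^2))
    if (r > .Machine$double.eps) x[ch, ] <- x[ch, ] * (spec$target_rms_uV / r)
  }
  # slow ocular channels, leaked into every EEG channel
  veog <- band_noise(n, c(0.5, 5), spec$fs) * spec$target_rms_uV
  heog <- band_noise(n, c(0.5, 5), spec$fs) * spec$target_rms_uV
  eeg <- x + spec$eog_leak[["veog"]] * rep(1, spec$n_channels) %o% veog +
    spec$eog_leak[["heog"]] * rep(1, spec$n_channels) %o% heog
  recording(subject_id = NA_character_, fs = spec$fs,
            samples = rbind(eeg, VEOG = veog, HEOG = heog),
            channel_labels = c(labels, eog_labels()))
}

simulate_meta <- function(group, n) {
  patient <- group == "patient"
  pos_int <- function(x) pmax(0, round(x))
  sex <- character(n)
  sex[patient] <- sample(c("male", "female"), sum(patient), replace = TRUE,
                         prob = c(25, 32))
  sex[!patient] <- sample(c("male", "female"), sum(!patient), replace = TRUE,
                          prob = c(35, 52))
  data.frame(
    subject_id = character(n), group = group,
    age = pmin(58, pmax(20, round(stats::rnorm(
      n, ifelse(patient, 41.2, 40.1), ifelse(patient, 10.5, 10.6))))),
    sex = sex,
    iq = round(stats::rnorm(n, ifelse(patient, 102.8, 106.1),
                            ifelse(patient, 17.5, 14.7))),
    education = pos_int(stats::rnorm(n, ifelse(patient, 12.3, 14.2),
                                     ifelse(patient, 3.2, 2.9))),
    ymrs = ifelse(patient, pos_int(stats::rnorm(n, 12.5, 10.7)), 0L),
    madrs = ifelse(patient, pos_int(stats::rnorm(n, 13.0, 11.1)), 0L),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic resting-EEG cohort
#'
#' Simulates every subject of a [cohort_spec()]: multichannel recordings in
#' microvolts with the planted group-by-band coupling structure, occasional
#' high-amplitude artifacts, and a demographic/clinical metadata table.
#' Deterministic for a fixed `spec$seed` (per-subject random streams are
#' drawn once from the master seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `recordings` (list of `sl_recording`) and `meta`
#'   (data frame with columns subject_id, group, age, sex, iq, education,
#'   ymrs, madrs).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  n <- length(groups)
  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  ids <- character(n)
  ids[groups == "patient"] <- sprintf("bd%03d", seq_len(spec$n_patients))
  ids[groups == "control"] <- sprintf("nc%03d", seq_len(spec$n_controls))
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- simulate_subject(spec, groups[i], subject_seeds[i])
    rec$subject_id <- ids[i]
    if (spec$artifact_rate > 0)
      rec <- plant_artifacts(rec, spec$artifact_rate,
                             seed = subject_seeds[i] %% 1000003L + 7L)
    recordings[[i]] <- rec
  }
  set.seed(subject_seeds[n + 1L])
  meta <- simulate_meta(groups, n)
  meta$subject_id <- ids
  list(recordings = recordings, meta = meta)
}

#' Plant high-amplitude artifact epochs in a recording
#'
#' Adds a 200 ms raised-cosine pulse of 400 uV peak (well beyond the
#' +/-150 uV rejection threshold) to one randomly chosen EEG channel in each
#' of `round(rate)` distinct, epoch-aligned 2 s windows. The affected epoch
#' indices are recorded in the `artifact_epochs` attribute.
#'
#' @param rec An `sl_recording`.
#' @param rate Number of artifact epochs to plant (non-negative).
#' @param seed Integer seed; placement is reproducible.
#' @param epoch_seconds Epoch length used for alignment (default 2).
#' @return The recording with artifacts added.
#' @export
plant_artifacts <- function(rec, rate, seed, epoch_seconds = 2) {
  stopifnot(inherits(rec, "sl_recording"), rate >= 0)
  n_art <- round_half_up(rate)
  if (n_art == 0) {
    attr(rec, "artifact_epochs") <- integer(0)
    return(rec)
  }
  set.seed(seed)
  epoch_len <- round(epoch_seconds * rec$fs)
  n_epochs <- floor(ncol(rec$samples) / epoch_len)
  n_art <- min(n_art, n_epochs)
  eps <- sort(sample.int(n_epochs, n_art))
  eeg_idx <- which(rec$channel_labels %in% eeg_montage())
  pulse_len <- round(0.2 * rec$fs)
  pulse <- 400 * (1 - cos(2 * pi * seq_len(pulse_len) / (pulse_len + 1))) / 2
  for (e in eps) {
    ch <- sample(eeg_idx, 1L)
    start <- (e - 1L) * epoch_len + sample.int(epoch_len - pulse_len, 1L)
    idx <- start + seq_len(pulse_len) - 1L
    rec$samples[ch, idx] <- rec$samples[ch, idx] + pulse
  }
  attr(rec, "artifact_epochs") <- eps
  rec
}

#' Draw clinical scores with a target correlation to a network metric
#'
#' Generates MADRS-like severity scores whose population correlation with
#' the supplied per-subject metric equals `spec$score_coupling`. The latent
#' Gaussian score is scaled to the conventional MADRS scale (mean 13.0,
#' SD 11.1) and then rounded and clipped to non-negative integers, which
#' attenuates the realized correlation slightly.
#'
#' @param metrics Numeric vector of per-subject network metric values; must
#'   not be constant.
#' @param spec A [cohort_spec()] (supplies `score_coupling`).
#' @param seed Integer seed.
#' @param mean_score,sd_score Scale of the returned scores.
#' @return Integer vector of scores, same length as `metrics`.
#' @export
generate_scores <- function(metrics, spec, seed,
                            mean_score = 13.0, sd_score = 11.1) {
  rho <- spec$score_coupling
  if (abs(rho) > 1) stop("score_coupling must lie in [-1, 1]")
  if (stats::sd(metrics) < .Machine$double.eps)
    stop("metric vector is constant; scores with a target correlation are undefined")
  set.seed(seed)
  z <- as.numeric(scale(metrics))
  latent <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(metrics))
  pmax(0L, as.integer(round(mean_score + sd_score * latent)))
}
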