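#' Stimulus design for the block simulation
#'
#' The default protocol is a 30 s block whose first 20 s contain 100 repeated
#' trials 200 ms apart; within each trial, spot A is stimulated at the trial
#' onset and spot B 50 ms later. Electrical activity is sampled at 1000 Hz,
#' hemodynamics at 10 Hz.
#'
#' @param n_trials number of trials. Default 100.
#' @param trial_spacing_s inter-trial interval in s. Default 0.2.
#' @param block_duration_s block length in s. Default 30.
#' @param spot_offsets_s named numeric, within-trial stimulus offset of each
#'   spot in s. Default `c(A = 0, B = 0.05)`.
#' @param fs_electrical,fs_hemodynamic sampling rates in Hz.
#' @return `eegdot_design` with `trial_onsets_s` and the above fields.
#' @examples
#' d <- generate_design()
#' length(d$trial_onsets_s)      # 100
#' max(d$trial_onsets_s)         # 19.8
#' @export
generate_design <- function(n_trials = 100L,
                            trial_spacing_s = 0.2,
                            block_duration_s = 30,
                            spot_offsets_s = c(A = 0, B = 0.05),
                            fs_electrical = 1000,
                            fs_hemodynamic = 10) {
  if (trial_spacing_s <= 0 || block_duration_s <= 0 ||
      fs_electrical <= 0 || fs_hemodynamic <= 0) {
    stop("durations and sampling rates must be positive", call. = FALSE)
  }
  if (n_trials < 0) stop("`n_trials` must be >= 0", call. = FALSE)
  if (n_trials > 0 &&
      (n_trials - 1) * trial_spacing_s + trial_spacing_s > block_duration_s) {
    stop("trials overflow the simulation block", call. = FALSE)
  }
  onsets <- if (n_trials > 0) (seq_len(n_trials) - 1) * trial_spacing_s else numeric(0)
  structure(
    list(
      n_trials = as.integer(n_trials),
      trial_spacing_s = trial_spacing_s,
      block_duration_s = block_duration_s,
      spot_offsets_s = spot_offsets_s,
      trial_onsets_s = onsets,
      fs_electrical = fs_electrical,
      fs_hemodynamic = fs_hemodynamic
    ),
    class = "eegdot_design"
  )
}

#' Define an activation spot on the cortical shell
#'
#' A spot is the set of source voxels within `radius_mm` of a center point
#' (about an 8 mm diameter patch by default, emulating a digit representation
#' in sensorimotor cortex). On coarse source lattices the set may be small; it
#' always contains at least the voxel nearest the center.
#'
#' @param sources `eegdot_source_space`.
#' @param center length-3 position in mm (projected radially onto the shell).
#' @param label spot label, conventionally `"A"` or `"B"`.
#' @param radius_mm spot radius. Default 4.
#' @return `eegdot_spot` with `center`, `voxel_ids`, `label`.
#' @export
activation_spot <- function(sources, center, label = "A", radius_mm = 4) {
  stopifnot(inherits(sources, "eegdot_source_space"), length(center) == 3)
  center <- center / sqrt(sum(center^2)) * sources$radius_mm
  d <- sqrt(colSums((t(sources$positions) - center)^2))
  ids <- which(d <= radius_mm)
  if (length(ids) == 0) ids <- which.min(d)
  structure(
    list(center = center, voxel_ids = as.integer(ids), label = label,
         radius_mm = radius_mm),
    class = "eegdot_spot"
  )
}

#' Response kernels linking the event train to source activity
#'
#' The neural kernel is a unit-peak Gaussian bell (peak 50 ms after the
#' stimulus, 40 ms FWHM); the hemodynamic kernel is a unit-peak canonical
#' double-gamma response (peak ~6 s, undershoot ~16 s, undershoot ratio 1/6).
#' The HbO response follows the kernel; the Hb response is opposite in sign
#' with one third of the amplitude.
#'
#' @param fs_electrical,fs_hemodynamic sampling rates in Hz.
#' @param neural_peak_s,neural_fwhm_s Gaussian bell peak latency and FWHM (s).
#' @param hb_ratio HbO:Hb peak amplitude ratio. Default 3.
#' @return `eegdot_kernels` with `neural`, `hrf` (each `t`, `y`,
#'   `peak_latency_s`) and `hb_ratio`.
#' @export
default_kernels <- function(fs_electrical = 1000, fs_hemodynamic = 10,
                            neural_peak_s = 0.05, neural_fwhm_s = 0.04,
                            hb_ratio = 3) {
  sd_s <- neural_fwhm_s / (2 * sqrt(2 * log(2)))
  t_n <- seq(0, neural_peak_s + 5 * sd_s, by = 1 / fs_electrical)
  y_n <- exp(-(t_n - neural_peak_s)^2 / (2 * sd_s^2))
  y_n <- y_n / max(y_n)

  t_h <- seq(0, 32, by = 1 / fs_hemodynamic)
  y_h <- stats::dgamma(t_h, shape = 6, scale = 1) -
    stats::dgamma(t_h, shape = 16, scale = 1) / 6
  y_h <- y_h / max(y_h)

  structure(
    list(
      neural = list(t = t_n, y = y_n,
                    peak_latency_s = t_n[which.max(y_n)]),
      hrf = list(t = t_h, y = y_h, peak_latency_s = t_h[which.max(y_h)]),
      hb_ratio = hb_ratio
    ),
    class = "eegdot_kernels"
  )
}

# discrete convolution of an impulse train with a kernel, truncated to the
# train length (kernel index 1 aligns with the impulse sample)
convolve_train <- function(train, kernel) {
  n <- length(train)
  p <- length(kernel)
  padded <- c(numeric(p - 1), train)
  out <- stats::filter(padded, kernel, method = "convolution", sides = 1)
  as.numeric(out)[p:(p - 1 + n)]
}

# impulse train on a sampling grid
event_train <- function(onsets_s, fs, n_samples) {
  tr <- numeric(n_samples)
  idx <- round(onsets_s * fs) + 1L
  idx <- idx[idx >= 1 & idx <= n_samples]
  for (i in idx) tr[i] <- tr[i] + 1
  tr
}

#' Simulate co-localized electrical and hemodynamic source activity
#'
#' Each activation spot carries one impulse train (one impulse per trial, at
#' the trial onset plus the spot's within-trial offset). The train is
#' convolved with the neural kernel to give the evoked electrical activity of
#' the spot's voxels, and with the hemodynamic kernel to give the evoked HbO
#' response (`Hb = -HbO / hb_ratio`). I.i.d. Gaussian background activity is
#' added to every source voxel at every sample: its standard deviation is
#' `background["electrical"]` times the maximum single-stimulus evoked
#' electrical amplitude (default 1/20), and `background["hbo"]` /
#' `background["hb"]` times the maximum single-stimulus evoked amplitude of
#' the respective chromophore (defaults 4 and 2). The single-stimulus maxima
#' (the unit-peak kernels) are the reference rather than the superposed block
#' signal, whose hemodynamic plateau stacks ~45 overlapping responses.
#'
#' @param design `eegdot_design`.
#' @param spots list of `eegdot_spot`s (disjoint voxel sets).
#' @param sources `eegdot_source_space`.
#' @param kernels `eegdot_kernels`. Default [default_kernels()] at the
#'   design's sampling rates.
#' @param background named numeric with elements `electrical`, `hbo`, `hb`:
#'   background standard deviations relative to the evoked maxima.
#' @param seed integer RNG seed for the background draws.
#' @return `eegdot_activity`: `electrical` (V x Te), `hbo`, `hb` (V x Th),
#'   `evoked` (the clean per-spot time courses and voxel ids), `event_trains`,
#'   time axes, and the spot list.
#' @export
simulate_sources <- function(design, spots, sources,
                             kernels = NULL,
                             background = c(electrical = 1 / 20, hbo = 4, hb = 2),
                             seed = 1L) {
  stopifnot(inherits(design, "eegdot_design"))
  if (inherits(spots, "eegdot_spot")) spots <- list(spots)
  ids <- unlist(lapply(spots, `[[`, "voxel_ids"))
  if (anyDuplicated(ids)) stop("activation spots must not overlap", call. = FALSE)
  if (is.null(kernels)) {
    kernels <- default_kernels(design$fs_electrical, design$fs_hemodynamic)
  }

  n_vox <- nrow(sources$positions)
  t_e <- round(design$block_duration_s * design$fs_electrical)
  t_h <- round(design$block_duration_s * design$fs_hemodynamic)

  trains_e <- list()
  trains_h <- list()
  evoked_e <- list()
  evoked_h <- list()
  for (sp in spots) {
    onsets <- design$trial_onsets_s + design$spot_offsets_s[[sp$label]]
    trains_e[[sp$label]] <- event_train(onsets, design$fs_electrical, t_e)
    trains_h[[sp$label]] <- event_train(onsets, design$fs_hemodynamic, t_h)
    evoked_e[[sp$label]] <- convolve_train(trains_e[[sp$label]], kernels$neural$y)
    evoked_h[[sp$label]] <- convolve_train(trains_h[[sp$label]], kernels$hrf$y)
  }
  # background scale reference: the maximum amplitude of the evoked response
  # to a single stimulus (the unit-peak kernels), not of the superposed block
  # signal -- at 200 ms trial spacing ~45 hemodynamic responses overlap, and
  # scaling the background to that plateau would drown the evoked activity
  max_e <- max(abs(kernels$neural$y))
  max_hbo <- max(abs(kernels$hrf$y))
  max_hb <- max_hbo / kernels$hb_ratio

  electrical <- matrix(0, n_vox, t_e)
  hbo <- matrix(0, n_vox, t_h)
  hb <- matrix(0, n_vox, t_h)
  for (sp in spots) {
    electrical[sp$voxel_ids, ] <- rep(evoked_e[[sp$label]], each = length(sp$voxel_ids))
    hbo[sp$voxel_ids, ] <- rep(evoked_h[[sp$label]], each = length(sp$voxel_ids))
    hb[sp$voxel_ids, ] <- rep(-evoked_h[[sp$label]] / kernels$hb_ratio,
                              each = length(sp$voxel_ids))
  }

  with_seed(seed, {
    if (background[["electrical"]] > 0 && max_e > 0) {
      electrical <- electrical +
        matrix(stats::rnorm(n_vox * t_e, sd = background[["electrical"]] * max_e),
               n_vox, t_e)
    }
    if (background[["hbo"]] > 0 && max_hbo > 0) {
      hbo <- hbo + matrix(stats::rnorm(n_vox * t_h, sd = background[["hbo"]] * max_hbo),
                          n_vox, t_h)
    }
    if (background[["hb"]] > 0 && max_hb > 0) {
      hb <- hb + matrix(stats::rnorm(n_vox * t_h, sd = background[["hb"]] * max_hb),
                        n_vox, t_h)
    }
  })

  structure(
    list(
      electrical = electrical, hbo = hbo, hb = hb,
      evoked = list(electrical = evoked_e, hbo = evoked_h),
      event_trains = list(electrical = trains_e, hemodynamic = trains_h),
      spots = spots,
      time_electrical = (seq_len(t_e) - 1) / design$fs_electrical,
      time_hemodynamic = (seq_len(t_h) - 1) / design$fs_hemodynamic,
      kernels = kernels, background = background, seed = seed,
      design = design
    ),
    class = "eegdot_activity"
  )
}

#' Project source activity to noisy sensor recordings
#'
#' EEG is the leadfield applied to the electrical activity; DOT optical
#' density changes are the Jacobian applied to the stacked `[HbO; Hb]`
#' activity. Additive i.i.d. Gaussian sensor noise is scaled per modality (and
#' per wavelength for DOT) so that the squared maximum amplitude of the
#' pre-noise signal divided by the noise variance equals the configured SNR.
#'
#' @param activity `eegdot_activity`.
#' @param leadfield `eegdot_leadfield`.
#' @param jacobian `eegdot_jacobian`.
#' @param snr named numeric: `eeg` plus one entry per wavelength (names in
#'   nm). Default `c(eeg = 10, "750" = 10, "850" = 20)`. Use `Inf` for
#'   noiseless recordings.
#' @param seed integer RNG seed for the sensor noise.
#' @return `eegdot_recordings`: `eeg` (E x Te), `dod` ((C*W) x Th), the clean
#'   projections `eeg_clean`, `dod_clean`, noise standard deviations, time
#'   axes, `snr`, `seed`.
#' @export
generate_recordings <- function(activity, leadfield, jacobian,
                                snr = c(eeg = 10, `750` = 10, `850` = 20),
                                seed = 1L) {
  stopifnot(inherits(activity, "eegdot_activity"),
            inherits(leadfield, "eegdot_leadfield"),
            inherits(jacobian, "eegdot_jacobian"))
  L <- leadfield$matrix
  J <- jacobian$matrix
  if (ncol(L) != nrow(activity$electrical)) {
    stop("leadfield and activity dimensions disagree", call. = FALSE)
  }
  if (ncol(J) != 2 * nrow(activity$hbo)) {
    stop("jacobian and activity dimensions disagree", call. = FALSE)
  }

  eeg_clean <- L %*% activity$electrical
  dod_clean <- J %*% rbind(activity$hbo, activity$hb)

  n_ch <- jacobian$n_channels
  wl <- as.character(jacobian$wavelengths)
  sd_eeg <- snr_noise_sd(eeg_clean, snr[["eeg"]])
  sd_wl <- vapply(seq_along(wl), function(w) {
    rows <- (w - 1) * n_ch + seq_len(n_ch)
    snr_noise_sd(dod_clean[rows, , drop = FALSE], snr[[wl[w]]])
  }, numeric(1))

  eeg <- eeg_clean
  dod <- dod_clean
  with_seed(seed, {
    if (sd_eeg > 0) {
      eeg <- eeg + matrix(stats::rnorm(length(eeg), sd = sd_eeg),
                          nrow(eeg), ncol(eeg))
    }
    for (w in seq_along(wl)) {
      if (sd_wl[w] > 0) {
        rows <- (w - 1) * n_ch + seq_len(n_ch)
        dod[rows, ] <- dod[rows, ] +
          matrix(stats::rnorm(n_ch * ncol(dod), sd = sd_wl[w]), n_ch, ncol(dod))
      }
    }
  })

  structure(
    list(
      eeg = eeg, dod = dod,
      eeg_clean = eeg_clean, dod_clean = dod_clean,
      noise_sd = c(eeg = sd_eeg, stats::setNames(sd_wl, wl)),
      snr = snr, seed = seed,
      time_electrical = activity$time_electrical,
      time_hemodynamic = activity$time_hemodynamic,
      design = activity$design,
      n_channels_dot = n_ch,
      wavelengths = jacobian$wavelengths
    ),
    class = "eegdot_recordings"
  )
}

snr_noise_sd <- function(clean, snr) {
  if (is.infinite(snr)) return(0)
  if (snr <= 0) stop("SNR must be positive", call. = FALSE)
  a <- max(abs(clean))
  if (a == 0) return(0)
  a / sqrt(snr)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
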