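#' Reconstruction map container
#'
#' Per-voxel amplitudes of a source reconstruction, either a single map
#' (one column) or a per-timestep series. `values` are raw solver outputs;
#' `normalized` marks maps scaled to unit maximum absolute amplitude.
#'
#' @param values numeric vector (V) or matrix (V x T).
#' @param modality `"eeg"`, `"dot_hbo"`, `"dot_hb"`, or `"projection"`.
#' @param time optional time axis (s) for map series.
#' @param normalized logical flag.
#' @return `eegdot_map`.
#' @export
reconstruction_map <- function(values, modality, time = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  structure(list(values = values, modality = modality, time = time,
                 normalized = normalized),
            class = "eegdot_map")
}

#' Scale each map (column) to unit maximum absolute amplitude
#' @param map `eegdot_map`.
#' @return normalized `eegdot_map` (all-zero columns are left at zero).
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "eegdot_map"))
  v <- map$values
  mx <- apply(abs(v), 2, max)
  mx[mx == 0] <- 1
  map$values <- sweep(v, 2, mx, "/")
  map$normalized <- TRUE
  map
}

#' Trial-average EEG preprocessing
#'
#' Cuts the continuous EEG into trial epochs (one inter-trial interval long,
#' starting at each trial onset) and averages them, suppressing background and
#' sensor noise by roughly the square root of the trial count.
#'
#' @param recordings `eegdot_recordings` (or a bare E x T matrix with `fs`).
#' @param design `eegdot_design`.
#' @param fs sampling rate, required when `recordings` is a bare matrix.
#' @return list: `data` (E x L averaged trial), `time` (s within trial),
#'   `n_trials` averaged.
#' @export
preprocess_eeg <- function(recordings, design, fs = NULL) {
  stopifnot(inherits(design, "eegdot_design"))
  if (inherits(recordings, "eegdot_recordings")) {
    x <- recordings$eeg
    fs <- design$fs_electrical
  } else {
    x <- as.matrix(recordings)
    if (is.null(fs)) stop("`fs` required for matrix input", call. = FALSE)
  }
  len <- round(design$trial_spacing_s * fs)
  starts <- round(design$trial_onsets_s * fs) + 1L
  starts <- starts[starts + len - 1L <= ncol(x)]
  if (length(starts) == 0) stop("no complete trials in the recording", call. = FALSE)
  acc <- matrix(0, nrow(x), len)
  for (s in starts) acc <- acc + x[, s:(s + len - 1L), drop = FALSE]
  list(
    data = acc / length(starts),
    time = (seq_len(len) - 1) / fs,
    n_trials = length(starts)
  )
}

#' Block-average DOT preprocessing
#'
#' Low-pass filters each optical-density channel (zero-phase second-order
#' Butterworth, 1 Hz cutoff by default) and averages over a post-onset
#' response window covering the bulk of the hemodynamic response.
#'
#' @param recordings `eegdot_recordings` or a bare (C*W) x T matrix.
#' @param design `eegdot_design`.
#' @param cutoff_hz low-pass cutoff. Default 1.
#' @param window_s averaging window (s, relative to block start). Default
#'   `c(2, 25)`.
#' @param fs sampling rate, required for matrix input.
#' @return numeric vector of block-averaged optical density changes (C*W).
#' @export
preprocess_dot <- function(recordings, design, cutoff_hz = 1,
                           window_s = c(2, 25), fs = NULL) {
  stopifnot(inherits(design, "eegdot_design"))
  if (inherits(recordings, "eegdot_recordings")) {
    x <- recordings$dod
    fs <- design$fs_hemodynamic
  } else {
    x <- as.matrix(recordings)
    if (is.null(fs)) stop("`fs` required for matrix input", call. = FALSE)
  }
  if (fs <= 2 * cutoff_hz) {
    stop("sampling rate must exceed twice the filter cutoff", call. = FALSE)
  }
  xf <- butter_lowpass(x, cutoff_hz, fs)
  idx <- which((seq_len(ncol(x)) - 1) / fs >= window_s[1] &
                 (seq_len(ncol(x)) - 1) / fs <= window_s[2])
  if (length(idx) == 0) stop("averaging window contains no samples", call. = FALSE)
  rowMeans(xf[, idx, drop = FALSE])
}

# zero-phase (forward-backward) order-2 Butterworth low-pass, row-wise
butter_lowpass <- function(x, cutoff_hz, fs) {
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
}

#' EEG source reconstruction (uniform or DOT-informed prior)
#'
#' Applies the covariance-component solver independently to every timestep of
#' the averaged trial. Sensor noise is modeled as i.i.d. (a single identity
#' noise component). With a uniform prior the sources are i.i.d. too (identity
#' prior component: the EEG-only scheme). With [build_dot_prior()] /
#' [projection_prior()] weights, the prior component is the diagonal matrix of
#' per-voxel weights, so voxels that were active in the hemodynamic
#' reconstruction are allowed larger variance.
#'
#' @param avg_trial averaged-trial matrix (E x L) or the list returned by
#'   [preprocess_eeg()].
#' @param leadfield `eegdot_leadfield`.
#' @param prior `NULL` for the uniform (EEG-only) prior, or an `eegdot_prior`.
#' @param timesteps optional integer indices of the columns to reconstruct
#'   (default: all).
#' @param tol,max_iter solver options, see [reml_fit()].
#' @return `eegdot_map` series (V x length(timesteps), raw amplitudes) with
#'   the trial time axis; normalize with [normalize_map()] for display.
#' @export
reconstruct_eeg <- function(avg_trial, leadfield, prior = NULL,
                            timesteps = NULL, tol = 1e-6, max_iter = 128L) {
  tm <- NULL
  if (is.list(avg_trial) && !is.null(avg_trial$data)) {
    tm <- avg_trial$time
    avg_trial <- avg_trial$data
  }
  stopifnot(inherits(leadfield, "eegdot_leadfield"))
  L <- leadfield$matrix
  if (max(abs(L)) == 0) stop("leadfield is identically zero", call. = FALSE)
  p <- ncol(L)
  q <- if (is.null(prior)) rep(1, p) else prior_weights(prior, p)
  if (is.null(timesteps)) timesteps <- seq_len(ncol(avg_trial))

  noise <- covariance_model(list(rep(1, nrow(L))), side = "noise")
  pr <- covariance_model(list(q), side = "prior")
  out <- matrix(0, p, length(timesteps))
  for (i in seq_along(timesteps)) {
    y <- avg_trial[, timesteps[i], drop = FALSE]
    if (max(abs(y)) == 0) next
    fit <- reml_fit(y, L, noise, pr, tol = tol, max_iter = max_iter)
    out[, i] <- fit$beta_hat
  }
  reconstruction_map(out, "eeg",
                     time = if (!is.null(tm)) tm[timesteps] else NULL)
}

#' DOT source reconstruction
#'
#' Covariance-component solve of the block-averaged optical-density vector.
#' Sensor noise is i.i.d. within each wavelength with its own variance (two
#' noise components); HbO and Hb source activity are each i.i.d. with their
#' own variances (two prior components). Optionally the identity prior blocks
#' are replaced with a Gaussian spatial-smoothness kernel
#' `G[i, j] = exp(-||ri - rj||^2 / sigma^2)`.
#'
#' @param dod_avg block-averaged optical-density vector (C*W).
#' @param jacobian `eegdot_jacobian`.
#' @param positions V x 3 source positions (needed for smoothing only).
#' @param smoothing_sigma_mm `NULL` (i.i.d. priors) or the Gaussian kernel
#'   scale in mm.
#' @param tol,max_iter solver options.
#' @return list of two single-map `eegdot_map`s, `hbo` and `hb`, max-normalized.
#' @export
reconstruct_dot <- function(dod_avg, jacobian, positions = NULL,
                            smoothing_sigma_mm = NULL,
                            tol = 1e-6, max_iter = 128L) {
  stopifnot(inherits(jacobian, "eegdot_jacobian"))
  J <- jacobian$matrix
  if (length(dod_avg) != nrow(J)) {
    stop("dod_avg length must equal the Jacobian row count (channels x wavelengths)",
         call. = FALSE)
  }
  n_ch <- jacobian$n_channels
  n_wl <- length(jacobian$wavelengths)
  v <- ncol(J) / 2

  noise_comps <- lapply(seq_len(n_wl), function(w) {
    d <- numeric(n_ch * n_wl)
    d[(w - 1) * n_ch + seq_len(n_ch)] <- 1
    d
  })
  if (is.null(smoothing_sigma_mm)) {
    prior_comps <- lapply(1:2, function(cc) {
      d <- numeric(2 * v)
      d[(cc - 1) * v + seq_len(v)] <- 1
      d
    })
  } else {
    if (is.null(positions)) stop("`positions` required for smoothing", call. = FALSE)
    G <- smoothness_kernel(positions, smoothing_sigma_mm)
    prior_comps <- lapply(1:2, function(cc) {
      M <- matrix(0, 2 * v, 2 * v)
      idx <- (cc - 1) * v + seq_len(v)
      M[idx, idx] <- G
      M
    })
  }

  fit <- reml_fit(matrix(dod_avg, ncol = 1), J,
                  covariance_model(noise_comps, side = "noise"),
                  covariance_model(prior_comps, side = "prior"),
                  tol = tol, max_iter = max_iter)
  list(
    hbo = normalize_map(reconstruction_map(fit$beta_hat[seq_len(v)], "dot_hbo")),
    hb = normalize_map(reconstruction_map(fit$beta_hat[v + seq_len(v)], "dot_hb")),
    fit = fit
  )
}

#' Gaussian spatial-smoothness kernel
#'
#' `G[i, j] = exp(-||ri - rj||^2 / sigma^2)`; in the `sigma -> 0` limit this
#' is the identity.
#'
#' @param positions V x 3 (mm). @param sigma_mm kernel scale (> 0).
#' @return V x V matrix.
#' @export
smoothness_kernel <- function(positions, sigma_mm) {
  if (sigma_mm <= 0) stop("`sigma_mm` must be positive", call. = FALSE)
  d <- cross_dist(positions, positions)
  diag(d) <- 0  # self-distances suffer floating cancellation in cross_dist
  exp(-(d / sigma_mm)^2)
}

#' DOT-reconstruction spatial prior for EEG
#'
#' Converts a (max-normalized) HbO reconstruction map into per-voxel prior
#' variance weights. Amplitudes below the threshold `k` are zeroed (removing
#' low-amplitude ripples); the weights are
#' `q_i = 1 - exp(-(b'_i + a) / b)` with `b'` the thresholded normalized
#' amplitudes, so every voxel keeps a baseline variance `1 - exp(-a/b)` and
#' strongly active voxels approach `1 - exp(-(1 + a)/b)`.
#'
#' @param hbo_map `eegdot_map` (single map) or numeric vector of amplitudes.
#' @param k amplitude threshold on the normalized map, in `[0, 1)`. Default 0.1.
#' @param a baseline parameter (> 0). Default 0.1; use 0.25 with 64-channel
#'   EEG montages.
#' @param b dynamic-range parameter (> 0). Default 1.
#' @return `eegdot_prior`: `q_diag` (per-voxel weights in (0, 1]), `params`,
#'   and the thresholded normalized map `beta_prime`.
#' @examples
#' build_dot_prior(c(0, 1), a = 0.1, b = 1)$q_diag  # 0.09516, 0.66713
#' @export
build_dot_prior <- function(hbo_map, k = 0.1, a = 0.1, b = 1) {
  if (b <= 0) stop("`b` must be positive", call. = FALSE)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (k < 0 || k >= 1) stop("`k` must lie in [0, 1)", call. = FALSE)
  v <- if (inherits(hbo_map, "eegdot_map")) hbo_map$values[, 1] else as.numeric(hbo_map)
  v <- abs(v)
  if (max(v) > 0) v <- v / max(v)
  beta_prime <- v * (v > k)
  q <- 1 - exp(-(beta_prime + a) / b)
  structure(
    list(q_diag = q, params = list(k = k, a = a, b = b), beta_prime = beta_prime,
         source = "dot_reconstruction"),
    class = "eegdot_prior"
  )
}

prior_weights <- function(prior, p) {
  stopifnot(inherits(prior, "eegdot_prior"))
  if (length(prior$q_diag) != p) {
    stop("prior weight length does not match the source space", call. = FALSE)
  }
  prior$q_diag
}

#' Modified Beer-Lambert law channel conversion
#'
#' Converts per-channel optical-density changes at two wavelengths to
#' chromophore concentration changes by inverting the 2 x 2 extinction system
#' `dOD(lambda) = ln(10) eps(lambda, c) DPF(lambda) d * dC`.
#'
#' @param dod_avg optical-density vector (C*W, wavelength blocks stacked).
#' @param distances_mm per-channel source-detector distances (mm).
#' @param wavelengths wavelengths (nm), in block order.
#' @param extinction extinction matrix from [hemoglobin_extinction()].
#' @param dpf named differential pathlength factors per wavelength.
#' @return matrix C x 2 with columns `hbo`, `hb`.
#' @export
mbll <- function(dod_avg, distances_mm, wavelengths = c(750, 850),
                 extinction = hemoglobin_extinction(wavelengths),
                 dpf = c(`750` = 6, `850` = 5)) {
  n_ch <- length(distances_mm)
  n_wl <- length(wavelengths)
  if (length(dod_avg) != n_ch * n_wl) {
    stop("dod_avg length must be channels x wavelengths", call. = FALSE)
  }
  wl <- as.character(wavelengths)
  E <- log(10) * extinction[wl, c("hbo", "hb"), drop = FALSE] * dpf[wl]
  if (abs(det(E)) < 1e-12 * max(abs(E))^2) {
    stop("extinction/pathlength system is singular", call. = FALSE)
  }
  out <- matrix(0, n_ch, 2, dimnames = list(NULL, c("hbo", "hb")))
  for (ch in seq_len(n_ch)) {
    y <- dod_avg[(seq_len(n_wl) - 1) * n_ch + ch]
    out[ch, ] <- solve(E * distances_mm[ch], y)
  }
  out
}

#' Cortical-projection spatial prior (baseline method)
#'
#' The simpler prior used as a comparison to the DOT-reconstruction prior:
#' per-channel HbO changes are computed with the modified Beer-Lambert law,
#' placed at each channel's source-detector midpoint projected radially onto
#' the cortical shell, and interpolated over the source space with a Gaussian
#' kernel. The interpolated map is normalized and passed through the same
#' weighting function as [build_dot_prior()].
#'
#' @param dod_avg block-averaged optical-density vector (C*W).
#' @param optodes `eegdot_optodes`.
#' @param sources `eegdot_source_space`.
#' @param sigma_mm Gaussian interpolation scale (mm). Default 15.
#' @param k,a,b weighting parameters, as in [build_dot_prior()].
#' @param wavelengths,extinction,dpf see [mbll()].
#' @return `eegdot_prior` with the interpolated normalized `map` attached.
#' @export
projection_prior <- function(dod_avg, optodes, sources, sigma_mm = 15,
                             k = 0.1, a = 0.1, b = 1,
                             wavelengths = c(750, 850),
                             extinction = hemoglobin_extinction(wavelengths),
                             dpf = c(`750` = 6, `850` = 5)) {
  stopifnot(inherits(optodes, "eegdot_optodes"),
            inherits(sources, "eegdot_source_space"))
  ch <- optodes$channels
  conc <- mbll(dod_avg, optodes$distances_mm, wavelengths, extinction, dpf)
  mid <- (optodes$source_positions[ch[, 1], , drop = FALSE] +
            optodes$detector_positions[ch[, 2], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2)) * sources$radius_mm
  d <- cross_dist(sources$positions, mid)      # V x C
  w <- exp(-(d / sigma_mm)^2)
  map <- as.numeric(w %*% conc[, "hbo"])
  if (max(abs(map)) > 0) map <- map / max(abs(map))
  pr <- build_dot_prior(map, k = k, a = a, b = b)
  pr$source <- "projection"
  pr$map <- reconstruction_map(map, "projection", normalized = TRUE)
  pr
}
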