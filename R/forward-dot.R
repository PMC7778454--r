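#' Hemoglobin extinction coefficients
#'
#' Molar decadic extinction coefficients (1/(cm*M)) of oxygenated and
#' deoxygenated hemoglobin at the model wavelengths, read from the packaged
#' table (`inst/extdata/hemoglobin_extinction.csv`).
#'
#' @param wavelengths numeric, wavelengths in nm that must be present in the
#'   table. Default `c(750, 850)`.
#' @return matrix with rows named by wavelength and columns `hbo`, `hb`.
#' @export
hemoglobin_extinction <- function(wavelengths = c(750, 850)) {
  path <- system.file("extdata", "hemoglobin_extinction.csv", package = "eegdot")
  tab <- utils::read.csv(path, comment.char = "#")
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) {
    stop("extinction table has no entry for wavelength(s) ",
         paste(wavelengths[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- as.matrix(tab[idx, c("hbo", "hb")])
  rownames(out) <- as.character(wavelengths)
  out
}

#' Continuous-wave DOT Jacobian for the spherical phantom
#'
#' Rytov sensitivity of log-intensity (optical density) changes to voxel-wise
#' chromophore concentration changes, built from diffusion-approximation
#' Green's functions of a semi-infinite homogeneous medium fitted to the scalp
#' patch. Each optode is replaced by an isotropic source buried one transport
#' mean free path below its scalp point (plus a mirrored image source above an
#' extrapolated boundary); the per-voxel absorption sensitivity of a channel
#' is the classical three-point kernel
#' `G(source -> voxel) * G(voxel -> detector) / G(source -> detector)`,
#' scaled by the voxel volume. Chromophore columns are the absorption
#' sensitivities scaled by `ln(10)` times the molar extinction coefficients at
#' each wavelength, so the matrix maps `[dHbO; dHb]` (concentration changes)
#' to `dOD` (natural-log optical density changes), wavelength blocks stacked
#' row-wise.
#'
#' @param head_or_model `eegdot_head` or `eegdot_head_model`.
#' @param optodes `eegdot_optodes` from [place_sensors()].
#' @param sources `eegdot_source_space`; defaults to the head's own.
#' @param extinction extinction matrix as from [hemoglobin_extinction()].
#' @param boundary_A internal-reflection parameter of the extrapolated
#'   boundary (`z_b = 2 A D`). Default 2.95 (tissue/air, n ~ 1.4).
#' @param voxel_thickness_mm thickness assigned to the cortical-shell voxels
#'   when converting sensitivities to volume integrals. Default 2.
#' @return An `eegdot_jacobian`: `matrix` ((C*W) x (V*2)), `wavelengths`,
#'   `n_channels`, `extinction_coeffs`, `channel_midpoints_cortex` (C x 3 mm,
#'   source-detector midpoints projected radially onto the cortical shell),
#'   `distances_mm`.
#' @examples
#' hm <- build_spherical_head(n_sources = 600)
#' opt <- place_sensors(hm, "dot_regular")
#' J <- compute_dot_jacobian(hm, opt)
#' dim(J$matrix)  # 48 x 1200
#' @export
compute_dot_jacobian <- function(head_or_model, optodes, sources = NULL,
                                 extinction = hemoglobin_extinction(),
                                 boundary_A = 2.95,
                                 voxel_thickness_mm = 2) {
  head <- if (inherits(head_or_model, "eegdot_head")) head_or_model$head else head_or_model
  if (is.null(sources) && inherits(head_or_model, "eegdot_head")) {
    sources <- head_or_model$sources
  }
  stopifnot(inherits(optodes, "eegdot_optodes"),
            inherits(sources, "eegdot_source_space"))
  r_scalp <- unname(head$shell_radii["scalp"])
  opt_r <- c(sqrt(rowSums(optodes$source_positions^2)),
             sqrt(rowSums(optodes$detector_positions^2)))
  if (max(abs(opt_r - r_scalp)) > 1e-6 * r_scalp) {
    stop("optodes must lie on the scalp shell", call. = FALSE)
  }

  wl <- as.character(head$wavelengths)
  ext <- extinction[wl, , drop = FALSE]
  ch <- optodes$channels
  n_ch <- nrow(ch)
  vox <- sources$positions
  n_vox <- nrow(vox)
  vol <- sources$spacing_mm^2 * voxel_thickness_mm

  blocks <- vector("list", length(wl))
  for (w in seq_along(wl)) {
    op <- head$optical_props[[wl[w]]]
    if (op$musp <= 0) stop("reduced scattering coefficient must be > 0", call. = FALSE)
    mua <- op$mua
    musp <- op$musp
    D <- 1 / (3 * (mua + musp))
    mueff <- sqrt(mua / D)
    z0 <- 1 / (mua + musp)
    zb <- 2 * boundary_A * D

    bury <- function(p) p * (r_scalp - z0) / r_scalp
    mirror <- function(p) p * (r_scalp + z0 + 2 * zb) / r_scalp
    gf <- function(d) exp(-mueff * d) / (4 * pi * D * pmax(d, 1e-9))
    gpair <- function(real, image, q) {
      gf(cross_dist(real, q)) - gf(cross_dist(image, q))
    }

    src_fl <- gpair(bury(optodes$source_positions),
                    mirror(optodes$source_positions), vox)   # nS x V
    det_fl <- gpair(bury(optodes$detector_positions),
                    mirror(optodes$detector_positions), vox) # nD x V
    # per-channel direct fluence: evaluate pairwise on matched rows
    phi0 <- numeric(n_ch)
    bs <- bury(optodes$source_positions)
    ms <- mirror(optodes$source_positions)
    bd <- bury(optodes$detector_positions)
    for (k in seq_len(n_ch)) {
      d1 <- sqrt(sum((bs[ch[k, 1], ] - bd[ch[k, 2], ])^2))
      d2 <- sqrt(sum((ms[ch[k, 1], ] - bd[ch[k, 2], ])^2))
      phi0[k] <- gf(d1) - gf(d2)
    }
    sens <- (src_fl[ch[, 1], , drop = FALSE] * det_fl[ch[, 2], , drop = FALSE]) /
      phi0 * vol                                             # C x V, per unit mua
    blocks[[w]] <- cbind(sens * (log(10) * ext[w, "hbo"]),
                         sens * (log(10) * ext[w, "hb"]))
  }
  J <- do.call(rbind, blocks)
  rownames(J) <- paste0(
    rep(wl, each = n_ch), "nm_ch",
    rep(seq_len(n_ch), times = length(wl))
  )

  mid <- (optodes$source_positions[ch[, 1], , drop = FALSE] +
            optodes$detector_positions[ch[, 2], , drop = FALSE]) / 2
  mid_cortex <- mid / sqrt(rowSums(mid^2)) * sources$radius_mm

  structure(
    list(
      matrix = J,
      wavelengths = head$wavelengths,
      n_channels = n_ch,
      n_voxels = n_vox,
      extinction_coeffs = ext,
      channel_midpoints_cortex = mid_cortex,
      distances_mm = optodes$distances_mm,
      voxel_volume_mm3 = vol
    ),
    class = "eegdot_jacobian"
  )
}

#' @export
print.eegdot_jacobian <- function(x, ...) {
  cat(sprintf(
    "DOT Jacobian: %d channels x %d wavelengths -> %d voxels x 2 chromophores\n",
    x$n_channels, length(x$wavelengths), x$n_voxels
  ))
  invisible(x)
}
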