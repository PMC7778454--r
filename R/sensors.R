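#' Place EEG electrodes or DOT optodes on the scalp shell
#'
#' EEG layouts follow the 10-20 / 10-10 angular scheme: electrodes are defined
#' by inclination from the vertex and azimuth around it, then mapped radially
#' to the scalp sphere. DOT layouts are rectangular source/detector
#' checkerboards laid out in the tangent plane of a right-lateral cortical
#' patch (centered at 45 degrees elevation on the right hemisphere, over the
#' sensorimotor analogue of the phantom) and projected radially onto the
#' scalp. Channels are nearest-neighbour source-detector pairs.
#'
#' Layouts:
#' \describe{
#'   \item{`eeg32`, `eeg64`}{32- or 64-electrode 10-20/10-10 montages.}
#'   \item{`dot_regular`}{4x4 checkerboard, 22 mm spacing, 24 channels with
#'     source-detector distances in 17-27 mm.}
#'   \item{`dot_regular_plus_detector`}{the regular grid plus one extra
#'     detector beyond the lateral edge, adding two channels (26 total).}
#'   \item{`dot_high_density`}{6x6 checkerboard, 13 mm spacing, 60 channels
#'     with distances in 7.5-29 mm.}
#' }
#'
#' @param head_or_model an `eegdot_head` (from [build_spherical_head()]) or a
#'   bare `eegdot_head_model`.
#' @param layout one of `"eeg32"`, `"eeg64"`, `"dot_regular"`,
#'   `"dot_high_density"`, `"dot_regular_plus_detector"`.
#' @param patch_elevation_deg elevation (degrees above the equator) of the DOT
#'   patch center on the right hemisphere. Default 45.
#' @return For EEG layouts an `eegdot_electrodes` object (`positions` E x 3 mm,
#'   `labels`); for DOT layouts an `eegdot_optodes` object with
#'   `source_positions`, `detector_positions`, `channels` (two-column matrix of
#'   source/detector indices), per-channel `distances_mm`, `density`, and the
#'   patch geometry (`patch_center_dir`, `patch_basis`, `patch_halfwidth_mm`).
#' @examples
#' hm <- build_spherical_head(n_sources = 600)
#' opt <- place_sensors(hm, "dot_regular")
#' nrow(opt$channels)       # 24
#' range(opt$distances_mm)  # within 17-27 mm
#' @export
place_sensors <- function(head_or_model, layout,
                          patch_elevation_deg = 45) {
  head <- if (inherits(head_or_model, "eegdot_head")) head_or_model$head else head_or_model
  if (!inherits(head, "eegdot_head_model")) {
    stop("first argument must come from build_spherical_head()", call. = FALSE)
  }
  layout <- match.arg(layout, c(
    "eeg32", "eeg64", "dot_regular", "dot_high_density",
    "dot_regular_plus_detector"
  ))
  r_scalp <- unname(head$shell_radii["scalp"])

  if (layout %in% c("eeg32", "eeg64")) {
    tab <- electrode_angles(if (layout == "eeg32") 32L else 64L)
    incl <- tab$incl * pi / 180
    az <- tab$az * pi / 180
    pos <- r_scalp * cbind(
      x = sin(incl) * cos(az),
      y = sin(incl) * sin(az),
      z = cos(incl)
    )
    rownames(pos) <- tab$label
    return(structure(
      list(positions = pos, labels = tab$label, layout = layout),
      class = "eegdot_electrodes"
    ))
  }

  el <- patch_elevation_deg * pi / 180
  center_dir <- c(cos(el), 0, sin(el))  # right hemisphere (+x), elevated
  grid <- switch(layout,
    dot_regular = dot_checkerboard(4L, 22),
    dot_regular_plus_detector = dot_checkerboard(4L, 22, extra_detector = TRUE),
    dot_high_density = dot_checkerboard(6L, 13)
  )
  src <- tangent_to_sphere(center_dir, grid$src_uv, r_scalp)
  det <- tangent_to_sphere(center_dir, grid$det_uv, r_scalp)
  d <- sqrt(rowSums((src[grid$channels[, 1], , drop = FALSE] -
                       det[grid$channels[, 2], , drop = FALSE])^2))
  structure(
    list(
      source_positions = src,
      detector_positions = det,
      channels = grid$channels,
      distances_mm = d,
      density = if (layout == "dot_high_density") "high" else "regular",
      layout = layout,
      patch_center_dir = center_dir,
      patch_basis = tangent_basis(center_dir),
      patch_halfwidth_mm = grid$halfwidth
    ),
    class = "eegdot_optodes"
  )
}

# Checkerboard optode grid in tangent-plane mm coordinates. Sources occupy
# (row+col) even cells. Channels are the nearest-neighbour edges; the optional
# extra detector sits beyond the +u edge, 25.1 mm (tangent) from two edge
# sources, adding exactly two channels.
dot_checkerboard <- function(n, spacing, extra_detector = FALSE) {
  idx <- expand.grid(i = seq_len(n) - 1L, j = seq_len(n) - 1L)
  uv <- cbind(
    u = (idx$j - (n - 1) / 2) * spacing,
    v = (idx$i - (n - 1) / 2) * spacing
  )
  is_src <- (idx$i + idx$j) %% 2L == 0L
  src_uv <- uv[is_src, , drop = FALSE]
  det_uv <- uv[!is_src, , drop = FALSE]
  if (extra_detector) {
    # beyond the +u edge, equidistant from the two sources in the last column
    extra <- c((n - 1) / 2 * spacing + 12, 0.5 * spacing)
    det_uv <- rbind(det_uv, extra)
  }
  d <- cross_dist(src_uv, det_uv)
  hit <- which(d <= sqrt(2) * spacing * 0.999 & d > 0, arr.ind = TRUE)
  # keep axis-aligned neighbours (distance == spacing) and the extra-detector
  # links (distance between spacing and sqrt(2)*spacing)
  keep <- d[hit] <= spacing * 1.0001 |
    (extra_detector & hit[, 2] == nrow(det_uv))
  channels <- unname(hit[keep, , drop = FALSE])
  channels <- channels[order(channels[, 1], channels[, 2]), , drop = FALSE]
  colnames(channels) <- c("source", "detector")
  rownames(src_uv) <- paste0("S", seq_len(nrow(src_uv)))
  rownames(det_uv) <- paste0("D", seq_len(nrow(det_uv)))
  list(
    src_uv = src_uv, det_uv = det_uv, channels = channels,
    halfwidth = (n - 1) / 2 * spacing
  )
}

# 10-20 / 10-10 electrode angles. Inclination is degrees from the vertex
# (Cz = 0, outer ring = 92); azimuth is degrees in the xy-plane from the right
# ear axis (+x), counterclockwise seen from above (+y anterior).
electrode_angles <- function(n_channels) {
  ring <- function(label, az) data.frame(label = label, incl = 92, az = az)
  below <- function(label, az) data.frame(label = label, incl = 102, az = az)
  # midline labels: inclination as a fraction of the outer-ring inclination
  mid <- function(label, frac, front) {
    data.frame(label = label, incl = 92 * frac, az = if (front) 90 else 270)
  }
  inner <- function(label, row_frac, k, left, front) {
    y <- row_frac * (if (front) 1 else -1)
    x <- 0.245 * k * sqrt(max(0, 1 - row_frac^2)) * (if (left) -1 else 1)
    r <- sqrt(x^2 + y^2)
    data.frame(label = label, incl = 92 * r,
               az = (atan2(y, x) * 180 / pi) %% 360)
  }
  rows <- list(AF = 0.75, F = 0.5, FC = 0.25, CP = 0.25, P = 0.5, PO = 0.75)
  front <- c(AF = TRUE, F = TRUE, FC = TRUE, CP = FALSE, P = FALSE, PO = FALSE)

  inner_lab <- function(prefix, num) {
    k <- ceiling(num / 2)
    left <- num %% 2 == 1
    inner(paste0(prefix, num), rows[[prefix]], k, left, front = front[[prefix]])
  }
  # C row sits on the equatorial line of the disc (y = 0)
  c_lab <- function(num) {
    k <- ceiling(num / 2)
    left <- num %% 2 == 1
    x <- 0.245 * k * (if (left) -1 else 1)
    data.frame(label = paste0("C", num), incl = 92 * abs(x),
               az = if (left) 180 else 0)
  }

  base32 <- rbind(
    ring("Fp1", 108), ring("Fp2", 72),
    inner_lab("AF", 3), inner_lab("AF", 4),
    ring("F7", 144), inner_lab("F", 3),
    mid("Fz", 0.5, TRUE), inner_lab("F", 4), ring("F8", 36),
    inner_lab("FC", 5), inner_lab("FC", 1), inner_lab("FC", 2), inner_lab("FC", 6),
    ring("T7", 180), c_lab(3), data.frame(label = "Cz", incl = 0, az = 0),
    c_lab(4), ring("T8", 0),
    inner_lab("CP", 5), inner_lab("CP", 1), inner_lab("CP", 2), inner_lab("CP", 6),
    ring("P7", 216), inner_lab("P", 3), mid("Pz", 0.5, FALSE),
    inner_lab("P", 4), ring("P8", 324),
    inner_lab("PO", 3), inner_lab("PO", 4),
    ring("O1", 252), mid("Oz", 1, FALSE), ring("O2", 288)
  )
  if (n_channels == 32L) return(base32)

  extra32 <- rbind(
    mid("Fpz", 1, TRUE), mid("AFz", 0.75, TRUE), mid("FCz", 0.25, TRUE),
    mid("CPz", 0.25, FALSE), mid("POz", 0.75, FALSE),
    ring("AF7", 126), ring("AF8", 54),
    inner_lab("F", 1), inner_lab("F", 2), inner_lab("F", 5), inner_lab("F", 6),
    inner_lab("FC", 3), inner_lab("FC", 4),
    ring("FT7", 162), ring("FT8", 18),
    c_lab(1), c_lab(2), c_lab(5), c_lab(6),
    inner_lab("CP", 3), inner_lab("CP", 4),
    ring("TP7", 198), ring("TP8", 342),
    inner_lab("P", 1), inner_lab("P", 2), inner_lab("P", 5), inner_lab("P", 6),
    ring("PO7", 234), ring("PO8", 306),
    below("TP9", 198), below("TP10", 342), below("Iz", 270)
  )
  rbind(base32, extra32)
}

#' @export
print.eegdot_electrodes <- function(x, ...) {
  cat(sprintf("EEG montage '%s': %d electrodes on the scalp shell\n",
              x$layout, nrow(x$positions)))
  invisible(x)
}

#' @export
print.eegdot_optodes <- function(x, ...) {
  cat(sprintf(
    "DOT grid '%s': %d sources, %d detectors, %d channels (SD %.1f-%.1f mm)\n",
    x$layout, nrow(x$source_positions), nrow(x$detector_positions),
    nrow(x$channels), min(x$distances_mm), max(x$distances_mm)
  ))
  invisible(x)
}
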