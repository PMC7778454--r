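#' Valid voxels at half maximum
#'
#' Voxels whose absolute amplitude is at least half the maximum absolute
#' amplitude of the map (inclusive threshold) -- the full-width-half-maximum
#' support used by the bias-spread metric.
#'
#' @param values numeric per-voxel amplitudes (signed allowed).
#' @return integer indices of valid voxels; empty (with a warning) for an
#'   all-zero map.
#' @examples
#' half_max_voxels(c(1.0, 0.6, 0.4))  # 1 2
#' @export
half_max_voxels <- function(values) {
  a <- abs(values)
  mx <- max(a)
  if (mx == 0) {
    warning("all-zero map: no valid voxels")
    return(integer(0))
  }
  which(a >= 0.5 * mx)
}

#' Bias, spread and BSM of a set of valid voxels
#'
#' `bias` is the Euclidean distance (mm) from the unweighted center of mass of
#' the valid voxels to the true activation center; `spread` is the mean square
#' distance (mm^2) of the valid voxels to that center of mass; the bias-spread
#' metric is `BSM = sqrt(bias^2 + spread)` (mm).
#'
#' @param valid integer indices into `positions`.
#' @param positions V x 3 voxel positions (mm).
#' @param true_center length-3 true activation center (mm).
#' @param weights optional per-voxel amplitudes for an amplitude-weighted
#'   center of mass (off by default; the standard metric is unweighted).
#' @return `eegdot_bsm`: `bias`, `spread`, `bsm`, `detected`, `center_of_mass`,
#'   `valid_voxel_ids`.
#' @examples
#' pos <- rbind(c(0, 0, 0), c(2, 0, 0))
#' bias_spread(1:2, pos, c(1, 0, 0))  # bias 0, spread 1, bsm 1
#' @export
bias_spread <- function(valid, positions, true_center, weights = NULL) {
  if (length(valid) == 0) stop("empty valid-voxel set: BSM undefined", call. = FALSE)
  pts <- positions[valid, , drop = FALSE]
  if (is.null(weights)) {
    com <- colMeans(pts)
  } else {
    w <- abs(weights[valid])
    com <- colSums(pts * w) / sum(w)
  }
  bias <- sqrt(sum((com - true_center)^2))
  spread <- mean(rowSums((pts - matrix(com, nrow(pts), 3, byrow = TRUE))^2))
  structure(
    list(
      bias = bias, spread = spread, bsm = sqrt(bias^2 + spread),
      detected = TRUE, center_of_mass = com,
      valid_voxel_ids = as.integer(valid)
    ),
    class = "eegdot_bsm"
  )
}

undetected_bsm <- function() {
  structure(
    list(bias = NA_real_, spread = NA_real_, bsm = NA_real_,
         detected = FALSE, center_of_mass = rep(NA_real_, 3),
         valid_voxel_ids = integer(0)),
    class = "eegdot_bsm"
  )
}

#' Two-spot detection and per-spot BSM
#'
#' Applies the two-spot rule to a reconstruction map. Normally the half-max
#' valid voxels are partitioned by their nearer true center (ties to spot A)
#' and each spot's bias/spread is computed from its own subset. Two degenerate
#' "single reconstructed region" cases are handled specially: when every valid
#' voxel is nearer one center, the other spot is reported undetected; when the
#' valid set forms a single lattice-contiguous blob that straddles both
#' centers, the whole blob is used for both spots' bias and spread.
#' Contiguity is decided by single-linkage clustering with a merge distance of
#' 1.5x the lattice spacing (i.e. blobs are sets of adjacent voxels).
#'
#' @param values per-voxel reconstruction amplitudes.
#' @param positions V x 3 voxel positions (mm).
#' @param spot_a,spot_b `eegdot_spot`s or length-3 centers (mm); must be
#'   distinct.
#' @param link_radius_mm single-linkage merge distance defining a contiguous
#'   blob; default 1.5x `spacing_mm` (or 1.5x the median nearest-neighbour
#'   distance of the valid voxels when `spacing_mm` is `NULL`).
#' @param spacing_mm source-lattice spacing used for the default link radius.
#' @return list with elements `A` and `B` (each an `eegdot_bsm`).
#' @export
two_spot_assessment <- function(values, positions, spot_a, spot_b,
                                link_radius_mm = NULL, spacing_mm = NULL) {
  ca <- if (inherits(spot_a, "eegdot_spot")) spot_a$center else spot_a
  cb <- if (inherits(spot_b, "eegdot_spot")) spot_b$center else spot_b
  if (sqrt(sum((ca - cb)^2)) < 1e-9) {
    stop("spot centers must be distinct", call. = FALSE)
  }
  valid <- half_max_voxels(values)
  if (length(valid) == 0) {
    return(list(A = undetected_bsm(), B = undetected_bsm()))
  }
  pts <- positions[valid, , drop = FALSE]
  da <- sqrt(colSums((t(pts) - ca)^2))
  db <- sqrt(colSums((t(pts) - cb)^2))
  nearer_a <- da <= db  # ties to A

  # one region missing: all valid voxels nearer one center
  if (all(nearer_a)) {
    return(list(A = bias_spread(valid, positions, ca), B = undetected_bsm()))
  }
  if (all(!nearer_a)) {
    return(list(A = undetected_bsm(), B = bias_spread(valid, positions, cb)))
  }

  if (is.null(link_radius_mm)) {
    sp <- spacing_mm
    if (is.null(sp)) {
      sp <- if (length(valid) > 1) {
        d <- as.matrix(stats::dist(pts))
        diag(d) <- Inf
        stats::median(apply(d, 1, min))
      } else 1
    }
    link_radius_mm <- 1.5 * sp
  }
  blob <- if (length(valid) > 1) {
    stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                  h = link_radius_mm)
  } else 1L

  if (length(unique(blob)) == 1L) {
    # a single contiguous blob straddling both centers: use it for both spots
    return(list(A = bias_spread(valid, positions, ca),
                B = bias_spread(valid, positions, cb)))
  }

  list(A = bias_spread(valid[nearer_a], positions, ca),
       B = bias_spread(valid[!nearer_a], positions, cb))
}

#' @export
print.eegdot_bsm <- function(x, ...) {
  if (!x$detected) {
    cat("BSM: spot undetected\n")
  } else {
    cat(sprintf("BSM %.2f mm (bias %.2f mm, spread %.2f mm^2, %d valid voxels)\n",
                x$bsm, x$bias, x$spread, length(x$valid_voxel_ids)))
  }
  invisible(x)
}
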