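#' Analytic EEG leadfield for the four-shell sphere
#'
#' Scalp potentials generated by radially oriented unit dipoles on the
#' cortical shell, computed from the classical Legendre-series solution of the
#' Poisson problem in concentric conducting spheres. Within each shell the
#' potential is a combination of solid harmonics `r^n` and `r^-(n+1)`; the
#' per-degree coefficients are obtained by solving the small linear system
#' given by continuity of potential and radial current at each interface and
#' zero current through the scalp. Radial scaling keeps the system
#' well-conditioned at high degree.
#'
#' Dipoles are evaluated `dipole_depth_mm` below the nominal source radius:
#' the source shell sits exactly on the brain/CSF interface, where the
#' interior harmonic expansion is singular, so the dipoles are retracted
#' slightly into the brain compartment. Columns are average-referenced
#' (each sums to zero over electrodes).
#'
#' @param head_or_model `eegdot_head` or `eegdot_head_model`.
#' @param electrodes `eegdot_electrodes` from [place_sensors()].
#' @param sources `eegdot_source_space`; defaults to the head's own.
#' @param n_terms truncation order of the Legendre series. Default 60; the
#'   resistive skull damps high degrees strongly, and the largest neglected
#'   term magnitude is recorded in the provenance attributes.
#' @param dipole_depth_mm retraction of the dipole below the source radius
#'   (mm). Default 2.
#' @return An `eegdot_leadfield`: `matrix` (E x V, average-referenced scalp
#'   potential per unit radial dipole moment), plus provenance fields
#'   `n_terms`, `dipole_depth_mm`, `tail_magnitude`.
#' @examples
#' hm <- build_spherical_head(n_sources = 600)
#' el <- place_sensors(hm, "eeg32")
#' L <- compute_eeg_leadfield(hm, el)
#' max(abs(colSums(L$matrix)))  # ~0: average reference
#' @export
compute_eeg_leadfield <- function(head_or_model, electrodes, sources = NULL,
                                  n_terms = 60L, dipole_depth_mm = 2) {
  head <- if (inherits(head_or_model, "eegdot_head")) head_or_model$head else head_or_model
  if (is.null(sources) && inherits(head_or_model, "eegdot_head")) {
    sources <- head_or_model$sources
  }
  stopifnot(inherits(electrodes, "eegdot_electrodes"),
            inherits(sources, "eegdot_source_space"))

  radii <- unname(head$shell_radii)
  sigma <- unname(head$conductivities)
  r_scalp <- radii[4]
  src_r <- sqrt(rowSums(sources$positions^2))
  dip_r <- src_r - dipole_depth_mm
  if (any(dip_r >= radii[1])) {
    stop("dipoles must lie strictly inside the brain shell; increase `dipole_depth_mm`",
         call. = FALSE)
  }
  if (any(sqrt(rowSums(electrodes$positions^2)) > r_scalp * (1 + 1e-6))) {
    stop("electrodes must lie on the scalp shell", call. = FALSE)
  }
  # all sources are on one shell -> one eccentricity, one coefficient vector
  f <- dip_r[1] / r_scalp
  if (max(abs(dip_r - dip_r[1])) > 1e-6) {
    stop("source space must be a single cortical shell", call. = FALSE)
  }

  cn <- sphere_series_coefficients(radii / r_scalp, sigma, f, n_terms) /
    (4 * pi * sigma[4] * r_scalp^2)

  # cos(angle between electrode direction and dipole direction)
  e_dir <- electrodes$positions / r_scalp
  s_dir <- sources$normals
  ct <- tcrossprod(e_dir, s_dir)
  ct[ct > 1] <- 1
  ct[ct < -1] <- -1

  L <- legendre_series(ct, cn)
  L <- sweep(L, 2, colMeans(L))  # average reference
  dimnames(L) <- list(electrodes$labels, sources$voxel_ids)

  tail_mag <- abs(cn[n_terms]) / max(abs(cn))
  structure(
    list(
      matrix = L,
      n_terms = n_terms,
      dipole_depth_mm = dipole_depth_mm,
      tail_magnitude = tail_mag,
      electrodes = electrodes$labels
    ),
    class = "eegdot_leadfield"
  )
}

# Per-degree scalp coefficients c_n for a radial unit dipole at normalized
# eccentricity f inside an M-shell sphere with normalized interface radii
# x (x[M] = 1) and conductivities sigma. The scalp potential is
#   V(theta) = (1 / (4 pi sigma_M R^2)) * sum_n c_n P_n(cos theta).
# Unknowns are scaled per layer (A_j by its outer radius^n, B_j by its inner
# radius^-(n+1)) so matrix entries stay O(n).
sphere_series_coefficients <- function(x, sigma, f, n_terms) {
  m <- length(x)
  stopifnot(length(sigma) == m, f < x[1], f > 0)
  cn <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    nun <- 7L  # A1, A2, B2, A3, B3, A4, B4 (m = 4)
    A <- matrix(0, nun, nun)
    b <- numeric(nun)
    # index helpers: A_j -> col a(j), B_j -> col bb(j) (j >= 2)
    a <- c(1L, 2L, 4L, 6L)
    bb <- c(NA, 3L, 5L, 7L)
    inner_r <- c(NA, x[1], x[2], x[3])  # inner radius of layer j (j >= 2)
    # source strength: primary field n * f^(n-1) * r^-(n+1); we factor the
    # physical prefactor out, so s1 multiplies r^-(n+1) directly.
    row <- 0L
    for (j in 1:(m - 1)) {
      xj <- x[j]
      # scaled evaluations at interface x_j
      # layer j (evaluated at its outer radius): A term = Atilde_j,
      #   B term = Btilde_j * (inner_j / x_j)^(n+1)
      # layer j+1 (evaluated at its inner radius x_j): A term =
      #   Atilde_{j+1} * (x_j / x_{j+1})^n, B term = Btilde_{j+1}
      tj <- if (j >= 2) (inner_r[j] / xj)^(n + 1) else NA
      u_next <- (xj / x[j + 1])^n
      # potential continuity
      row <- row + 1L
      A[row, a[j]] <- 1
      if (j >= 2) A[row, bb[j]] <- tj
      A[row, a[j + 1]] <- -u_next
      A[row, bb[j + 1]] <- -1
      if (j == 1) b[row] <- -n * f^(n - 1) * xj^(-(n + 1))
      # radial current continuity (times r to keep powers aligned)
      row <- row + 1L
      A[row, a[j]] <- sigma[j] * n
      if (j >= 2) A[row, bb[j]] <- -sigma[j] * (n + 1) * tj
      A[row, a[j + 1]] <- -sigma[j + 1] * n * u_next
      A[row, bb[j + 1]] <- sigma[j + 1] * (n + 1)
      if (j == 1) b[row] <- sigma[1] * (n + 1) * n * f^(n - 1) * xj^(-(n + 1))
    }
    # insulating outer boundary at x = 1: n*A_4 - (n+1)*B_4*(x_3)^(n+1) = 0
    row <- row + 1L
    A[row, a[m]] <- n
    A[row, bb[m]] <- -(n + 1) * (inner_r[m])^(n + 1)
    sol <- solve(A, b)
    # scalp potential at r = 1: Atilde_4 + Btilde_4 * x_3^(n+1)
    cn[n] <- sol[a[m]] + sol[bb[m]] * (inner_r[m])^(n + 1)
  }
  cn
}

# sum_n coef[n] * P_n(x) evaluated elementwise via the Legendre recurrence.
legendre_series <- function(x, coef) {
  p_prev <- array(1, dim = dim(x))  # P_0
  p_cur <- x                        # P_1
  out <- coef[1] * p_cur
  n_terms <- length(coef)
  if (n_terms >= 2) {
    for (n in 2:n_terms) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      out <- out + coef[n] * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

#' @export
print.eegdot_leadfield <- function(x, ...) {
  cat(sprintf(
    "EEG leadfield: %d electrodes x %d sources (series order %d, tail %.1e)\n",
    nrow(x$matrix), ncol(x$matrix), x$n_terms, x$tail_magnitude
  ))
  invisible(x)
}
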