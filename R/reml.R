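#' Covariance-component model
#'
#' A covariance matrix expressed as a nonnegative linear combination
#' `C = sum_i lambda_i Q_i` of fixed symmetric positive semidefinite
#' components. Components may be given as full symmetric matrices or as
#' diagonal vectors (stored compactly). The coefficients `lambda_i` are the
#' hyperparameters estimated by [reml_fit()].
#'
#' @param components list of components; each a symmetric matrix or a numeric
#'   vector interpreted as a diagonal.
#' @param side `"noise"` (sensor space) or `"prior"` (source space).
#' @param lambda optional fixed/starting coefficients (nonnegative).
#' @return `eegdot_covmodel`.
#' @examples
#' cm <- covariance_model(list(diag(3)), side = "noise")
#' @export
covariance_model <- function(components, side = c("noise", "prior"),
                             lambda = NULL) {
  side <- match.arg(side)
  if (!is.list(components)) components <- list(components)
  if (length(components) == 0) stop("at least one component required", call. = FALSE)
  comps <- lapply(components, function(q) {
    if (is.matrix(q)) {
      if (nrow(q) != ncol(q) || max(abs(q - t(q))) > 1e-8 * max(1, max(abs(q)))) {
        stop("matrix components must be symmetric", call. = FALSE)
      }
      q
    } else if (is.numeric(q)) {
      if (any(q < 0)) stop("diagonal components must be nonnegative", call. = FALSE)
      q  # diagonal, stored as a vector
    } else {
      stop("components must be matrices or numeric diagonals", call. = FALSE)
    }
  })
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == length(comps), all(lambda >= 0))
  }
  structure(list(components = comps, side = side, lambda = lambda),
            class = "eegdot_covmodel")
}

comp_dim <- function(q) if (is.matrix(q)) nrow(q) else length(q)

# project a prior component into sensor space: H Q H^T
sensor_component <- function(q, H) {
  if (is.matrix(q)) H %*% q %*% t(H) else H %*% (q * t(H))
}

assemble_cov <- function(components, lambda) {
  n <- comp_dim(components[[1]])
  C <- matrix(0, n, n)
  for (i in seq_along(components)) {
    q <- components[[i]]
    if (is.matrix(q)) C <- C + lambda[i] * q else diag(C) <- diag(C) + lambda[i] * q
  }
  C
}

#' Restricted maximum likelihood fit of a linear Gaussian inverse problem
#'
#' Fits the model `Y = H beta + e` with `beta ~ N(0, C_P)`,
#' `e ~ N(0, C_N)`, where the noise and prior covariances are linear
#' combinations of fixed components (see [covariance_model()]). The
#' coefficients are estimated by maximizing the log-likelihood of the
#' marginal model `cov(Y) = H C_P H^T + C_N`, with the columns of `Y` treated
#' as i.i.d. realizations. Optimization is Fisher scoring on the
#' log-coefficients (which enforces positivity) with Levenberg-Marquardt
#' damping and step rejection, so the objective trace is non-decreasing. The
#' source estimate is the posterior mean
#' `beta_hat = C_P H^T (H C_P H^T + C_N)^{-1} Y` at the optimum.
#'
#' @param Y measurement matrix (channels x timepoints) or vector.
#' @param H forward matrix (channels x sources).
#' @param noise_model,prior_model `eegdot_covmodel`s (sides `"noise"` and
#'   `"prior"`).
#' @param tol relative objective-change convergence tolerance. Default 1e-6.
#' @param max_iter maximum accepted iterations. Default 128.
#' @param update if `FALSE` the coefficients are fixed at the models'
#'   `lambda` values and only the posterior mean is computed.
#' @return `eegdot_reml`: `beta_hat`, `lambda_noise`, `lambda_prior`,
#'   `objective_trace`, `converged`, `n_iter`, and the assembled sensor-space
#'   covariances.
#' @export
reml_fit <- function(Y, H, noise_model, prior_model,
                     tol = 1e-6, max_iter = 128L, update = TRUE) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("Y must not contain NA", call. = FALSE)
  m <- nrow(Y)
  stopifnot(nrow(H) == m,
            inherits(noise_model, "eegdot_covmodel"),
            inherits(prior_model, "eegdot_covmodel"))
  p <- ncol(H)
  for (q in noise_model$components) {
    if (comp_dim(q) != m) stop("noise component dimension mismatch", call. = FALSE)
  }
  for (q in prior_model$components) {
    if (comp_dim(q) != p) stop("prior component dimension mismatch", call. = FALSE)
  }
  if (max(abs(H)) == 0) stop("forward matrix is identically zero", call. = FALSE)

  T_n <- ncol(Y)
  S <- tcrossprod(Y) / T_n

  # sensor-space versions of all components
  Qn <- lapply(noise_model$components, function(q) if (is.matrix(q)) q else diag(q, m))
  Ap <- lapply(prior_model$components, sensor_component, H = H)
  Qs <- c(Qn, Ap)
  kn <- length(Qn)
  k <- length(Qs)

  all_zero_y <- max(abs(Y)) == 0
  if (all_zero_y) warning("Y is identically zero; returning a zero estimate")

  # initialization: split the empirical variance equally across components
  tr_s <- max(sum(diag(S)), m * 1e-12)
  lam <- vapply(Qs, function(q) tr_s / (k * max(sum(diag(q)), 1e-12)), numeric(1))
  fixed <- c(noise_model$lambda, prior_model$lambda)
  if (!update) {
    if (length(fixed) != k) {
      stop("update = FALSE requires lambda on both covariance models", call. = FALSE)
    }
    lam <- fixed
  } else if (length(fixed) == k) {
    lam <- pmax(fixed, 1e-12)
  }

  jitter <- function(C) {
    eps <- 1e-10 * mean(diag(C))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
    C + diag(eps, m)
  }
  objective <- function(lam) {
    Cyy <- jitter(Reduce(`+`, Map(`*`, Qs, lam)))
    ch <- tryCatch(chol(Cyy), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    Fv <- -T_n / 2 * (logdet + sum(Sinv * S))
    list(F = Fv, Sinv = Sinv)
  }

  theta <- log(lam)
  ob <- objective(exp(theta))
  if (!is.finite(ob$F)) stop("singular marginal covariance at initialization", call. = FALSE)
  trace_F <- ob$F
  converged <- FALSE
  n_iter <- 0L
  damping <- 1e-4

  if (update && !all_zero_y) {
    for (it in seq_len(max_iter)) {
      lam <- exp(theta)
      Sinv <- ob$Sinv
      SinvS <- Sinv %*% S
      B <- lapply(Qs, function(q) Sinv %*% q)
      g <- vapply(seq_len(k), function(i) {
        lam[i] * T_n / 2 * (sum(t(SinvS) * B[[i]]) - sum(diag(B[[i]])))
      }, numeric(1))
      FI <- matrix(0, k, k)
      for (i in seq_len(k)) {
        for (j in i:k) {
          v <- lam[i] * lam[j] * T_n / 2 * sum(t(B[[i]]) * B[[j]])
          FI[i, j] <- v
          FI[j, i] <- v
        }
      }
      accepted <- FALSE
      for (try in 1:12) {
        step <- tryCatch(
          solve(FI + damping * (diag(diag(FI), k) + diag(1e-8, k)), g),
          error = function(e) NULL
        )
        if (is.null(step)) { damping <- damping * 10; next }
        step <- pmax(pmin(step, 8), -8)  # trust region in log-space
        theta_new <- pmax(pmin(theta + step, 40), -40)
        ob_new <- objective(exp(theta_new))
        if (is.finite(ob_new$F) && ob_new$F >= trace_F[length(trace_F)] - 1e-9 * (1 + abs(ob_new$F))) {
          theta <- theta_new
          ob <- ob_new
          damping <- max(damping / 4, 1e-8)
          accepted <- TRUE
          break
        }
        damping <- damping * 10
      }
      if (!accepted) break
      n_iter <- it
      f_new <- ob$F
      f_old <- trace_F[length(trace_F)]
      trace_F <- c(trace_F, f_new)
      if (abs(f_new - f_old) < tol * (1 + abs(f_new))) {
        converged <- TRUE
        break
      }
    }
  } else {
    converged <- TRUE
  }

  lam <- exp(theta)
  lam_n <- lam[seq_len(kn)]
  lam_p <- lam[kn + seq_len(k - kn)]
  Cyy <- jitter(Reduce(`+`, Map(`*`, Qs, lam)))
  SinvY <- solve(Cyy, Y)
  # beta = C_P H^T Cyy^-1 Y, computed without forming the p x p prior
  beta <- matrix(0, p, T_n)
  HtSy <- t(H) %*% SinvY
  for (j in seq_along(prior_model$components)) {
    q <- prior_model$components[[j]]
    beta <- beta + lam_p[j] * (if (is.matrix(q)) q %*% HtSy else q * HtSy)
  }
  if (all_zero_y) beta[] <- 0

  structure(
    list(
      beta_hat = beta,
      lambda_noise = lam_n,
      lambda_prior = lam_p,
      objective_trace = trace_F,
      converged = converged,
      n_iter = n_iter,
      C_N = assemble_cov(Qn, lam_n),
      marginal_cov = Cyy
    ),
    class = "eegdot_reml"
  )
}

#' Posterior-mean source estimate for fixed covariances
#'
#' Computes `C_P H^T (H C_P H^T + C_N)^{-1} Y` (the maximum a posteriori /
#' posterior-mean estimate under Gaussian assumptions). The `"dual"` form
#' `(H^T C_N^{-1} H + C_P^{-1})^{-1} H^T C_N^{-1} Y` is algebraically
#' identical (Woodbury identity) when `C_P` is invertible and is provided for
#' cross-checking.
#'
#' @param Y measurements (channels x timepoints).
#' @param H forward matrix.
#' @param C_N,C_P assembled noise (channels) and prior (sources) covariance
#'   matrices.
#' @param form `"primal"` or `"dual"`.
#' @return source estimate (sources x timepoints).
#' @export
posterior_mean <- function(Y, H, C_N, C_P, form = c("primal", "dual")) {
  form <- match.arg(form)
  Y <- as.matrix(Y)
  m <- nrow(Y)
  if (nrow(H) != m || nrow(C_N) != m || nrow(C_P) != ncol(H)) {
    stop("dimension mismatch between Y, H and the covariances", call. = FALSE)
  }
  if (form == "primal") {
    Cyy <- H %*% C_P %*% t(H) + C_N
    Cyy <- Cyy + diag(1e-10 * mean(diag(Cyy)), m)
    C_P %*% t(H) %*% solve(Cyy, Y)
  } else {
    Ni <- solve(C_N)
    A <- t(H) %*% Ni %*% H + solve(C_P)
    solve(A, t(H) %*% (Ni %*% Y))
  }
}

#' Tikhonov (ridge) solution of the linear inverse problem
#'
#' Closed-form minimizer of `||Y - H beta||^2 + lambda ||beta||^2`. This is
#' the degenerate case of the covariance-component model with identity noise
#' and prior covariances and fixed coefficient ratio `lambda`.
#'
#' @param Y measurements. @param H forward matrix.
#' @param lambda positive ridge weight.
#' @return source estimate.
#' @export
tikhonov_solve <- function(Y, H, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("`lambda` must be a positive scalar", call. = FALSE)
  }
  Y <- as.matrix(Y)
  solve(crossprod(H) + diag(lambda, ncol(H)), crossprod(H, Y))
}

#' @export
print.eegdot_reml <- function(x, ...) {
  cat(sprintf(
    "ReML fit: %d iterations (%s), lambda_N = %s, lambda_P = %s\n",
    x$n_iter, if (x$converged) "converged" else "max_iter",
    paste(signif(x$lambda_noise, 3), collapse = ", "),
    paste(signif(x$lambda_prior, 3), collapse = ", ")
  ))
  invisible(x)
}
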