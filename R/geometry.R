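## Rigid superposition, internal coordinates, and the Kabsch-aligned
## reverse-diffusion step.

#' Kabsch superposition
#'
#' Least-squares rigid alignment of \code{mobile} onto \code{reference},
#' constrained to proper rotations (det = +1), via SVD of the covariance of
#' the mask-centered point sets.  The returned transform minimizes the RMSD
#' over all rigid motions; a mirror-image input therefore retains a
#' positive residual.
#'
#' @param mobile,reference N x 3 coordinate matrices (Angstrom).
#' @param mask logical or integer subset of rows used for the fit (all rows
#'   by default).  At least 3 non-collinear points are required.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3), \code{rmsd} (Angstrom, over the masked points) and
#'   \code{transform(m)}, a function applying the fit to any N x 3 matrix.
#' @export
kabschAlign <- function(mobile, reference, mask = NULL) {
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  P <- mobile[mask, , drop = FALSE]
  Q <- reference[mask, , drop = FALSE]
  if (nrow(P) < 3) stop("kabschAlign needs >= 3 masked points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (qr(P0)$rank < 2) stop("degenerate (collinear) point set")
  H <- crossprod(P0, Q0)                      # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)                 # proper rotation
  tvec <- cq - as.vector(R %*% cp)
  fitted <- sweep(P0 %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd,
       transform = function(m) sweep(m %*% t(R), 2, tvec, "+"))
}

#' Root-mean-square deviation after optimal rigid superposition
#'
#' @inheritParams kabschAlign
#' @return RMSD in Angstrom
#' @export
alignedRmsd <- function(mobile, reference, mask = NULL)
  kabschAlign(mobile, reference, mask)$rmsd

#' Signed dihedral angle
#'
#' Angle between the plane through (p1, p2, p3) and the plane through
#' (p2, p3, p4), signed by the right-hand rule about the p2 -> p3 axis;
#' result in (-pi, pi].
#'
#' @param p1,p2,p3,p4 length-3 vectors.
#' @return angle in radians.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate dihedral: collinear points")
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2],
          b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1])
  b2n <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / b2n, sum(n1 * n2))
}

# Analytic gradient of the dihedral wrt the four points.
# Returns a 4 x 3 matrix. Standard formulation (cf. Blondel & Karplus).
.dihedralGrad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- sqrt(sum(b2^2))
  g1 <- -b2n / sum(n1^2) * n1
  g4 <- b2n / sum(n2^2) * n2
  t1 <- sum(b1 * b2) / sum(b2^2)
  t2 <- sum(b3 * b2) / sum(b2^2)
  g2 <- (-1 - t1) * g1 + t2 * g4
  g3 <- t1 * g1 + (-1 - t2) * g4
  rbind(g1, g2, g3, g4)
}

#' EDM-style noise schedule
#'
#' Decreasing sigma grid sigma_i = (smax^(1/rho) + i/N (smin^(1/rho) -
#' smax^(1/rho)))^rho for i = 0..N, paired with a normalized diffusion time
#' t_i = 1 - i/N so that t = 1 is the fully-noised end and t = 0 the data
#' end (the convention the time-dependent potentials use).
#'
#' @param num_steps number of reverse steps N.
#' @param sigma_min,sigma_max noise bounds (Angstrom-scale).
#' @param sigma_data data scale used by the denoiser parameterization.
#' @param rho grid-warping exponent (EDM default 7).
#' @return list of class \code{noise_schedule} with \code{sigmas}
#'   (length N + 1, decreasing) and \code{tvals} (length N + 1, 1 -> 0).
#' @export
noiseSchedule <- function(num_steps = 40L, sigma_min = 0.05,
                          sigma_max = 160, sigma_data = 16, rho = 7) {
  stopifnot(num_steps >= 1, sigma_min > 0, sigma_max > sigma_min)
  i <- seq(0, num_steps) / num_steps
  sig <- (sigma_max^(1 / rho) +
          i * (sigma_min^(1 / rho) - sigma_max^(1 / rho)))^rho
  structure(list(num_steps = as.integer(num_steps), sigmas = sig,
                 tvals = 1 - i, sigma_min = sigma_min,
                 sigma_max = sigma_max, sigma_data = sigma_data,
                 rho = rho),
            class = "noise_schedule")
}

# Ancestral VE interpolation toward the denoised estimate:
# mean = xhat + (s_next^2/s_t^2) (x_t - xhat), sd = s_next sqrt(1 - s_next^2/s_t^2).
.reverseMoments <- function(x_noisy, x_denoised, sigma_t, sigma_next) {
  ratio2 <- (sigma_next / sigma_t)^2
  list(mean = x_denoised + ratio2 * (x_noisy - x_denoised),
       sd = sigma_next * sqrt(max(1 - ratio2, 0)))
}

#' One reverse-diffusion step with optional Kabsch alignment
#'
#' Interpolates the current noisy coordinates toward the denoiser's
#' prediction and injects the ancestral noise for the next noise level.
#' With \code{align = TRUE} (the default) the denoised estimate is first
#' rigidly superposed onto the noisy coordinates, so that the interpolation
#' acts on the minimal projection between the two structures; with
#' \code{align = FALSE} the plain update is applied (useful to demonstrate
#' how an unaligned interpolation can drift out of distribution).  With
#' \code{augment = TRUE} the noisy input is randomly rotated and translated
#' before the step, mimicking the rigid augmentation a non-equivariant
#' denoiser is exposed to.
#'
#' @param x_noisy,x_denoised N x 3 matrices.
#' @param sigma_t,sigma_next current and next noise levels
#'   (\code{sigma_t > sigma_next}).
#' @param align rigidly align the denoised estimate onto the noisy input
#'   first?
#' @param augment apply a random rigid motion to the noisy input first?
#' @param seed integer seed or NULL.
#' @return N x 3 matrix at the next noise level.
#' @export
alignedReverseStep <- function(x_noisy, x_denoised, sigma_t, sigma_next,
                               align = TRUE, augment = FALSE, seed = NULL) {
  if (!all(dim(x_noisy) == dim(x_denoised)))
    stop("shape mismatch between noisy and denoised coordinates")
  stopifnot(sigma_t > sigma_next)
  withSeed(seed, {
    if (augment) {
      R <- randomRotation()
      tv <- stats::rnorm(3)
      x_noisy <- sweep(x_noisy %*% t(R), 2, tv, "+")
    }
    if (align && nrow(x_noisy) >= 3)
      x_denoised <- kabschAlign(x_denoised, x_noisy)$transform(x_denoised)
    mom <- .reverseMoments(x_noisy, x_denoised, sigma_t, sigma_next)
    mom$mean + mom$sd * matrix(stats::rnorm(length(x_noisy)),
                               nrow(x_noisy), 3)
  })
}

#' Uniform random rotation matrix
#'
#' Proper rotation drawn from the Haar measure (QR of a Gaussian matrix
#' with sign fix).
#'
#' @return 3 x 3 rotation matrix with det +1.
#' @export
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
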