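## Feynman-Kac steering of a pluggable diffusion sampler: sequential Monte
## Carlo particles, importance resampling, and gradient guidance on the
## denoised prediction.

#' Steering configuration
#'
#' @param num_particles number of SMC particles k (>= 1).
#' @param resample_interval resample every this many timesteps (default 3).
#' @param guidance_steps m gradient-descent steps applied to the guidance
#'   offset after each resampling (default 4).
#' @param guidance_step_size step size for those updates; NULL (default)
#'   auto-scales so the first step moves no atom by more than 0.5 Angstrom.
#' @param weights a \code{\link{potentialWeights}} (carries the component
#'   weights, the clash gate and the tilt strength lambda).
#' @param seed integer seed for the whole run, or NULL.
#' @return list of class \code{steering_config}
#' @export
steeringConfig <- function(num_particles = 4L, resample_interval = 3L,
                           guidance_steps = 4L, guidance_step_size = NULL,
                           weights = potentialWeights(), seed = NULL) {
  stopifnot(num_particles >= 1, resample_interval >= 1, guidance_steps >= 0)
  structure(list(num_particles = as.integer(num_particles),
                 resample_interval = as.integer(resample_interval),
                 guidance_steps = as.integer(guidance_steps),
                 guidance_step_size = guidance_step_size,
                 weights = weights, seed = seed),
            class = "steering_config")
}

#' Gaussian ancestral sampler over a noise schedule
#'
#' The transition kernel tau(x_next | xhat, x_t, step) is the exact
#' Gaussian ancestral posterior of the variance-exploding forward process:
#' mean xhat + (s_next^2 / s_t^2)(x_t - xhat), isotropic sd
#' s_next sqrt(1 - s_next^2 / s_t^2).  Both sampling and the log-density
#' are exposed, which makes the proposal-density ratio of the guided
#' importance weights available in closed form.
#'
#' @param schedule a \code{\link{noiseSchedule}}.
#' @return list of class \code{diffusion_sampler} with elements
#'   \code{sample(xhat, x_t, step)} and
#'   \code{logDensity(x_next, xhat, x_t, step)}; \code{step} is the
#'   1-based transition index (from \code{sigmas[step]} to
#'   \code{sigmas[step + 1]}).
#' @export
gaussianSampler <- function(schedule) {
  sig <- schedule$sigmas
  moments <- function(xhat, x_t, step)
    .reverseMoments(x_t, xhat, sig[step], sig[step + 1])
  structure(list(
    schedule = schedule,
    sample = function(xhat, x_t, step) {
      mom <- moments(xhat, x_t, step)
      mom$mean + mom$sd * matrix(stats::rnorm(length(x_t)), nrow(x_t), 3)
    },
    logDensity = function(x_next, xhat, x_t, step) {
      mom <- moments(xhat, x_t, step)
      sum(stats::dnorm(x_next, mom$mean, mom$sd, log = TRUE))
    }), class = "diffusion_sampler")
}

#' Importance weights for guided particles
#'
#' Normalized Feynman-Kac weights: proposal-density ratio (unguided over
#' guided kernel, both evaluated at the realized sample) times
#' exp(lambda (E_prev - E_now)), computed in log space.  If every weight
#' underflows to zero the function falls back to uniform weights with a
#' warning.
#'
#' @param log_ratio per-particle log tau(x | xhat) - log tau(x | xhat +
#'   delta); zero when no guidance offset was applied.
#' @param energies_now,energies_prev per-particle energies of the denoised
#'   prediction at the current and previous checkpoint.
#' @param lambda tilt strength.
#' @return numeric vector of normalized weights (sums to 1).
#' @export
importanceWeights <- function(log_ratio, energies_now, energies_prev,
                              lambda) {
  lw <- log_ratio + lambda * (energies_prev - energies_now)
  if (all(!is.finite(lw))) {
    warning("all importance weights underflowed; falling back to uniform")
    return(rep(1 / length(lw), length(lw)))
  }
  w <- exp(lw - logSumExp(lw))
  w / sum(w)
}

#' Multinomial particle resampling
#'
#' Draws k particles with replacement according to \code{weights}; the
#' resampled particles get uniform log-weights and a zeroed guidance
#' offset.
#'
#' @param particles list of particle lists (fields \code{x}, \code{xhat},
#'   \code{delta}, \code{log_weight}, \code{energy_prev}).
#' @param weights normalized weights (non-negative, sum 1).
#' @param seed integer seed or NULL.
#' @return list of resampled particles (same length as input).
#' @export
resampleParticles <- function(particles, weights, seed = NULL) {
  if (any(weights < 0)) stop("negative resampling weight")
  k <- length(particles)
  idx <- withSeed(seed,
    sample.int(k, k, replace = TRUE, prob = weights))
  lapply(idx, function(i) {
    p <- particles[[i]]
    p$log_weight <- -log(k)
    p$delta <- p$delta * 0
    p
  })
}

#' Feynman-Kac steered reverse diffusion
#'
#' Runs the full steering loop: k particles are propagated through the
#' sampler using the guided prediction xhat + delta; every
#' \code{resample_interval}-th step (counting from the initial noise draw)
#' the particles are multinomially resampled under importance weights
#' combining the checkpoint-to-checkpoint energy difference of the
#' denoised predictions with the guided-proposal density ratio, the
#' guidance offsets are reset, and m gradient-descent steps on the
#' combined potential rebuild them.  The returned structure is particle
#' 1's final coordinates plus its final guidance offset.
#'
#' @param denoiser function \code{f(x, t)} returning denoised coordinates
#'   (same shape); t is the normalized diffusion time in [0, 1].
#' @param sampler a \code{\link{gaussianSampler}} (or any list providing
#'   \code{sample} and \code{logDensity} with the same signatures; a
#'   sampler without a tractable density may set \code{logDensity = NULL},
#'   forfeiting the ratio correction).
#' @param constraints a \linkS4class{ConstraintSet}.
#' @param config a \code{\link{steeringConfig}}.
#' @param n_atoms number of atoms of the sampled structure.
#' @param init_seed overrides \code{config$seed} when non-NULL.
#' @return list with \code{coords} (final N x 3 of particle 1 plus its
#'   guidance offset), \code{delta} (that offset), \code{prediction}
#'   (particle 1's final guided denoised prediction xhat_0 + delta, the
#'   quantity the energy diagnostics refer to), and
#'   \code{diagnostics}: \code{resample_steps}, \code{weights} (list of
#'   normalized weight vectors per checkpoint), \code{energies} (matrix,
#'   checkpoints x particles, of denoised-prediction energies), and
#'   \code{t_grid}.
#' @export
fkSteer <- function(denoiser, sampler, constraints, config = steeringConfig(),
                    n_atoms, init_seed = NULL) {
  k <- config$num_particles
  if (k < 1) stop("num_particles must be >= 1")
  w <- config$weights
  lambda <- w$lambda
  m <- config$guidance_steps
  sched <- sampler$schedule
  sig <- sched$sigmas
  tv <- sched$tvals
  n_steps <- sched$num_steps
  seed <- init_seed %||% config$seed

  diag_resample <- integer(0)
  diag_weights <- list()
  diag_energies <- list()

  withSeed(seed, {
    x <- lapply(seq_len(k), function(i)
      sig[1] * matrix(stats::rnorm(n_atoms * 3), n_atoms, 3))
    xhat <- lapply(x, denoiser, t = tv[1])
    delta <- lapply(seq_len(k), function(i) matrix(0, n_atoms, 3))
    e_prev <- rep(NA_real_, k)

    # m gradient-descent steps on E(xhat + delta); each step backtracks
    # (halving the step) until the energy does not increase, so guidance
    # never degrades the prediction it decorates
    guide <- function(xh, dl) {
      if (m == 0 || lambda == 0) return(dl)
      e_cur <- totalEnergy(xh + dl, constraints, w, t = t_now)
      for (j in seq_len(m)) {
        if (e_cur <= 0) break
        g <- gradTotalEnergy(xh + dl, constraints, w, t = t_now)
        mx <- max(rowNorms(g))
        if (mx == 0) break
        gamma <- config$guidance_step_size %||% (0.5 / mx)
        for (try in 1:6) {
          dl2 <- dl - gamma * g
          e2 <- totalEnergy(xh + dl2, constraints, w, t = t_now)
          if (e2 < e_cur) break
          gamma <- gamma / 2
        }
        if (e2 >= e_cur) break
        dl <- dl2; e_cur <- e2
      }
      dl
    }

    for (s in seq(0, n_steps)) {      # s transitions completed; state index s+1
      t_now <- tv[s + 1]
      if (s > 0) {
        x_prev <- x; xhat_prev <- xhat; delta_prev <- delta
        x <- lapply(seq_len(k), function(i)
          sampler$sample(xhat_prev[[i]] + delta_prev[[i]], x_prev[[i]], s))
        xhat <- lapply(x, denoiser, t = t_now)
      }
      bad <- vapply(seq_len(k), function(i)
        !all(is.finite(x[[i]])) || !all(is.finite(xhat[[i]])), TRUE)
      if (any(bad))
        stop("non-finite coordinates at step ", s, " (particle ",
             which(bad)[1], ")")

      if (s %% config$resample_interval == 0) {
        e_now <- vapply(xhat, totalEnergy, 1, constraints = constraints,
                        weights = w, t = t_now)
        if (!all(is.finite(e_now)))
          stop("non-finite energy at step ", s)
        if (s == 0) {
          lw <- -lambda * e_now
          wt <- exp(lw - logSumExp(lw)); wt <- wt / sum(wt)
        } else {
          log_ratio <- vapply(seq_len(k), function(i) {
            if (is.null(sampler$logDensity) ||
                all(delta_prev[[i]] == 0)) return(0)
            sampler$logDensity(x[[i]], xhat_prev[[i]], x_prev[[i]], s) -
              sampler$logDensity(x[[i]], xhat_prev[[i]] + delta_prev[[i]],
                                 x_prev[[i]], s)
          }, 1)
          wt <- importanceWeights(log_ratio, e_now, e_prev, lambda)
        }
        idx <- sample.int(k, k, replace = TRUE, prob = wt)
        x <- x[idx]; xhat <- xhat[idx]
        e_prev <- e_now[idx]
        delta <- lapply(xhat, guide, dl = matrix(0, n_atoms, 3))
        diag_resample <- c(diag_resample, s)
        diag_weights[[length(diag_weights) + 1L]] <- wt
        diag_energies[[length(diag_energies) + 1L]] <- e_now
      }
    }

    list(coords = x[[1]] + delta[[1]], delta = delta[[1]],
         prediction = xhat[[1]] + delta[[1]],
         particles = lapply(seq_len(k), function(i)
           list(x = x[[i]], xhat = xhat[[i]], delta = delta[[i]],
                log_weight = -log(k), energy_prev = e_prev[i])),
         diagnostics = list(resample_steps = diag_resample,
                            weights = diag_weights,
                            energies = do.call(rbind, diag_energies),
                            t_grid = tv))
  })
}
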