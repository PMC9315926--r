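#' Configuration for the chemotaxis track simulator
#'
#' Emulates low-frequency centroid tracking of cells migrating in a
#' chemoattractant gradient oriented along +x (source in the right
#' reservoir), sampled every 2 minutes.
#'
#' @param n_cells number of cells.
#' @param n_steps number of steps per track.
#' @param step_interval sampling interval, seconds.
#' @param speed mean cell speed, micrometres per minute.
#' @param beta directional bias in [0, 1]: each step heads exactly along +x
#'   with probability `beta`, otherwise its direction comes from the
#'   persistence kernel. `beta = 0` gives an unbiased walk.
#' @param persistence p in [0, 1): unbiased steps turn by an angle drawn
#'   uniformly from (-pi (1 - p), pi (1 - p)) relative to the previous
#'   heading; p = 0 is an isotropic walk, p -> 1 is straight-line motion.
#' @param speed_jitter lognormal sd of the multiplicative step-length
#'   jitter (0 = constant speed).
#' @param seed integer seed.
#' @return A validated config list of class `chemotaxis_sim_config`.
#' @export
chemotaxis_sim_config <- function(n_cells = 50, n_steps = 60,
                                  step_interval = 120, speed = 8,
                                  beta = 0.3, persistence = 0,
                                  speed_jitter = 0.25, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_steps = as.integer(n_steps),
              step_interval = step_interval, speed = speed, beta = beta,
              persistence = persistence, speed_jitter = speed_jitter,
              seed = as.integer(seed))
  if (cfg$beta < 0 || cfg$beta > 1) stop("beta must be in [0, 1]")
  if (cfg$persistence < 0 || cfg$persistence >= 1)
    stop("persistence must be in [0, 1)")
  if (cfg$step_interval <= 0) stop("step_interval must be > 0")
  class(cfg) <- "chemotaxis_sim_config"
  cfg
}

#' Simulate 2D cell tracks under a rightward gradient
#'
#' @param config a [chemotaxis_sim_config()].
#' @return A `cell_tracks` data frame with columns `cell_id`, `t_s`,
#'   `x_um`, `y_um` and attribute `gradient_axis = c(1, 0)`.
#' @export
simulate_chemotaxis_tracks <- function(config = chemotaxis_sim_config()) {
  stopifnot(inherits(config, "chemotaxis_sim_config"))
  set.seed(config$seed)
  step_len <- config$speed * config$step_interval / 60  # um per step
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    ns <- config$n_steps
    ang <- numeric(ns)
    prev <- runif(1, -pi, pi)
    for (s in seq_len(ns)) {
      if (runif(1) < config$beta) {
        ang[s] <- 0
      } else {
        half <- pi * (1 - config$persistence)
        ang[s] <- prev + runif(1, -half, half)
      }
      prev <- ang[s]
    }
    len <- if (config$speed_jitter > 0)
      step_len * exp(rnorm(ns, -config$speed_jitter^2 / 2,
                           config$speed_jitter))
    else rep(step_len, ns)
    x <- cumsum(c(0, len * cos(ang)))
    y <- cumsum(c(0, len * sin(ang)))
    out[[i]] <- data.frame(cell_id = i,
                           t_s = (0:ns) * config$step_interval,
                           x_um = x, y_um = y)
  }
  res <- do.call(rbind, out)
  attr(res, "gradient_axis") <- c(1, 0)
  class(res) <- c("cell_tracks", "data.frame")
  res
}
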