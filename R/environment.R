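#' Environment configuration
#'
#' Parameters of the stochastic moving-optimum environment: a deterministic
#' linear trend \eqn{\theta_t = \theta_0 + \eta t} plus AR(1) colored noise
#' \eqn{\phi_t = \alpha \phi_{t-1} + \beta \xi_t}, where \eqn{\xi_t} is
#' standard normal and \eqn{\beta} is chosen so that the stationary variance
#' of \eqn{\phi} equals `sigma2` for every autocorrelation `alpha`.
#'
#' @param theta0 Initial environmental optimum (trait units).
#' @param eta Rate of directional environmental change per generation
#'   (trait units / generation).
#' @param alpha Noise autocorrelation in (-1, 1): negative = blue noise,
#'   zero = white, positive = red.
#' @param sigma2 Environmental variance (trait units squared), must be > 0.
#'
#' @return An object of class `env_config`.
#' @examples
#' cfg <- env_config(eta = 0.04, alpha = 0.7)
#' optimum_at(200, cfg)
#' @export
env_config <- function(theta0 = 0, eta = 0, alpha = 0, sigma2 = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || abs(alpha) >= 1)
    stop("alpha must be a single number strictly between -1 and 1", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("sigma2 must be a single positive number", call. = FALSE)
  structure(
    list(theta0 = theta0, eta = eta, alpha = alpha, sigma2 = sigma2,
         beta = beta_from_alpha(alpha, sigma2)),
    class = "env_config"
  )
}

#' Noise scale for variance-normalized AR(1) noise
#'
#' Computes \eqn{\beta = \sigma \sqrt{1 - \alpha^2}} so that the AR(1)
#' process \eqn{\phi_t = \alpha \phi_{t-1} + \beta \xi_t} has stationary
#' variance \eqn{\sigma^2} regardless of the noise color \eqn{\alpha}.
#'
#' @param alpha Autocorrelation coefficient in (-1, 1).
#' @param sigma2 Target stationary variance, > 0.
#' @return The innovation scale \eqn{\beta}.
#' @examples
#' beta_from_alpha(0, 1)    # 1
#' beta_from_alpha(0.7, 1)  # sqrt(0.51)
#' @export
beta_from_alpha <- function(alpha, sigma2) {
  if (!is.numeric(alpha) || any(abs(alpha) >= 1))
    stop("alpha must lie strictly between -1 and 1", call. = FALSE)
  if (!is.numeric(sigma2) || any(sigma2 <= 0))
    stop("sigma2 must be positive", call. = FALSE)
  sqrt(sigma2) * sqrt(1 - alpha^2)
}

#' Deterministic optimum at a generation
#'
#' @param t Generation index (>= 0).
#' @param cfg An [env_config()].
#' @return \eqn{\theta_t = \theta_0 + \eta t}.
#' @export
optimum_at <- function(t, cfg) {
  stopifnot(all(t >= 0))
  cfg$theta0 + cfg$eta * t
}

#' Advance the AR(1) noise process one step
#'
#' Deterministic given the innovation draw: callers supply `xi`, one draw
#' from N(0, 1), so that all randomness flows through a single seeded RNG
#' stream.
#'
#' @param phi_prev Previous noise value.
#' @param alpha Autocorrelation.
#' @param beta Innovation scale (see [beta_from_alpha()]).
#' @param xi A standard-normal draw.
#' @return \eqn{\phi_t = \alpha \phi_{t-1} + \beta \xi_t}.
#' @export
advance_noise <- function(phi_prev, alpha, beta, xi) {
  alpha * phi_prev + beta * xi
}

#' Initial noise value drawn from the stationary distribution
#'
#' \eqn{\phi_0 \sim N(0, \sigma^2)}, so the noise process is stationary
#' from generation 0 onwards (burn-in statistics are stationary too).
#' Uses the current RNG stream.
#'
#' @param cfg An [env_config()].
#' @return A single noise value.
#' @export
init_noise <- function(cfg) {
  stats::rnorm(1L, mean = 0, sd = sqrt(cfg$sigma2))
}

#' One generation's realized environment
#'
#' @param t Generation index used for the trend.
#' @param phi Current noise value.
#' @param cfg An [env_config()].
#' @return A list with `t`, `theta_t`, `phi_t` and the realized optimum
#'   `theta_star_t = theta_t + phi_t`.
#' @export
environment_state <- function(t, phi, cfg) {
  theta <- optimum_at(t, cfg)
  list(t = t, theta_t = theta, phi_t = phi, theta_star_t = theta + phi)
}
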