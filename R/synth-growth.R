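#' Specify a growth model
#'
#' Logistic growth with an explicit lag: before `lag` the culture sits at
#' its starting density `od0`; afterwards it grows exponentially at
#' `mu = ln(2) / gt_true` and saturates at `carrying_capacity`. The default
#' starting density (OD600 = 0.01) matches standard microplate growth
#' assays.
#'
#' @param od0 Starting OD600 (> 0).
#' @param gt_true True generation time, minutes (> 0).
#' @param lag Lag phase, minutes.
#' @param carrying_capacity Saturating OD600 (> `od0`).
#' @param noise_sd Gaussian measurement noise SD, OD units.
#' @param seed Integer seed.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(od0 = 0.01, gt_true = 25, lag = 60,
                         carrying_capacity = 1.5, noise_sd = 0.002,
                         seed = 1L) {
  if (od0 <= 0) abort("`od0` must be > 0.")
  if (gt_true <= 0) abort("`gt_true` must be > 0.")
  if (carrying_capacity <= od0) abort("`carrying_capacity` must exceed `od0`.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(
      od0 = od0, gt_true = gt_true, lag = lag,
      carrying_capacity = carrying_capacity, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "growth_model"
  )
}

#' Simulate an OD600 growth curve
#'
#' Evaluates the logistic model at the requested times and adds Gaussian
#' measurement noise, flooring readings at a small positive value (1e-4 OD)
#' as a real plate reader's blanked readings would be before
#' log-transformation.
#'
#' @param model A [growth_model()].
#' @param times Strictly increasing sampling times, minutes.
#' @return A tibble `(time_min, od600)` of class `growth_curve`.
#' @export
#' @examples
#' gc <- simulate_growth_curve(growth_model(gt_true = 20, noise_sd = 0), 0:300)
#' tail(gc)
simulate_growth_curve <- function(model, times) {
  stopifnot(inherits(model, "growth_model"))
  if (length(times) == 0) abort("`times` must be non-empty.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  mu <- log(2) / model$gt_true
  K <- model$carrying_capacity
  t_eff <- pmax(times - model$lag, 0)
  e <- exp(mu * t_eff)
  od <- K * model$od0 * e / (K + model$od0 * (e - 1))
  if (model$noise_sd > 0) {
    od <- with_seed(
      derive_seed(model$seed, "od-noise"),
      od + rnorm(length(od), 0, model$noise_sd)
    )
  }
  out <- tibble::tibble(time_min = as.double(times), od600 = pmax(od, 1e-4))
  class(out) <- c("growth_curve", class(out))
  out
}
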