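#' Fit a power-law slow-release model
#'
#' Fits the Ritger-Peppas power law M(t) = k * t^n to cumulative release
#' data from slow-release substrate discs (FeedBead-type). The fit is by
#' nonlinear least squares on the original (mass) scale, so the reported
#' standard error is in mg; a log-log linear regression provides only
#' the starting values.
#'
#' @param times Sampling times, h. At least 3 points with t > 0.
#' @param masses Cumulative released mass at `times`, mg.
#' @param n_beads Number of discs the data refer to (bookkeeping only;
#'   release scales linearly with discs, see [scale_beads()]).
#' @return An object of class `release_model`: list with `k` (mg/h^n),
#'   `n` (diffusional exponent), `n_beads`, and `fit_stats` (`r_squared`,
#'   `sigma` the residual standard error in mg, `n_obs`).
#' @examples
#' t <- c(5, seq(10, 120, 10))
#' fit_release_model(t, 5.13 * t^0.65)
#' @export
fit_release_model <- function(times, masses, n_beads = 3) {
  keep <- is.finite(times) & is.finite(masses)
  times <- times[keep]; masses <- masses[keep]
  pos <- times > 0
  if (sum(pos) < 3) stop("need at least 3 samples with t > 0")
  if (any(masses < 0)) stop("cumulative masses must be >= 0")
  if (any(diff(masses[order(times)]) < 0))
    warning("cumulative masses are not monotone non-decreasing; fitting anyway")
  t_fit <- times[pos]; m_fit <- masses[pos]
  # log-log start values (guard zero masses)
  ok <- m_fit > 0
  if (sum(ok) >= 2) {
    lf <- stats::lm(log(m_fit[ok]) ~ log(t_fit[ok]))
    start <- list(k = exp(stats::coef(lf)[[1]]),
                  n = max(min(stats::coef(lf)[[2]], 1.2), 0.05))
  } else {
    start <- list(k = max(m_fit) / max(t_fit), n = 1)
  }
  fit <- minpack.lm::nlsLM(m_fit ~ k * t_fit^n, start = start,
                           lower = c(k = 1e-12, n = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((m_fit - mean(m_fit))^2)
  structure(
    list(k = unname(cf["k"]), n = unname(cf["n"]), n_beads = n_beads,
         fit_stats = list(
           r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
           sigma = sqrt(sum(res^2) / max(length(m_fit) - 2, 1)),
           n_obs = length(m_fit))),
    class = "release_model"
  )
}

#' Construct a release model from known parameters
#'
#' @param k Scale constant, mg/h^n. Must be > 0.
#' @param n Diffusional exponent; sanity-bounded to (0, 1.2].
#' @param n_beads Number of discs the parameters refer to.
#' @return A `release_model`.
#' @export
release_model <- function(k, n, n_beads = 3) {
  if (k <= 0) stop("'k' must be > 0")
  if (n <= 0 || n > 1.2) stop("'n' must be in (0, 1.2]")
  structure(list(k = k, n = n, n_beads = n_beads, fit_stats = NULL),
            class = "release_model")
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf("<release_model> M(t) = %.4g * t^%.4g mg (%d bead%s)\n",
              x$k, x$n, x$n_beads, if (x$n_beads == 1) "" else "s"))
  if (!is.null(x$fit_stats))
    cat(sprintf("  r2 = %.4f, residual SE = %.4g mg (%d points)\n",
                x$fit_stats$r_squared, x$fit_stats$sigma, x$fit_stats$n_obs))
  invisible(x)
}

#' Cumulative released mass
#'
#' @param model A `release_model`.
#' @param t Time(s), h; must be >= 0.
#' @return Released mass, mg (vectorised over `t`).
#' @export
released_mass <- function(model, t) {
  if (any(t < 0)) stop("'t' must be >= 0")
  model$k * t^model$n
}

#' Instantaneous release rate
#'
#' dM/dt = k * n * t^(n-1). For n < 1 the rate diverges at t = 0; there
#' the function warns and returns `Inf`.
#'
#' @inheritParams released_mass
#' @return Release rate, mg/h.
#' @export
release_rate <- function(model, t) {
  if (any(t < 0)) stop("'t' must be >= 0")
  out <- model$k * model$n * t^(model$n - 1)
  if (model$n < 1 && any(t == 0)) {
    warning("release rate diverges at t = 0 for n < 1; returning Inf")
    out[t == 0] <- Inf
  }
  out
}

#' Rescale a release model to a different number of discs
#'
#' Release scales linearly with the number of discs: a per-disc model is
#' the fitted k divided by the number of discs fitted.
#'
#' @param model A `release_model`.
#' @param n_beads Target number of discs.
#' @return A `release_model` for `n_beads` discs.
#' @export
scale_beads <- function(model, n_beads) {
  if (n_beads <= 0) stop("'n_beads' must be > 0")
  out <- model
  out$k <- model$k / model$n_beads * n_beads
  out$n_beads <- n_beads
  out$fit_stats <- NULL
  out
}

#' Classify the release mechanism from the diffusional exponent
#'
#' Disc (thin-film) geometry thresholds: n <= 0.50 Fickian diffusion;
#' 0.50 < n < 1.0 anomalous transport (diffusion plus matrix erosion);
#' n >= 1.0 case-II (relaxation/erosion controlled).
#'
#' @param n Diffusional exponent (> 0).
#' @return One of `"Fickian"`, `"anomalous (diffusion + erosion)"`,
#'   `"case-II"`.
#' @export
classify_mechanism <- function(n) {
  if (n <= 0) stop("'n' must be > 0")
  if (n <= 0.50) "Fickian"
  else if (n < 1.0) "anomalous (diffusion + erosion)"
  else "case-II"
}

#' Predict culture-average specific rates from a release model
#'
#' Assuming every mg of substrate released is consumed immediately and
#' biomass stays near-constant (severe carbon limitation), the average
#' specific uptake rate over a time window is the released mass divided
#' by biomass and window length; the implied growth rate follows from
#' the biomass yield.
#'
#' @param model A `release_model`.
#' @param biomass_total Total biomass in the flask, g DCW (> 0).
#' @param Y_XS Biomass yield, g/g.
#' @param window Averaging window `c(t0, t1)` in h, `t1 > t0 >= 0`.
#'   Defaults to the first 24 h of release.
#' @return List with `q_S_avg` (g substrate / g DCW / h) and `mu_avg`
#'   (1/h).
#' @examples
#' m <- release_model(5.13, 0.65)
#' predict_culture_rates(m, biomass_total = 0.29, Y_XS = 0.58)
#' @export
predict_culture_rates <- function(model, biomass_total, Y_XS,
                                  window = c(0, 24)) {
  if (biomass_total <= 0) stop("'biomass_total' must be > 0")
  if (length(window) != 2 || window[2] <= window[1] || window[1] < 0)
    stop("'window' must be c(t0, t1) with t1 > t0 >= 0")
  dm <- released_mass(model, window[2]) - released_mass(model, window[1])
  q_S <- dm / (1000 * biomass_total * (window[2] - window[1]))
  list(q_S_avg = q_S, mu_avg = q_S * Y_XS)
}
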