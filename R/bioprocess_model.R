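#' Product-formation kinetics
#'
#' Two expression modes are modelled. Constitutive glycolytic promoters
#' give growth-coupled production: q_p = alpha * mu, with alpha the
#' product-to-biomass yield (AU/g DCW). Stress/starvation promoters give
#' growth-decoupled production: tightly repressed while substrate is
#' plentiful, and transiently induced once the specific uptake rate
#' drops below a repression threshold, with first-order decay of the
#' induced rate (the induction does not persist even though the
#' limitation does). The induction clock resets whenever uptake rises
#' back above the threshold, so repeated growth/starvation cycles
#' re-induce.
#'
#' @param mode `"growth_coupled"` or `"starvation_induced"`.
#' @param alpha Growth-coupled slope (= Y_P/X), AU / g DCW.
#' @param q_p_max Peak induced specific production rate, AU / g DCW / h.
#' @param q_S_rep Repression threshold on the specific substrate uptake
#'   rate, g / g DCW / h (default 0.02, between the pseudo-starving
#'   uptake of 0.005 and the slowest growth-phase uptake of ~0.044).
#' @param tau Time constant of the transient induction decay, h.
#' @return An object of class `product_kinetics`.
#' @export
product_kinetics <- function(mode = c("growth_coupled", "starvation_induced"),
                             alpha = NULL, q_p_max = NULL, q_S_rep = 0.02,
                             tau = NULL) {
  mode <- match.arg(mode)
  if (mode == "growth_coupled") {
    if (is.null(alpha) || alpha <= 0)
      stop("growth-coupled kinetics need alpha > 0")
  } else {
    if (is.null(q_p_max) || q_p_max <= 0)
      stop("starvation-induced kinetics need q_p_max > 0")
    if (is.null(tau) || tau <= 0) stop("'tau' must be > 0")
    if (q_S_rep <= 0) stop("'q_S_rep' must be > 0")
  }
  structure(list(mode = mode, alpha = alpha, q_p_max = q_p_max,
                 q_S_rep = q_S_rep, tau = tau),
            class = "product_kinetics")
}

#' Growth-coupled specific production rate
#'
#' @param mu Specific growth rate, 1/h (>= 0).
#' @param alpha Product-to-biomass yield Y_P/X, AU / g DCW.
#' @return q_p in AU / g DCW / h.
#' @examples
#' qp_growth_coupled(0.025, 185.22)  # ~4.63 AU/g/h
#' @export
qp_growth_coupled <- function(mu, alpha) {
  if (any(mu < 0)) stop("'mu' must be >= 0")
  alpha * mu
}

#' Starvation-induced specific production rate
#'
#' q_p = q_p_max * exp(-t_since_induction / tau) while q_S is below the
#' repression threshold, and 0 otherwise.
#'
#' @param q_S Instantaneous specific substrate uptake rate, g/g/h.
#' @param t_since_induction Time since the uptake rate last dropped
#'   below the threshold, h.
#' @param q_p_max,q_S_rep,tau See [product_kinetics()].
#' @return q_p in AU / g DCW / h.
#' @export
qp_starvation_induced <- function(q_S, t_since_induction, q_p_max, q_S_rep,
                                  tau) {
  if (any(t_since_induction < 0)) stop("'t_since_induction' must be >= 0")
  ifelse(q_S < q_S_rep, q_p_max * exp(-t_since_induction / tau), 0)
}

#' Simulation parameters
#'
#' @param mu_max Maximum specific growth rate on glycerol, 1/h
#'   (default 0.20).
#' @param K_S Monod half-saturation constant, g/L (default 0.1; during
#'   feeding the culture sits on the steep part of the Monod curve so
#'   growth is feed-determined, the standard fed-batch quasi-steady
#'   picture).
#' @param Y_XS Biomass yield, g DCW / g glycerol.
#' @param m_S Maintenance coefficient, g / g DCW / h (default 0).
#' @param product A [product_kinetics()] object, or `NULL` for a
#'   non-producing simulation.
#' @param substrate,biomass `compound` objects for off-gas stoichiometry.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(mu_max = 0.20, K_S = 0.1, Y_XS = 0.58,
                              m_S = 0, product = NULL,
                              substrate = compound_library("glycerol"),
                              biomass = compound_library("biomass_generic")) {
  if (mu_max <= 0 || Y_XS <= 0 || K_S <= 0) stop("mu_max, K_S, Y_XS must be > 0")
  if (m_S < 0) stop("'m_S' must be >= 0")
  if (!is.null(product) && !inherits(product, "product_kinetics"))
    stop("'product' must be a product_kinetics object or NULL")
  structure(list(mu_max = mu_max, K_S = K_S, Y_XS = Y_XS, m_S = m_S,
                 product = product, substrate = substrate, biomass = biomass),
            class = "simulation_params")
}

# instantaneous kinetic rates given state; used by the ODE right-hand side
.kinetics <- function(S, tind, p) {
  S <- max(S, 0)
  mu <- p$mu_max * S / (p$K_S + S)
  q_S <- mu / p$Y_XS + p$m_S * as.numeric(S > 0)
  q_p <- 0
  if (!is.null(p$product)) {
    pk <- p$product
    q_p <- if (pk$mode == "growth_coupled") qp_growth_coupled(mu, pk$alpha)
           else qp_starvation_induced(q_S, tind, pk$q_p_max, pk$q_S_rep, pk$tau)
  }
  list(mu = mu, q_S = q_S, q_p = q_p)
}

#' Simulate a fed-batch cultivation
#'
#' Integrates the macroscopic fed-batch mass balances
#' dV/dt = F, d(XV)/dt = mu XV, d(SV)/dt = F S_feed - q_S XV,
#' d(PV)/dt = q_p XV, with Monod growth mu = mu_max S/(K_S + S) and
#' q_S = mu/Y_XS + m_S. During feeding phases the residual substrate
#' settles at the quasi-steady concentration at which consumption equals
#' supply, so the realized growth rate is feed-determined. Off-gas rates
#' (OUR, CER, RQ) are attached at every output step from the carbon and
#' electron balances. Phases terminate on substrate depletion (batch), a
#' biomass target, or a fixed duration, per the schedule.
#'
#' @param schedule A [feed_schedule()] (see also [build_schedule()]).
#' @param params A [simulation_params()] object.
#' @param dt_out Output sampling interval, h.
#' @param rtol,atol Solver tolerances passed to [deSolve::ode()].
#' @return A `culture_timecourse`: data.frame with columns `t` (h),
#'   `V` (L), `X` (g DCW/L), `S` (g/L), `P` (AU/mL), `F` (L/h),
#'   `fed` (cumulative fed glycerol, g), `mu` (1/h), `q_S` (g/g/h),
#'   `q_p` (AU/g/h), `OUR`, `CER` (mmol/L/h), `RQ`, and `phase`
#'   (1-based phase index). Attributes `params`, `schedule` and
#'   `phases` (phase boundary table) are attached.
#' @examples
#' sch <- build_schedule("FB-mu", mu_set = 0.15, S0 = 20, X0 = 1)
#' params <- simulation_params(Y_XS = 0.61)
#' tc <- simulate_cultivation(sch, params, dt_out = 0.5)
#' tail(tc[, c("t", "X", "S", "RQ")])
#' @export
simulate_cultivation <- function(schedule, params, dt_out = 0.1,
                                 rtol = 1e-8, atol = 1e-8) {
  if (!inherits(schedule, "feed_schedule")) stop("'schedule' must be a feed_schedule")
  if (!inherits(params, "simulation_params")) stop("'params' must be simulation_params")
  S_deplete <- 0.01   # g/L: batch ends when residual glycerol falls here
  max_phase_h <- 400  # safety cap for target-terminated phases

  state <- c(V = schedule$V0, XV = schedule$X0 * schedule$V0,
             SV = schedule$S0 * schedule$V0, PV = 0, tind = 0, fed = 0)
  t0 <- 0
  rows <- list()
  XV0_vec <- numeric(length(schedule$phases))
  phase_tab <- data.frame(phase = integer(), label = character(),
                          mode = character(), t_start = numeric(),
                          t_end = numeric())

  for (i in seq_along(schedule$phases)) {
    ph <- schedule$phases[[i]]
    XV0 <- unname(state["XV"])
    XV0_vec[i] <- XV0
    feed_fun <- switch(ph$mode,
      batch = function(tau) 0,
      exponential = local({
        mu <- ph$mu_set; Y <- params$Y_XS; mS <- params$m_S
        Sf <- ph$S_feed; XV0c <- XV0
        function(tau) exponential_feed_rate(mu, XV0c, Y, Sf, mS, tau)
      }),
      constant = local({
        Fc <- pseudo_starving_feed_rate(ph$q_S_set, XV0, ph$S_feed)
        function(tau) Fc
      })
    )
    S_feed <- ph$S_feed %||% 0
    # reset the induction clock when entering a growth phase
    if (ph$mode != "constant") state["tind"] <- 0

    rhs <- function(t, y, parms) {
      kin <- .kinetics(y["SV"] / y["V"], y["tind"], params)
      Fr <- feed_fun(t - t0)
      inducing <- as.numeric(kin$q_S < (params$product$q_S_rep %||% Inf))
      list(c(V = Fr,
             XV = kin$mu * y[["XV"]],
             SV = Fr * S_feed - kin$q_S * y[["XV"]],
             PV = kin$q_p * y[["XV"]],
             tind = if (is.null(params$product)) 0 else inducing,
             fed = Fr * S_feed))
    }
    has_root <- (ph$mode == "batch" && is.null(ph$duration)) ||
                !is.null(ph$X_stop)
    rootfun <- function(t, y, parms) {
      r <- numeric(0)
      if (ph$mode == "batch" && is.null(ph$duration))
        r <- c(r, y[["SV"]] / y[["V"]] - S_deplete)
      if (!is.null(ph$X_stop))
        r <- c(r, y[["XV"]] / y[["V"]] - ph$X_stop)
      r
    }
    t_end_max <- t0 + (ph$duration %||% max_phase_h)
    times <- unique(c(seq(t0, t_end_max, by = dt_out), t_end_max))
    sol <- if (has_root) {
      # lsodar halts at the first root (phase termination)
      deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                   method = "lsodar", rootfunc = rootfun,
                   rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol)
    }
    sol <- as.data.frame(sol)
    if (any(!is.finite(unlist(sol[nrow(sol), ]))) ||
        any(sol$V <= 0) || any(sol$XV < -atol))
      stop("integration failed in phase ", i, " ('", ph$label, "'); ",
           "last state: ", paste(round(unlist(sol[nrow(sol), ]), 4),
                                 collapse = ", "))
    sol$phase <- i
    rows[[i]] <- if (i == 1) sol else sol[-1, ]
    phase_tab <- rbind(phase_tab,
                       data.frame(phase = i, label = ph$label, mode = ph$mode,
                                  t_start = t0, t_end = max(sol$time)))
    last <- sol[nrow(sol), ]
    state <- c(V = last$V, XV = last$XV, SV = max(last$SV, 0), PV = last$PV,
               tind = last$tind, fed = last$fed)
    t0 <- last$time
  }

  out <- do.call(rbind, rows)
  # instantaneous rates and off-gas at each output step
  kin <- lapply(seq_len(nrow(out)), function(j)
    .kinetics(out$SV[j] / out$V[j], out$tind[j], params))
  mu <- vapply(kin, `[[`, numeric(1), "mu")
  q_S <- vapply(kin, `[[`, numeric(1), "q_S")
  q_p <- vapply(kin, `[[`, numeric(1), "q_p")
  X <- out$XV / out$V
  OUR <- CER <- RQ <- rep(NA_real_, nrow(out))
  for (j in seq_len(nrow(out))) {
    if (q_S[j] > 0) {
      g <- gas_rates_from_yields(q_S[j], mu[j] / q_S[j],
                                 params$substrate, params$biomass, X = X[j])
      OUR[j] <- g$OUR; CER[j] <- g$CER; RQ[j] <- g$RQ
    } else OUR[j] <- CER[j] <- 0
  }
  Fr <- numeric(nrow(out))
  for (i in seq_along(schedule$phases)) {
    idx <- out$phase == i
    ph <- schedule$phases[[i]]
    ts <- phase_tab$t_start[i]
    Fr[idx] <- switch(ph$mode,
      batch = 0,
      exponential = exponential_feed_rate(ph$mu_set, XV0_vec[i],
        params$Y_XS, ph$S_feed, params$m_S, out$time[idx] - ts),
      constant = pseudo_starving_feed_rate(ph$q_S_set, XV0_vec[i],
                                           ph$S_feed))
  }
  tc <- data.frame(t = out$time, V = out$V, X = X, S = pmax(out$SV, 0) / out$V,
                   P = out$PV / (out$V * 1000), F = Fr, fed = out$fed,
                   mu = mu, q_S = q_S, q_p = q_p,
                   OUR = OUR, CER = CER, RQ = RQ, phase = out$phase)
  attr(tc, "params") <- params
  attr(tc, "schedule") <- schedule
  attr(tc, "phases") <- phase_tab
  class(tc) <- c("culture_timecourse", "data.frame")
  tc
}

#' Phase boundary table of a simulated time course
#'
#' @param tc A `culture_timecourse`.
#' @return data.frame with phase index, label, mode, start and end time.
#' @export
phase_table <- function(tc) attr(tc, "phases")

#' Write a time course as delimited text
#'
#' @param tc A `culture_timecourse` (or compatible data.frame).
#' @param path Output file; tab-separated with a header line.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.table(as.data.frame(tc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a time course written by [write_timecourse()]
#'
#' @param path Input file.
#' @return data.frame with the documented time-course columns.
#' @export
read_timecourse <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
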