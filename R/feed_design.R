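#' Define one feed phase
#'
#' A cultivation is described as an ordered list of phases. Three modes
#' are supported: `batch` (no feed, runs to substrate depletion or for a
#' fixed duration), `exponential` (pre-programmed feed holding a
#' constant specific growth rate `mu_set`), and `constant` (fixed feed
#' rate sized to deliver a target specific uptake rate `q_S_set` at the
#' biomass present when the phase starts; the pseudo-starving regime).
#'
#' @param mode One of `"batch"`, `"exponential"`, `"constant"`.
#' @param mu_set Set-point specific growth rate (1/h), exponential mode.
#' @param q_S_set Set-point specific substrate uptake rate (g/g/h),
#'   constant mode.
#' @param S_feed Feed glycerol concentration, g/L (feeding modes).
#' @param X_stop Terminate when biomass reaches this DCW, g/L.
#' @param duration Terminate after this many hours.
#' @param label Optional phase label.
#' @return An object of class `feed_phase`.
#' @export
feed_phase <- function(mode = c("batch", "exponential", "constant"),
                       mu_set = NULL, q_S_set = NULL, S_feed = NULL,
                       X_stop = NULL, duration = NULL, label = NULL) {
  mode <- match.arg(mode)
  missing_par <- character()
  if (mode == "exponential") {
    if (is.null(mu_set)) missing_par <- c(missing_par, "mu_set")
    if (is.null(S_feed)) missing_par <- c(missing_par, "S_feed")
    if (!is.null(mu_set) && mu_set <= 0) stop("'mu_set' must be > 0")
  }
  if (mode == "constant") {
    if (is.null(q_S_set)) missing_par <- c(missing_par, "q_S_set")
    if (is.null(S_feed)) missing_par <- c(missing_par, "S_feed")
    if (!is.null(q_S_set) && q_S_set <= 0) stop("'q_S_set' must be > 0")
  }
  if (length(missing_par))
    stop("missing parameters for ", mode, " phase: ",
         paste(missing_par, collapse = ", "))
  if (!is.null(S_feed) && S_feed <= 0) stop("'S_feed' must be > 0")
  if (is.null(X_stop) && is.null(duration) && mode != "batch")
    stop("feeding phases need a termination rule: 'X_stop' or 'duration'")
  structure(
    list(mode = mode, mu_set = mu_set, q_S_set = q_S_set, S_feed = S_feed,
         X_stop = X_stop, duration = duration,
         label = label %||% mode),
    class = "feed_phase"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a feed schedule
#'
#' @param phases List of [feed_phase()] objects; the first must be a
#'   batch phase.
#' @param strain Strain label (bookkeeping).
#' @param V0 Initial volume, L.
#' @param X0 Initial biomass, g DCW/L.
#' @param S0 Initial (batch) glycerol, g/L.
#' @return An object of class `feed_schedule`.
#' @export
feed_schedule <- function(phases, strain = "strain", V0 = 2, X0 = 0.5,
                          S0 = 40) {
  if (!length(phases)) stop("need at least one phase")
  if (!all(vapply(phases, inherits, logical(1), "feed_phase")))
    stop("'phases' must be a list of feed_phase objects")
  if (phases[[1]]$mode != "batch") stop("the first phase must be a batch phase")
  if (V0 <= 0 || X0 < 0 || S0 < 0) stop("invalid initial state")
  structure(list(phases = phases, strain = strain, V0 = V0, X0 = X0, S0 = S0),
            class = "feed_schedule")
}

#' @export
print.feed_schedule <- function(x, ...) {
  cat(sprintf("<feed_schedule> %s: V0 %.2g L, X0 %.2g g/L, S0 %.2g g/L\n",
              x$strain, x$V0, x$X0, x$S0))
  for (i in seq_along(x$phases)) {
    p <- x$phases[[i]]
    stopr <- if (!is.null(p$X_stop)) sprintf("to %.3g g/L DCW", p$X_stop)
             else if (!is.null(p$duration)) sprintf("for %.3g h", p$duration)
             else "to substrate depletion"
    set <- switch(p$mode,
                  batch = "",
                  exponential = sprintf(" mu %.3g /h,", p$mu_set),
                  constant = sprintf(" q_S %.3g g/g/h,", p$q_S_set))
    cat(sprintf("  %d. %-12s%s %s\n", i, p$label, set, stopr))
  }
  invisible(x)
}

#' Exponential feed rate for a constant specific growth rate
#'
#' From the biomass mass balance, the feed rate that keeps the specific
#' growth rate at `mu_set` under carbon limitation is
#' F(t) = (mu_set / Y_XS + m_S) * XV0 * exp(mu_set * t) / S_feed.
#'
#' @param mu_set Set-point growth rate, 1/h.
#' @param XV0 Total biomass at feed start, g DCW.
#' @param Y_XS Biomass yield, g/g.
#' @param S_feed Feed substrate concentration, g/L.
#' @param m_S Maintenance coefficient, g substrate / g DCW / h
#'   (default 0).
#' @param t Time since feed start, h (vectorised).
#' @return Feed rate, L/h.
#' @examples
#' exponential_feed_rate(0.15, 40, 0.61, 400, t = 0)  # 0.0246 L/h
#' @export
exponential_feed_rate <- function(mu_set, XV0, Y_XS, S_feed, m_S = 0, t = 0) {
  if (S_feed <= 0) stop("'S_feed' must be > 0")
  if (Y_XS <= 0) stop("'Y_XS' must be > 0")
  if (mu_set < 0 || XV0 < 0 || m_S < 0 || any(t < 0))
    stop("arguments must be >= 0")
  (mu_set / Y_XS + m_S) * XV0 * exp(mu_set * t) / S_feed
}

#' Constant feed rate for pseudo-starving induction
#'
#' Sizes the constant feed that delivers a target specific substrate
#' uptake rate to the biomass present at induction start. This is the
#' bioreactor implementation of the uptake regime slow-release discs
#' give in shake flasks (q_S about 0.005 g/g/h, implying an initial
#' growth rate near 0.003 1/h).
#'
#' @param q_S_set Target specific uptake rate, g substrate / g DCW / h.
#' @param X_total Total biomass at induction start, g DCW.
#' @param S_feed Feed substrate concentration, g/L.
#' @return Feed rate, L/h.
#' @examples
#' pseudo_starving_feed_rate(0.005, 140, 400)  # 1.75 mL/h
#' @export
pseudo_starving_feed_rate <- function(q_S_set, X_total, S_feed) {
  if (q_S_set <= 0 || X_total <= 0 || S_feed <= 0)
    stop("all arguments must be > 0")
  q_S_set * X_total / S_feed
}

#' Build a named cultivation strategy
#'
#' Constructs the three fed-batch strategies studied for growth-coupled
#' versus growth-decoupled production:
#' \describe{
#'   \item{`FB-mu`}{batch, then one exponential constant-mu phase
#'     terminating at a DCW target (default 80 g/L).}
#'   \item{`PS`}{batch, exponential growth at mu 0.15 1/h to 70 g/L,
#'     then a single constant-rate pseudo-starving induction
#'     (q_S 0.005 g/g/h).}
#'   \item{`3-PS`}{batch plus three cycles of exponential growth (mu
#'     0.15 1/h, to 40, 60, 80 g/L) each followed by a 24 h
#'     pseudo-starving induction.}
#' }
#'
#' @param strategy One of `"FB-mu"`, `"PS"`, `"3-PS"`.
#' @param mu_set Growth-phase specific growth rate, 1/h (FB-mu default
#'   0.025; PS and 3-PS default 0.15).
#' @param q_S_set Induction specific uptake rate, g/g/h (default 0.005).
#' @param X_stop DCW target(s), g/L: scalar for FB-mu (80) and PS (70),
#'   length-3 vector for 3-PS (40, 60, 80).
#' @param induction_hours Duration of each constant-rate induction, h
#'   (PS default 40, 3-PS default 24).
#' @param S_feed Feed glycerol concentration, g/L (default 400; the
#'   actual feed strength is rig-specific and configurable).
#' @param strain,V0,X0,S0 Passed to [feed_schedule()].
#' @return A `feed_schedule`.
#' @export
build_schedule <- function(strategy = c("FB-mu", "PS", "3-PS"),
                           mu_set = NULL, q_S_set = 0.005, X_stop = NULL,
                           induction_hours = NULL, S_feed = 400,
                           strain = strategy, V0 = 2, X0 = 0.5, S0 = 40) {
  strategy <- match.arg(strategy)
  batch <- feed_phase("batch", label = "batch")
  phases <- switch(
    strategy,
    "FB-mu" = {
      mu_set <- mu_set %||% 0.025
      X_stop <- X_stop %||% 80
      list(batch,
           feed_phase("exponential", mu_set = mu_set, S_feed = S_feed,
                      X_stop = X_stop,
                      label = sprintf("exp mu=%.3g", mu_set)))
    },
    "PS" = {
      mu_set <- mu_set %||% 0.15
      X_stop <- X_stop %||% 70
      induction_hours <- induction_hours %||% 40
      list(batch,
           feed_phase("exponential", mu_set = mu_set, S_feed = S_feed,
                      X_stop = X_stop, label = "growth"),
           feed_phase("constant", q_S_set = q_S_set, S_feed = S_feed,
                      duration = induction_hours, label = "pseudo-starving"))
    },
    "3-PS" = {
      mu_set <- mu_set %||% 0.15
      X_stop <- X_stop %||% c(40, 60, 80)
      induction_hours <- induction_hours %||% 24
      if (length(X_stop) != 3) stop("'X_stop' must have length 3 for 3-PS")
      ph <- list(batch)
      for (i in 1:3) {
        ph <- c(ph, list(
          feed_phase("exponential", mu_set = mu_set, S_feed = S_feed,
                     X_stop = X_stop[i], label = sprintf("growth %d", i)),
          feed_phase("constant", q_S_set = q_S_set, S_feed = S_feed,
                     duration = induction_hours,
                     label = sprintf("pseudo-starving %d", i))))
      }
      ph
    }
  )
  feed_schedule(phases, strain = strain, V0 = V0, X0 = X0, S0 = S0)
}

#' Export a feed profile as a two-column table
#'
#' Evaluates the feed-rate profile of a simulated cultivation (or a
#' single exponential phase) on a time grid for transfer to a pump
#' controller.
#'
#' @param tc A simulated time course (see [simulate_cultivation()]).
#' @param path Optional file; when given, a tab-separated two-column
#'   table (t, F) is written.
#' @return Invisibly, a data.frame with columns `t` (h) and `F` (L/h).
#' @export
export_feed_profile <- function(tc, path = NULL) {
  out <- data.frame(t = tc$t, F = tc$F)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(out)
}
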