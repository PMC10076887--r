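# default relative standard deviations per measured rate, from the
# precision of the underlying assays: DCW < 5%, HPLC (substrate) < 1%,
# off-gas < 5%
.DEFAULT_RATE_RSD <- c(substrate = 0.01, biomass = 0.05, o2 = 0.05,
                       co2 = 0.05)

#' Measured specific rate vector for balance reconciliation
#'
#' Rates are on a C-mol (or mol, for O2/CO2) per g DCW per h basis, with
#' the sign convention consumed negative / produced positive:
#' substrate and O2 negative, biomass and CO2 positive. The measurement
#' covariance defaults to a diagonal built from per-assay relative
#' standard deviations.
#'
#' @param substrate,biomass,o2,co2 Specific rates (C-mol or mol / g DCW
#'   / h), signed.
#' @param sd Optional vector of standard deviations (same order); when
#'   omitted, `rsd * |rate|` is used.
#' @param rsd Relative standard deviations per species (named vector;
#'   defaults substrate 1%, biomass 5%, O2 5%, CO2 5%).
#' @return An object of class `rate_vector`: list with `rates` (named
#'   numeric of length 4) and `cov` (4 x 4 diagonal matrix).
#' @export
rate_vector <- function(substrate, biomass, o2, co2, sd = NULL,
                        rsd = .DEFAULT_RATE_RSD) {
  x <- c(substrate = unname(substrate), biomass = unname(biomass),
         o2 = unname(o2), co2 = unname(co2))
  if (any(!is.finite(x))) stop("rates must be finite")
  if (is.null(sd)) sd <- rsd[names(x)] * abs(x)
  if (any(sd <= 0))
    stop("zero/negative measurement standard deviations: covariance not positive definite")
  structure(list(rates = x, cov = diag(sd^2, nrow = 4,
                                       ncol = 4)),
            class = "rate_vector")
}

#' Convert mass-based measurements to a C-mol rate vector
#'
#' Bridges routinely reported quantities (q_S in g/g/h, mu in 1/h, gas
#' rates in mmol/g/h) to the C-mol basis and sign convention used by the
#' balances.
#'
#' @param q_S Specific substrate uptake, g / g DCW / h (positive).
#' @param mu Specific growth rate, 1/h.
#' @param q_O2,q_CO2 Specific gas rates, mmol / g DCW / h (positive).
#' @param substrate,biomass `compound` objects.
#' @param ... Passed to [rate_vector()] (e.g. `sd`, `rsd`).
#' @return A `rate_vector`.
#' @export
rate_vector_from_mass <- function(q_S, mu, q_O2, q_CO2,
                                  substrate = compound_library("glycerol"),
                                  biomass = compound_library("biomass_generic"),
                                  ...) {
  rate_vector(substrate = -q_S / substrate$cmol_mass,
              biomass = mu / biomass$cmol_mass,
              o2 = -q_O2 / 1000, co2 = q_CO2 / 1000, ...)
}

#' Carbon and electron balance matrix
#'
#' Row 1 carries the carbon content per unit rate of each species (1 for
#' C-mol based species and CO2, 0 for O2); row 2 the degree of reduction
#' (gamma of substrate and biomass, -4 for O2, 0 for CO2). With the
#' consumed-negative sign convention, a consistent rate vector x
#' satisfies E x = 0.
#'
#' @param substrate,biomass `compound` objects.
#' @return 2 x 4 matrix with columns substrate, biomass, o2, co2.
#' @examples
#' balance_matrix()
#' @export
balance_matrix <- function(substrate = compound_library("glycerol"),
                           biomass = compound_library("biomass_generic")) {
  for (cmp in list(substrate, biomass))
    if (!inherits(cmp, "compound")) stop("inputs must be 'compound' objects")
  E <- rbind(carbon = c(1, 1, 0, 1),
             electron = c(substrate$gamma, biomass$gamma, -4, 0))
  colnames(E) <- c("substrate", "biomass", "o2", "co2")
  E
}

#' Reconcile measured rates against conservation balances
#'
#' Balance-constrained weighted least squares: the measured vector is
#' projected onto the null space of the balance matrix, weighting by the
#' measurement covariance, x_hat = x - Sigma E' (E Sigma E')^-1 E x.
#' The residual epsilon = E x gives the consistency statistic
#' h = epsilon' (E Sigma E')^-1 epsilon, chi-squared distributed with
#' rank(E) degrees of freedom when the measurements are consistent.
#'
#' @param x A [rate_vector()].
#' @param E Balance matrix (default [balance_matrix()] with the generic
#'   compositions).
#' @param confidence Confidence level of the consistency test
#'   (default 0.95).
#' @return An object of class `reconciliation_result`: list with
#'   `x_hat` (reconciled rates), `residual` (epsilon), `h`, `dof`,
#'   `critical`, `pass`, `confidence`, and `recovery` (carbon/electron
#'   recovery of the measured vector, %).
#' @export
reconcile <- function(x, E = balance_matrix(), confidence = 0.95) {
  if (!inherits(x, "rate_vector")) stop("'x' must be a rate_vector")
  if (qr(E)$rank < nrow(E)) stop("'E' must have full row rank")
  S <- x$cov
  ESE <- E %*% S %*% t(E)
  kappa <- kappa(ESE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("E Sigma E' is numerically singular (condition number ",
         format(kappa, digits = 3), ")")
  eps <- drop(E %*% x$rates)
  W <- solve(ESE)
  x_hat <- x$rates - drop(S %*% t(E) %*% W %*% eps)
  h <- drop(t(eps) %*% W %*% eps)
  dof <- nrow(E)
  ct <- consistency_test(h, dof, confidence)
  structure(list(x_hat = x_hat, residual = eps, h = h, dof = dof,
                 critical = ct$critical, pass = ct$pass,
                 confidence = confidence, recovery = recovery(x, E)),
            class = "reconciliation_result")
}

#' @export
print.reconciliation_result <- function(x, ...) {
  cat(sprintf("<reconciliation> h = %.4g (chi2 crit %.3f at %.0f%%, dof %d): %s\n",
              x$h, x$critical, 100 * x$confidence, x$dof,
              if (x$pass) "consistent" else "GROSS ERROR suspected"))
  cat(sprintf("  recovery: carbon %.1f%%, electron %.1f%%\n",
              x$recovery["carbon"], x$recovery["electron"]))
  invisible(x)
}

#' Chi-squared consistency test
#'
#' @param h Test statistic from [reconcile()] (>= 0).
#' @param dof Degrees of freedom (>= 1).
#' @param confidence Confidence level in (0, 1); default 0.95 (critical
#'   value 5.991 at dof 2).
#' @return List with `pass` (logical), `critical` and `p_value`.
#' @export
consistency_test <- function(h, dof, confidence = 0.95) {
  if (dof < 1 || dof != round(dof)) stop("'dof' must be a positive integer")
  if (confidence <= 0 || confidence >= 1) stop("'confidence' must be in (0, 1)")
  if (h < 0) stop("'h' must be >= 0")
  crit <- stats::qchisq(confidence, df = dof)
  list(pass = h <= crit, critical = crit,
       p_value = stats::pchisq(h, df = dof, lower.tail = FALSE))
}

#' Carbon and electron recovery of a measured rate vector
#'
#' Carbon recovery is carbon appearing in products (biomass + CO2) as a
#' percentage of carbon disappearing from consumed substrate; electron
#' recovery weights rates by degree of reduction, counting O2 uptake as
#' the electron sink. Both equal 100% for an exactly balanced vector.
#'
#' @param x A [rate_vector()].
#' @param E Balance matrix (provides the gamma entries).
#' @return Named numeric: `carbon` and `electron`, %.
#' @export
recovery <- function(x, E = balance_matrix()) {
  if (!inherits(x, "rate_vector")) stop("'x' must be a rate_vector")
  r <- x$rates
  carbon_w <- E["carbon", ] * r
  elec_w <- E["electron", ] * r
  c_cons <- -sum(carbon_w[carbon_w < 0])
  e_cons <- -sum(elec_w[elec_w < 0])   # electron source: consumed substrate
  # sink: electrons fixed in biomass plus those taken up by O2 (gamma -4
  # times a negative rate is positive)
  e_sink <- sum(elec_w[elec_w > 0])
  if (c_cons == 0 || e_cons == 0)
    stop("zero consumption: recovery undefined")
  c(carbon = 100 * sum(carbon_w[carbon_w > 0]) / c_cons,
    electron = 100 * e_sink / e_cons)
}
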