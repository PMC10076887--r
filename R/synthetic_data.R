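#' Measurement noise model
#'
#' Relative standard deviations of the routine assays, matching the
#' precision of the instrumentation typically reported for this kind of
#' cultivation work: dry cell weight < 5% (measured in quadruplicate),
#' HPLC substrate quantification < 1%, off-gas molar fractions < 5%,
#' lipolytic activity < 4%. Noise is multiplicative (Gaussian with
#' channel-specific relative SD), reflecting the relative nature of the
#' stated precisions.
#'
#' @param rsd_dcw,rsd_hplc,rsd_gas,rsd_activity Relative SDs in (0, 1).
#' @param replicates_dcw Number of DCW replicate weighings averaged per
#'   reported sample (default 4).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rsd_dcw = 0.05, rsd_hplc = 0.01, rsd_gas = 0.05,
                        rsd_activity = 0.04, replicates_dcw = 4) {
  rsds <- c(rsd_dcw, rsd_hplc, rsd_gas, rsd_activity)
  if (any(rsds < 0) || any(rsds >= 1)) stop("RSDs must be in [0, 1)")
  if (replicates_dcw < 1) stop("'replicates_dcw' must be >= 1")
  structure(list(rsd_dcw = rsd_dcw, rsd_hplc = rsd_hplc, rsd_gas = rsd_gas,
                 rsd_activity = rsd_activity,
                 replicates_dcw = replicates_dcw),
            class = "noise_model")
}

# multiplicative Gaussian noise, truncated at zero
.mnoise <- function(x, rsd, n = length(x)) {
  pmax(x * (1 + stats::rnorm(n, 0, rsd)), 0)
}

# off-gas bookkeeping: map OUR/CER (mmol/L/h) to outlet molar fractions
# at a fixed gas feed, and back. Inert-balance approximation (outlet
# molar flow ~ inlet), air at 20.95% O2 / 0.04% CO2, 25 C ideal gas.
.GAS <- list(y_O2_in = 0.2095, y_CO2_in = 0.0004, Vm = 24.465)

.gas_to_fractions <- function(OUR, CER, V, airflow_L_min = 2) {
  n_in <- airflow_L_min * 60 / .GAS$Vm * 1000   # mmol total gas / h
  list(y_O2 = (.GAS$y_O2_in * n_in - OUR * V) / n_in,
       y_CO2 = (.GAS$y_CO2_in * n_in + CER * V) / n_in)
}

.fractions_to_gas <- function(y_O2, y_CO2, V, airflow_L_min = 2) {
  n_in <- airflow_L_min * 60 / .GAS$Vm * 1000
  list(OUR = (.GAS$y_O2_in - y_O2) * n_in / V,
       CER = (y_CO2 - .GAS$y_CO2_in) * n_in / V)
}

#' Sample a noisy measured dataset from a simulated time course
#'
#' Applies the channel-specific multiplicative noise of a
#' [noise_model()] to a simulated cultivation: DCW is reported as the
#' mean of replicate noisy weighings, substrate and activity get their
#' assay RSDs, and off-gas noise is applied to the inlet-outlet molar
#' fraction differences (the quantity OUR and CER are computed from, and
#' the one whose relative precision the per-batch recalibrated analyser
#' controls) before the rates are recomputed. All channels are truncated
#' at zero.
#'
#' @param tc A `culture_timecourse`.
#' @param nm A [noise_model()].
#' @param airflow_L_min Gas feed used for the molar-fraction bridge,
#'   L/min (default 2).
#' @return A data.frame shaped like `tc` with noisy `X`, `S`, `P`,
#'   `OUR`, `CER`, `RQ` columns (other columns carried through).
#' @export
noisy_timecourse <- function(tc, nm = noise_model(), airflow_L_min = 2) {
  out <- as.data.frame(tc)
  n <- nrow(out)
  reps <- matrix(.mnoise(rep(out$X, nm$replicates_dcw), nm$rsd_dcw),
                 nrow = n)
  out$X <- rowMeans(reps)
  out$S <- .mnoise(out$S, nm$rsd_hplc)
  if (!is.null(out$P)) out$P <- .mnoise(out$P, nm$rsd_activity)
  if (!is.null(out$OUR) && !is.null(out$CER)) {
    fr <- .gas_to_fractions(out$OUR, out$CER, out$V, airflow_L_min)
    d_O2 <- .mnoise(.GAS$y_O2_in - fr$y_O2, nm$rsd_gas)
    d_CO2 <- .mnoise(fr$y_CO2 - .GAS$y_CO2_in, nm$rsd_gas)
    g <- .fractions_to_gas(.GAS$y_O2_in - d_O2, .GAS$y_CO2_in + d_CO2,
                           out$V, airflow_L_min)
    out$OUR <- pmax(g$OUR, 0)
    out$CER <- pmax(g$CER, 0)
    out$RQ <- ifelse(out$OUR > 0, out$CER / out$OUR, NA_real_)
  }
  out
}

#' Sample noisy cumulative release measurements
#'
#' @param model A `release_model`.
#' @param times Sampling times, h (> 0, sorted ascending).
#' @param sigma_mg Additive Gaussian SD of the HPLC-derived cumulative
#'   mass, mg (default 1.132, the residual scatter scale of a typical
#'   3-disc fit).
#' @param enforce_monotone Re-sort masses to be non-decreasing
#'   (default `FALSE`).
#' @return data.frame with `t` (h) and `mass` (mg, truncated >= 0).
#' @export
release_samples <- function(model, times, sigma_mg = 1.132,
                            enforce_monotone = FALSE) {
  if (any(times <= 0)) stop("'times' must be > 0")
  if (is.unsorted(times)) stop("'times' must be sorted ascending")
  m <- pmax(released_mass(model, times) +
              stats::rnorm(length(times), 0, sigma_mg), 0)
  if (enforce_monotone) m <- cummax(m)
  data.frame(t = times, mass = m)
}

#' Multiply one measured rate by a gross-error factor
#'
#' Fixture generator for the consistency test: corrupts a single rate
#' while leaving the claimed covariance unchanged, the signature of an
#' undetected instrument fault.
#'
#' @param x A [rate_vector()].
#' @param which One of `"substrate"`, `"biomass"`, `"o2"`, `"co2"`.
#' @param factor Multiplicative error (> 0).
#' @return A `rate_vector` with the corrupted rate.
#' @export
inject_gross_error <- function(x, which, factor) {
  if (!inherits(x, "rate_vector")) stop("'x' must be a rate_vector")
  if (factor <= 0) stop("'factor' must be > 0")
  if (!which %in% names(x$rates))
    stop("unknown species '", which, "'; expected one of ",
         paste(names(x$rates), collapse = ", "))
  x$rates[which] <- x$rates[which] * factor
  x
}

#' Generate a synthetic transcript count table
#'
#' Negative-binomial counts across samples with one designated dominant
#' gene, for exercising the TPM ranking. Gene lengths are drawn
#' uniformly between 500 and 5000 bp.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_samples Number of samples.
#' @param dominant_gene_frac Expected fraction of the length-normalized
#'   transcript pool (hence of TPM) taken by the dominant gene
#'   (default 0.2).
#' @param dispersion NB dispersion (size parameter; default 10).
#' @param mean_count Baseline expected count per non-dominant gene
#'   (default 100).
#' @return data.frame with `gene_id`, `length` and one count column per
#'   sample; the dominant gene is `"g1"`.
#' @export
synthetic_counts <- function(n_genes = 50, n_samples = 5,
                             dominant_gene_frac = 0.2, dispersion = 10,
                             mean_count = 100) {
  if (n_genes < 2) stop("'n_genes' must be >= 2")
  if (dominant_gene_frac <= 0 || dominant_gene_frac >= 1)
    stop("'dominant_gene_frac' must be in (0, 1)")
  lengths <- round(stats::runif(n_genes, 500, 5000))
  mu <- rep(mean_count, n_genes)
  # dominance is defined on the length-normalized (TPM) scale: the
  # dominant gene's expected count-per-kb is frac/(1-frac) times the
  # summed count-per-kb of all other genes
  mu[1] <- dominant_gene_frac / (1 - dominant_gene_frac) *
    sum(mu[-1] / lengths[-1]) * lengths[1]
  cts <- vapply(seq_len(n_samples), function(s)
    stats::rnbinom(n_genes, size = dispersion, mu = mu), numeric(n_genes))
  out <- data.frame(gene_id = paste0("g", seq_len(n_genes)),
                    length = lengths, cts)
  names(out)[-(1:2)] <- paste0("sample", seq_len(n_samples))
  out
}

#' Generate noisy balanced rate vectors
#'
#' Draws replicate measured rate vectors around an exactly balanced
#' truth constructed from a biomass yield on glycerol, applying the
#' per-assay RSDs multiplicatively. Used for calibration checks of the
#' reconciliation machinery (pass rate of the consistency test, recovery
#' distributions).
#'
#' @param n Number of replicates.
#' @param Y_XS Biomass yield defining the balanced truth, g/g.
#' @param q_S Specific uptake rate of the truth, g/g/h.
#' @param substrate,biomass `compound` objects.
#' @param rsd Named RSD vector (see [rate_vector()]).
#' @return List with `truth` (a `rate_vector`) and `replicates` (list of
#'   `n` noisy `rate_vector`s).
#' @export
noisy_balanced_rates <- function(n, Y_XS = 0.58, q_S = 0.044,
                                 substrate = compound_library("glycerol"),
                                 biomass = compound_library("biomass_generic"),
                                 rsd = .DEFAULT_RATE_RSD) {
  g <- gas_rates_from_yields(q_S, Y_XS, substrate, biomass)
  truth <- rate_vector_from_mass(q_S, Y_XS * q_S, g$q_O2, g$q_CO2,
                                 substrate, biomass, rsd = rsd)
  reps <- lapply(seq_len(n), function(i) {
    noisy <- truth$rates * (1 + stats::rnorm(4, 0, rsd[names(truth$rates)]))
    rate_vector(noisy["substrate"], noisy["biomass"], noisy["o2"],
                noisy["co2"], rsd = rsd)
  })
  list(truth = truth, replicates = reps)
}
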