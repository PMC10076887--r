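# trapezoidal integral of y over t
.trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# rows of a time course falling in [t0, t1); the sample closest to t1 is
# included as the phase endpoint so differences span the whole phase
.phase_rows <- function(tc, phase) {
  t0 <- phase[1]; t1 <- phase[2]
  if (t1 <= t0) stop("'phase' must be c(t0, t1) with t1 > t0")
  idx <- which(tc$t >= t0 - 1e-9 & tc$t <= t1 + 1e-9)
  if (length(idx) < 3) stop("fewer than 3 samples in the requested phase")
  idx
}

#' Estimate specific growth and uptake rates from a time course
#'
#' The realized specific growth rate is the least-squares slope of
#' ln(total biomass) against time; the specific uptake rate is total
#' substrate consumed (fed glycerol corrected for the change in
#' dissolved glycerol) divided by the biomass-time integral (trapezoid).
#'
#' @param tc Time course with columns `t`, `V`, `X`, `S` and (for q_S)
#'   `fed`; typically from [simulate_cultivation()] or
#'   [noisy_timecourse()].
#' @param phase Time window `c(t0, t1)`, h (closed-open; the last sample
#'   at or before `t1` closes the window).
#' @return List with `mu_real` (1/h), `q_S` (g/g/h), and
#'   `substrate_consumed` (g).
#' @export
estimate_rates <- function(tc, phase) {
  idx <- .phase_rows(tc, phase)
  t <- tc$t[idx]
  XV <- tc$X[idx] * tc$V[idx]
  if (any(XV <= 0)) stop("total biomass must be positive throughout the phase")
  mu_real <- unname(stats::coef(stats::lm(log(XV) ~ t))[2])
  q_S <- NA_real_
  consumed <- NA_real_
  if (!is.null(tc$fed)) {
    SV <- tc$S[idx] * tc$V[idx]
    fed <- tc$fed[idx]
    consumed <- (fed[length(fed)] - fed[1]) + (SV[1] - SV[length(SV)])
    if (consumed < 0)
      warning("negative inferred substrate consumption; check the phase window")
    q_S <- consumed / .trapz(t, XV)
  }
  list(mu_real = mu_real, q_S = q_S, substrate_consumed = consumed)
}

#' Compute key performance indicators for a cultivation phase
#'
#' Yields, rates, productivities and titer over a phase window, using
#' the conventions of fed-batch physiology reporting: titer is the total
#' activity in the vessel in kAU (activity in AU/mL times volume in L);
#' the specific production rate divides total product formed by the
#' biomass-time integral; volumetric productivity divides it by final
#' volume and phase length. Undefined ratios (zero denominators) are
#' returned as `NA` rather than raised as errors.
#'
#' @inheritParams estimate_rates
#' @return An object of class `kpi_record`: list with `mu_real`, `q_S`,
#'   `Y_XS`, `Y_PX` (AU/g), `Y_PS` (AU/g), `q_p` (AU/g/h), `Q_v`
#'   (AU/L/h), `titer_total` (kAU), `activity` (AU/mL, at phase end),
#'   `RQ` (mean over phase, if present), `phase` and `strain`.
#' @export
compute_kpis <- function(tc, phase) {
  idx <- .phase_rows(tc, phase)
  t <- tc$t[idx]
  V <- tc$V[idx]
  XV <- tc$X[idx] * V
  dt <- t[length(t)] - t[1]
  est <- estimate_rates(tc, phase)
  int_XV <- .trapz(t, XV)
  dX_total <- XV[length(XV)] - XV[1]

  has_P <- !is.null(tc$P)
  if (has_P) {
    PV <- tc$P[idx] * V * 1000          # AU/mL * L * 1000 = AU total
    dP_total <- PV[length(PV)] - PV[1]
    activity_end <- tc$P[idx][length(idx)]
    V_end <- V[length(V)]
  }
  safe_div <- function(a, b) if (isTRUE(is.finite(b)) && b != 0) a / b else NA_real_

  structure(list(
    mu_real = est$mu_real,
    q_S = est$q_S,
    Y_XS = safe_div(est$mu_real, est$q_S),
    Y_PX = if (has_P) safe_div(dP_total, dX_total) else NA_real_,
    Y_PS = if (has_P) safe_div(dP_total, est$substrate_consumed) else NA_real_,
    q_p = if (has_P) safe_div(dP_total, int_XV) else NA_real_,
    Q_v = if (has_P) safe_div(dP_total, V_end * dt) else NA_real_,
    titer_total = if (has_P) activity_end * V_end else NA_real_,
    activity = if (has_P) activity_end else NA_real_,
    RQ = if (!is.null(tc$RQ)) mean(tc$RQ[idx], na.rm = TRUE) else NA_real_,
    phase = phase,
    strain = attr(tc, "schedule")$strain %||% NA_character_
  ), class = "kpi_record")
}

#' @export
print.kpi_record <- function(x, ...) {
  cat("<kpi_record>", if (!is.na(x$strain)) x$strain else "", "\n")
  cat(sprintf("  mu %.4g /h  q_S %.4g g/g/h  Y_X/S %.3g g/g\n",
              x$mu_real, x$q_S, x$Y_XS))
  if (is.finite(x$titer_total))
    cat(sprintf("  titer %.4g kAU  Y_P/X %.4g AU/g  q_p %.4g AU/g/h  Q_v %.4g AU/L/h\n",
                x$titer_total, x$Y_PX, x$q_p, x$Q_v))
  invisible(x)
}

#' Fold change between two KPI values
#'
#' @param a,b Numeric values; `b` must be > 0.
#' @return `a / b`.
#' @examples
#' fold_change(4.53, 1.25)  # 3.6-fold
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("'b' must be > 0")
  a / b
}

#' Convert a chromogenic assay slope to volumetric activity
#'
#' For a p-nitrophenyl ester assay read at 405 nm, activity of the
#' undiluted supernatant is slope / (epsilon * path) * dilution_factor,
#' in umol p-nitrophenol released per minute per mL (= AU/mL). One
#' activity unit releases 1 umol p-nitrophenol per minute.
#'
#' @param dA405_dt Absorbance slope, 1/min.
#' @param epsilon Molar absorptivity of p-nitrophenol under assay
#'   conditions, 1/mM/cm. Assay-specific; no default is assumed.
#' @param path Optical path length, cm.
#' @param dilution_factor Assay dilution of the supernatant (default 10:
#'   900 uL buffer + 100 uL sample).
#' @return Activity in AU/mL.
#' @export
activity_from_slope <- function(dA405_dt, epsilon, path = 1,
                                dilution_factor = 10) {
  if (epsilon <= 0 || path <= 0) stop("'epsilon' and 'path' must be > 0")
  if (dilution_factor <= 0) stop("'dilution_factor' must be > 0")
  dA405_dt / (epsilon * path) * dilution_factor
}

#' Transcripts per million and expression ranking
#'
#' Computes TPM per sample from a count table
#' (TPM_g = 1e6 * (count_g / length_kb_g) / sum_j(count_j / length_kb_j))
#' and ranks genes by their median, mean and maximum TPM across samples,
#' descending. Used to shortlist consistently highly expressed genes
#' (promoter candidates) across cultivation conditions.
#'
#' @param counts data.frame with columns `gene_id`, `length` (bp), and
#'   one column of read counts per sample.
#' @return List with `tpm` (data.frame, same shape as the count columns)
#'   and `ranking` (data.frame with `gene_id`, `median_tpm`, `mean_tpm`,
#'   `max_tpm` and the three rank columns, ordered by median rank).
#' @export
tpm_and_rank <- function(counts) {
  if (!all(c("gene_id", "length") %in% names(counts)))
    stop("'counts' needs columns 'gene_id' and 'length'")
  if (any(counts$length <= 0)) stop("gene lengths must be > 0")
  sample_cols <- setdiff(names(counts), c("gene_id", "length"))
  if (!length(sample_cols)) stop("no sample count columns found")
  cts <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (any(cts < 0)) stop("counts must be >= 0")
  if (any(colSums(cts) == 0))
    stop("sample(s) with all-zero counts: TPM undefined")
  rate <- cts / (counts$length / 1000)          # counts per kb
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  med <- apply(tpm, 1, stats::median)
  mn <- rowMeans(tpm)
  mx <- apply(tpm, 1, max)
  ranking <- data.frame(
    gene_id = counts$gene_id,
    median_tpm = med, mean_tpm = mn, max_tpm = mx,
    rank_median = rank(-med, ties.method = "min"),
    rank_mean = rank(-mn, ties.method = "min"),
    rank_max = rank(-mx, ties.method = "min"))
  ranking <- ranking[order(ranking$rank_median, ranking$rank_mean), ]
  rownames(ranking) <- NULL
  list(tpm = data.frame(gene_id = counts$gene_id, tpm,
                        check.names = FALSE),
       ranking = ranking)
}
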