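#' Run a cultivation scenario from a config file
#'
#' The scenario runner ties the pipeline stages together: it builds the
#' feed schedule, simulates the cultivation, samples a noisy measured
#' dataset, estimates KPIs over the feeding phase(s), and reconciles the
#' mean measured rates against the carbon and electron balances. A
#' scenario is a single human-readable YAML file; three bundled examples
#' live under `system.file("extdata", package = "fedbatchkit")`
#' (`scenario_gap_0.025.yaml`, `scenario_pdh_ps.yaml`,
#' `scenario_pdh_3ps.yaml`).
#'
#' Config fields (all defaults are surfaced in the bundled files):
#' `strain`, `strategy` (FB-mu | PS | 3-PS), `promoter_mode`
#' (growth_coupled | starvation_induced), `seed`, nested `feed`,
#' `kinetics`, `product` and `noise` blocks, and `output` paths
#' (`timecourse`, `kpi`, `reconciliation`; omit to skip writing).
#'
#' @param config Path to a YAML scenario file, or an equivalent named
#'   list.
#' @param out_dir Optional directory prepended to relative output paths.
#' @return Invisibly, a list with `timecourse`, `noisy`, `kpis` (one
#'   `kpi_record` per feeding span), `reconciliation` and the parsed
#'   `config`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validate_scenario(cfg)
  set.seed(cfg$seed)

  feed <- cfg$feed
  sch <- build_schedule(cfg$strategy,
                        mu_set = feed$mu_set,
                        q_S_set = feed$q_S_set %||% 0.005,
                        X_stop = if (!is.null(feed$X_stop)) unlist(feed$X_stop),
                        induction_hours = feed$induction_hours,
                        S_feed = feed$S_feed %||% 400,
                        strain = cfg$strain,
                        V0 = feed$V0 %||% 2, X0 = feed$X0 %||% 0.5,
                        S0 = feed$S0 %||% 40)
  kin <- cfg$kinetics %||% list()
  prod_cfg <- cfg$product %||% list()
  product <- if (identical(cfg$promoter_mode, "growth_coupled")) {
    product_kinetics("growth_coupled", alpha = prod_cfg$alpha %||% 100)
  } else {
    product_kinetics("starvation_induced",
                     q_p_max = prod_cfg$q_p_max %||% 12.5,
                     q_S_rep = prod_cfg$q_S_rep %||% 0.02,
                     tau = prod_cfg$tau %||% 12)
  }
  params <- simulation_params(mu_max = kin$mu_max %||% 0.20,
                              K_S = kin$K_S %||% 0.1,
                              Y_XS = kin$Y_XS %||% 0.58,
                              m_S = kin$m_S %||% 0,
                              product = product)
  tc <- simulate_cultivation(sch, params, dt_out = cfg$dt_out %||% 0.25)
  noise_cfg <- cfg$noise %||% list()
  nm <- noise_model(rsd_dcw = noise_cfg$rsd_dcw %||% 0.05,
                    rsd_hplc = noise_cfg$rsd_hplc %||% 0.01,
                    rsd_gas = noise_cfg$rsd_gas %||% 0.05,
                    rsd_activity = noise_cfg$rsd_activity %||% 0.04)
  noisy <- noisy_timecourse(tc, nm)

  ptab <- phase_table(tc)
  feeding <- ptab[ptab$mode != "batch", , drop = FALSE]
  span <- c(min(feeding$t_start), max(feeding$t_end))
  kpi <- compute_kpis(tc, span)
  message(sprintf("[%s] %d phases; feeding %0.1f-%0.1f h; titer %.3g kAU",
                  cfg$strain, nrow(ptab), span[1], span[2],
                  kpi$titer_total))

  growth <- ptab[ptab$mode == "exponential", , drop = FALSE]
  rec <- NULL
  if (nrow(growth)) {
    gphase <- c(growth$t_start[1], growth$t_end[1])
    est <- estimate_rates(tc, gphase)
    idx <- tc$t >= gphase[1] & tc$t <= gphase[2]
    qo2 <- mean(tc$OUR[idx] / tc$X[idx])
    qco2 <- mean(tc$CER[idx] / tc$X[idx])
    rv <- rate_vector_from_mass(est$q_S, est$mu_real, qo2, qco2,
                                params$substrate, params$biomass)
    rec <- reconcile(rv, balance_matrix(params$substrate, params$biomass))
  }

  outp <- cfg$output %||% list()
  resolve <- function(p) if (is.null(out_dir)) p else file.path(out_dir, p)
  if (!is.null(outp$timecourse)) write_timecourse(noisy, resolve(outp$timecourse))
  if (!is.null(outp$kpi))
    jsonlite::write_json(unclass(kpi), resolve(outp$kpi), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(outp$reconciliation) && !is.null(rec))
    jsonlite::write_json(lapply(unclass(rec), function(v)
      if (is.numeric(v)) as.list(v) else v),
      resolve(outp$reconciliation), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)

  invisible(list(timecourse = tc, noisy = noisy, kpis = list(kpi),
                 reconciliation = rec, config = cfg))
}

.validate_scenario <- function(cfg) {
  problems <- character()
  req <- c("strain", "strategy", "promoter_mode", "seed")
  for (f in req) if (is.null(cfg[[f]])) problems <- c(problems, f)
  if (!is.null(cfg$strategy) && !cfg$strategy %in% c("FB-mu", "PS", "3-PS"))
    problems <- c(problems, "strategy (must be FB-mu, PS or 3-PS)")
  if (!is.null(cfg$promoter_mode) &&
      !cfg$promoter_mode %in% c("growth_coupled", "starvation_induced"))
    problems <- c(problems,
                  "promoter_mode (must be growth_coupled or starvation_induced)")
  if (length(problems))
    stop("invalid scenario config; problems with field(s): ",
         paste(problems, collapse = ", "))
  invisible(TRUE)
}

#' Render KPI records as a comparison table
#'
#' Formats one or more [compute_kpis()] records as an aligned table
#' using the row vocabulary of fed-batch physiology reports ("Real mu",
#' "q_s", "Y_x/s", "RQ", "Titer", "Y_p/x", "q_p", "Specific
#' productivity", "Volumetric productivity", "Y_p/s", "Lipolytic
#' activity"). With exactly two records a fold-change column
#' (first / second) is appended.
#'
#' @param kpis A `kpi_record` or list of them.
#' @param digits Significant digits (default 3).
#' @return data.frame with a `parameter` column, one column per record,
#'   and `fold_change` when two records are given.
#' @export
report_tables <- function(kpis, digits = 3) {
  if (inherits(kpis, "kpi_record")) kpis <- list(kpis)
  if (!length(kpis)) stop("need at least one KPI record")
  if (!all(vapply(kpis, inherits, logical(1), "kpi_record")))
    stop("'kpis' must be kpi_record objects")
  rows <- c("Real mu (1/h)" = "mu_real",
            "q_s (g/g/h)" = "q_S",
            "Y_x/s (g/g)" = "Y_XS",
            "RQ" = "RQ",
            "Titer (kAU)" = "titer_total",
            "Lipolytic activity (AU/mL)" = "activity",
            "Y_p/x (AU/g)" = "Y_PX",
            "Y_p/s (AU/g)" = "Y_PS",
            "q_p / Specific productivity (AU/g/h)" = "q_p",
            "Volumetric productivity (AU/L/h)" = "Q_v")
  vals <- vapply(kpis, function(k)
    vapply(rows, function(f) as.numeric(k[[f]]), numeric(1)), numeric(length(rows)))
  vals <- matrix(vals, nrow = length(rows))
  labels <- vapply(seq_along(kpis), function(i)
    if (!is.na(kpis[[i]]$strain)) kpis[[i]]$strain else paste0("run", i),
    character(1))
  labels <- make.unique(labels)
  out <- data.frame(parameter = names(rows), signif(vals, digits))
  names(out)[-1] <- labels
  if (length(kpis) == 2)
    out$fold_change <- signif(ifelse(vals[, 2] > 0, vals[, 1] / vals[, 2],
                                     NA_real_), digits)
  out
}
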