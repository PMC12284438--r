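#' Uniformly rescale a flow waveform to a target cardiac output
#'
#' @param wf A flow [waveform()] (mL/s) with positive mean.
#' @param cardiac_output Target cardiac output (mL/min); the per-cycle
#'   volume becomes `cardiac_output * T / 60`.
#' @return The rescaled [waveform()] (shape preserved).
#' @export
scale_flow_to_co <- function(wf, cardiac_output) {
  stopifnot(inherits(wf, "waveform"), cardiac_output > 0)
  vol <- wf_cycle_integral(wf)
  if (vol <= 0) stop("waveform must have positive mean flow")
  target <- cardiac_output * wf$period / 60
  waveform(wf$time, wf$values * target / vol, wf$period)
}

# allocate a total distal resistance over terminals
.allocate_resistance <- function(tree, R_total,
                                 allocation = c("murray", "equal")) {
  allocation <- match.arg(allocation)
  term <- tree$terminals
  r <- tree$segments$radius_cm[match(term, tree$segments$id)]
  R_i <- if (allocation == "murray") R_total * sum(r^3) / r^3
         else rep(R_total * length(term), length(term))
  data.frame(terminal_id = unname(term), R_total_i = unname(R_i),
             stringsAsFactors = FALSE)
}

# build a terminal windkessel map from total resistance + uniform Sd
.wk_map_from <- function(tree, R_total, S_d, allocation = "murray") {
  al <- .allocate_resistance(tree, R_total, allocation)
  data.frame(terminal_id = al$terminal_id,
             R1 = al$R_total_i / 2, R2 = al$R_total_i / 2,
             Cd = 1 / S_d, stringsAsFactors = FALSE)
}

#' Calibrate baseline Windkessel parameters to measured hemodynamics
#'
#' Finds the total distal resistance and uniform distal stiffness such
#' that the simulated main-pulmonary-artery pressure matches a measured
#' mean pressure and pulse pressure (systolic minus diastolic). The two
#' problems are nearly separable -- mean pressure is set by resistance,
#' pulse pressure mostly by compliance -- so the routine alternates
#' multiplicative updates of each, at most `max_iter` times, stopping
#' when both targets agree within `tol` (relative).
#'
#' The calibrated total resistance is allocated over terminals either in
#' proportion to `r^-3` (Murray-law consistent, the default) or equally;
#' each terminal gets `R1 = R2` (half its allocated total) and
#' compliance `Cd = 1/S_d`.
#'
#' @param tree A [vascular_tree()].
#' @param params Wall [ho_params()].
#' @param inflow Root inflow [waveform()] (mL/s), already scaled to the
#'   measured cardiac output (see [scale_flow_to_co()]).
#' @param target_delta_mpa Measured MPA pulse pressure (mmHg).
#' @param target_mean_mpa Measured MPA mean pressure (mmHg).
#' @param config A [sim_config()].
#' @param allocation `"murray"` or `"equal"` terminal resistance split.
#' @param max_iter,tol Outer iteration controls.
#' @param S_d_bounds Allowed distal-stiffness range (mmHg/mL).
#' @return List of class `pa_calibration`: `R_d_total` (mmHg s/mL),
#'   `S_d` (mmHg/mL), `wk_map`, `achieved` (delta/mean), `converged`,
#'   `history`, and the final `simulation`.
#' @export
calibrate_baseline <- function(tree, params, inflow, target_delta_mpa,
                               target_mean_mpa, config = sim_config(),
                               allocation = "murray",
                               max_iter = 14, tol = 0.001,
                               S_d_bounds = c(1, 1e6)) {
  stopifnot(target_delta_mpa > 0, target_mean_mpa > 0)
  target_delta_mpa <- unname(target_delta_mpa)
  target_mean_mpa <- unname(target_mean_mpa)
  mean_q <- mean(inflow$values)
  if (mean_q <= 0) stop("inflow must have positive mean flow")
  R_total <- target_mean_mpa / mean_q
  sv <- wf_cycle_integral(inflow)
  S_d <- length(tree$terminals) * target_delta_mpa / sv
  history <- list()
  converged <- FALSE
  sim <- NULL
  prev <- NULL      # previous (log S_d, log delta) for the secant update
  n_pinned <- 0L    # consecutive iterations with S_d at a bound
  for (it in seq_len(max_iter)) {
    wk_map <- .wk_map_from(tree, R_total, S_d, allocation)
    sim <- simulate_tree(tree, params, inflow, wk_map, config)
    P <- extract_waveforms(sim, position = "proximal")$P
    mean_sim <- mean(P$values)
    delta_sim <- delta_mpa_pressure(P)
    history[[it]] <- data.frame(iter = it, R_d_total = R_total, S_d = S_d,
                                mean_mpa = mean_sim, delta_mpa = delta_sim)
    if (abs(mean_sim - target_mean_mpa) <= tol * target_mean_mpa &&
        abs(delta_sim - target_delta_mpa) <= tol * target_delta_mpa) {
      converged <- TRUE
      break
    }
    if (mean_sim <= 0 || delta_sim <= 0)
      stop("calibration produced non-physical pressures; achieved mean = ",
           signif(mean_sim, 4), ", delta = ", signif(delta_sim, 4))
    # mean pressure is essentially linear in total resistance
    R_total <- R_total * (target_mean_mpa / mean_sim)
    # pulse pressure: secant in log-log space against distal stiffness,
    # with a clamped step; a flat response means the distal compliance no
    # longer controls the pulse (it is proximal-limited)
    cur <- c(log(S_d), log(delta_sim))
    if (!is.null(prev) && abs(cur[1] - prev[1]) > 1e-12) {
      g <- (cur[2] - prev[2]) / (cur[1] - prev[1])
      if (abs(g) < 0.01 &&
          abs(delta_sim - target_delta_mpa) > 0.05 * target_delta_mpa) {
        hist_df <- do.call(rbind, history)
        stop(sprintf(paste0(
          "target pulse pressure %.3g mmHg appears unreachable: ",
          "achieved %.3g-%.3g mmHg over S_d in [%.3g, %.3g] ",
          "(pulse is proximal-limited)"),
          target_delta_mpa, min(hist_df$delta_mpa), max(hist_df$delta_mpa),
          min(hist_df$S_d), max(hist_df$S_d)))
      }
      step <- (log(target_delta_mpa) - cur[2]) / sign(g) /
        max(abs(g), 0.05)
      step <- max(min(step, log(8)), -log(8))
      S_d_new <- exp(cur[1] + step)
    } else {
      S_d_new <- S_d * (target_delta_mpa / delta_sim)^2
    }
    prev <- cur
    S_d <- max(min(S_d_new, S_d_bounds[2]), S_d_bounds[1])
    n_pinned <- if (S_d %in% S_d_bounds) n_pinned + 1L else 0L
    if (n_pinned >= 2L) {
      hist_df <- do.call(rbind, history)
      stop(sprintf(paste0(
        "target pulse pressure %.3g mmHg is unreachable within the ",
        "distal-stiffness bounds [%g, %g]: achieved %.3g-%.3g mmHg"),
        target_delta_mpa, S_d_bounds[1], S_d_bounds[2],
        min(hist_df$delta_mpa), max(hist_df$delta_mpa)))
    }
  }
  structure(list(R_d_total = R_total, S_d = S_d,
                 wk_map = .wk_map_from(tree, R_total, S_d, allocation),
                 achieved = c(delta_mpa = history[[length(history)]]$delta_mpa,
                              mean_mpa = history[[length(history)]]$mean_mpa),
                 converged = converged,
                 history = do.call(rbind, history),
                 simulation = sim, allocation = allocation),
            class = "pa_calibration")
}

#' @export
print.pa_calibration <- function(x, ...) {
  cat(sprintf(
    "Windkessel calibration (%s): R_d_total = %.4g mmHg s/mL, S_d = %.4g mmHg/mL\n  achieved delta = %.3g, mean = %.3g mmHg (%d iterations)\n",
    if (x$converged) "converged" else "NOT converged",
    x$R_d_total, x$S_d, x$achieved["delta_mpa"], x$achieved["mean_mpa"],
    nrow(x$history)))
  invisible(x)
}

#' Build the in-silico remodeling scenario matrix
#'
#' Enumerates the hypothetical remodeling states used to separate the
#' contributions of stiffness, resistance and flow: control; control
#' with the (lower) hypertensive flow; proximal-stiffness-only;
#' distal-stiffness-only; combined stiffness increase; distal-resistance
#' increase; stiffness + resistance; and the full hypertensive state
#' (stiffness + resistance + hypertensive flow).
#'
#' @param ph_scales List with elements `S_p` (proximal stiffness scale
#'   on c and k1), `S_d_scale` (distal stiffness scale; terminal
#'   compliance is divided by it) and `R_d_scale` (distal resistance
#'   scale).
#' @return data.frame with columns `label`, `S_p`, `S_d_scale`,
#'   `R_d_scale`, `flow` (`"control"` or `"ph"`).
#' @export
build_scenario_matrix <- function(ph_scales = list(S_p = 2, S_d_scale = 2,
                                                   R_d_scale = 3)) {
  s <- ph_scales
  stopifnot(s$S_p > 0, s$S_d_scale > 0, s$R_d_scale > 0)
  if (any(unlist(s[c("S_p", "S_d_scale", "R_d_scale")]) < 1))
    warning("remodeling scales < 1 invert the hypertensive direction")
  out <- rbind(
    data.frame(label = "CTL",            S_p = 1,     S_d_scale = 1,           R_d_scale = 1,           flow = "control"),
    data.frame(label = "CTL_PH_flow",    S_p = 1,     S_d_scale = 1,           R_d_scale = 1,           flow = "ph"),
    data.frame(label = "Sp_only",        S_p = s$S_p, S_d_scale = 1,           R_d_scale = 1,           flow = "control"),
    data.frame(label = "Sd_only",        S_p = 1,     S_d_scale = s$S_d_scale, R_d_scale = 1,           flow = "control"),
    data.frame(label = "S_up",           S_p = s$S_p, S_d_scale = s$S_d_scale, R_d_scale = 1,           flow = "control"),
    data.frame(label = "Rd_up",          S_p = 1,     S_d_scale = 1,           R_d_scale = s$R_d_scale, flow = "control"),
    data.frame(label = "S_Rd_up",        S_p = s$S_p, S_d_scale = s$S_d_scale, R_d_scale = s$R_d_scale, flow = "control"),
    data.frame(label = "S_Rd_up_PH_flow", S_p = s$S_p, S_d_scale = s$S_d_scale, R_d_scale = s$R_d_scale, flow = "ph"))
  stopifnot(!anyDuplicated(out$label))
  out
}

#' Run the remodeling scenarios and summarize each
#'
#' Simulates every scenario on the same tree: proximal stiffening scales
#' the wall parameters via [apply_stiffness_scaling()], distal scales
#' multiply every terminal's resistances and divide its compliance, and
#' the inflow is the control or hypertensive waveform. Reports MPA pulse
#' pressure and the impedance indices Z0 and Zc computed with the
#' pulse-pressure convention.
#'
#' @param scenarios data.frame from [build_scenario_matrix()].
#' @param tree A [vascular_tree()].
#' @param params Baseline wall [ho_params()].
#' @param baseline_wk Baseline Windkessel map (data.frame
#'   `terminal_id,R1,R2,Cd`), e.g. from [calibrate_baseline()].
#' @param inflows List with flow [waveform()]s `control` and `ph`.
#' @param config A [sim_config()].
#' @param f_max Zc band bound (Hz).
#' @return data.frame, one row per scenario: `label`,
#'   `delta_mpa_pressure`, `systolic_mpa`, `diastolic_mpa`, `Z0`, `Zc`,
#'   `converged`. Failed scenarios are kept with `NA` metrics.
#' @export
run_scenarios <- function(scenarios, tree, params, baseline_wk, inflows,
                          config = sim_config(), f_max = 250) {
  stopifnot(all(c("label", "S_p", "S_d_scale", "R_d_scale", "flow") %in%
                  names(scenarios)),
            all(c("control", "ph") %in% names(inflows)))
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    out <- data.frame(label = sc$label, delta_mpa_pressure = NA_real_,
                      systolic_mpa = NA_real_, diastolic_mpa = NA_real_,
                      Z0 = NA_real_, Zc = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      p_s <- apply_stiffness_scaling(params, sc$S_p)
      wk <- baseline_wk
      wk$R1 <- wk$R1 * sc$R_d_scale
      wk$R2 <- wk$R2 * sc$R_d_scale
      wk$Cd <- wk$Cd / sc$S_d_scale
      sim <- simulate_tree(tree, p_s, inflows[[sc$flow]], wk, config)
      wf <- extract_waveforms(sim, position = "proximal")
      spec <- impedance_spectrum(pulse_pressure_waveform(wf$P), wf$Q)
      list(delta = delta_mpa_pressure(wf$P), sys = max(wf$P$values),
           dia = min(wf$P$values), Z0 = z0(spec), Zc = zc(spec, f_max),
           conv = sim$converged)
    }, error = function(e) {
      warning("scenario '", sc$label, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      out$delta_mpa_pressure <- res$delta
      out$systolic_mpa <- res$sys
      out$diastolic_mpa <- res$dia
      out$Z0 <- res$Z0
      out$Zc <- res$Zc
      out$converged <- res$conv
    }
    out
  })
  do.call(rbind, rows)
}

#' Interaction index of combined remodeling events
#'
#' The excess of the combined scenario's change in a metric over the sum
#' of the single-factor changes (all relative to baseline):
#' `I = (m_combined - m_base) - sum(m_single - m_base)`. Nonzero values
#' mean the remodeling mechanisms interact rather than add.
#'
#' @param results data.frame from [run_scenarios()].
#' @param baseline_label,single_labels,combined_label Scenario labels.
#' @param metric Column of `results` to analyze (e.g.
#'   `"delta_mpa_pressure"`, `"Z0"`, `"Zc"`).
#' @return Interaction index in the metric's units.
#' @export
interaction_index <- function(results, baseline_label = "CTL",
                              single_labels = c("S_up", "Rd_up"),
                              combined_label = "S_Rd_up",
                              metric = "delta_mpa_pressure") {
  get1 <- function(lab) {
    j <- which(results$label == lab)
    if (length(j) != 1L) stop("label not found (or duplicated): ", lab)
    results[[metric]][j]
  }
  m_base <- get1(baseline_label)
  m_comb <- get1(combined_label)
  (m_comb - m_base) - sum(vapply(single_labels,
                                 function(l) get1(l) - m_base, numeric(1)))
}

#' Write scenario results as tidy CSV plus a JSON summary
#' @param results data.frame from [run_scenarios()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_scenarios <- function(results, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    long <- do.call(rbind, lapply(
      c("delta_mpa_pressure", "systolic_mpa", "diastolic_mpa", "Z0", "Zc"),
      function(m) data.frame(label = results$label, metric = m,
                             value = results[[m]])))
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(results, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(results)
}
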