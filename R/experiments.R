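#' Define an experimental condition
#'
#' A condition fixes the structural variant of the driver region and the
#' drive parameters of driver and cortical nodes. The study's default
#' contrast pairs high driver noise (`eta = 0.022`, modelling reticular
#' activating system and sensory-relay afferences) against near-zero noise
#' (`eta = 2.2e-8`) across the parceled / single / removed variants.
#'
#' @param sc_variant one of `"parceled"`, `"single"`, `"removed"`.
#' @param driver_role role tag of the driver group.
#' @param driver_p,driver_eta drive mean / noise std for driver nodes (ms^-1).
#' @param cortical_p,cortical_eta drive mean / noise std elsewhere (ms^-1).
#' @param name optional condition label (defaults to a compact summary).
#' @return list of class `jr_condition`.
#' @export
condition <- function(sc_variant = c("parceled", "single", "removed"),
                      driver_role = "thalamic", driver_p = 0.09,
                      driver_eta = 0.022, cortical_p = 0.09,
                      cortical_eta = 2.2e-8, name = NULL) {
  sc_variant <- match.arg(sc_variant)
  if (is.null(name))
    name <- sprintf("%s_eta%g", sc_variant, driver_eta)
  structure(list(sc_variant = sc_variant, driver_role = driver_role,
                 driver_p = driver_p, driver_eta = driver_eta,
                 cortical_p = cortical_p, cortical_eta = cortical_eta,
                 name = name), class = "jr_condition")
}

#' Default condition set of the driver-noise experiment
#'
#' Three structural variants crossed with two driver-noise levels.
#'
#' @param driver_role role tag of the driver group.
#' @param etas the two driver noise levels (ms^-1).
#' @return list of six `jr_condition` objects.
#' @export
default_conditions <- function(driver_role = "thalamic",
                               etas = c(0.022, 2.2e-8)) {
  out <- list()
  for (v in c("parceled", "single", "removed"))
    for (e in etas)
      out[[length(out) + 1]] <- condition(v, driver_role, driver_eta = e)
  out
}

#' Run one simulation trial and score it
#'
#' Builds the condition's structural variant, simulates at coupling `g`, and
#' computes the full metric record: fit to the reference target (`r_plv`
#' between cortical PLV upper triangles, `ksd` between dFC correlation
#' distributions), per-group signal extrema, spectral peak of the
#' node-averaged spectrum, driver SNR and cortex/driver relative power.
#' Divergent simulations are recorded as failed rows instead of aborting.
#'
#' @param sc a `structural_connectome` (parceled, i.e. unmodified).
#' @param cond a [condition()].
#' @param g coupling factor.
#' @param config a [sim_config()] (its seed is used as-is).
#' @param reference_target a `pseudo_empirical_target` (or NULL to skip the
#'   fit metrics).
#' @param params a [jr_parameters()].
#' @return one-row data.frame.
#' @export
run_trial <- function(sc, cond, g, config, reference_target = NULL,
                      params = jr_parameters()) {
  scv <- build_variant(sc, cond$driver_role, cond$sc_variant)
  drive <- drive_config(scv, cond$cortical_p, cond$cortical_eta,
                        driver_role = if (cond$sc_variant == "removed") NULL
                                      else cond$driver_role,
                        driver_p = cond$driver_p,
                        driver_eta = cond$driver_eta)
  rec <- data.frame(subject = sc$subject_id, condition = cond$name,
                    sc_variant = cond$sc_variant,
                    driver_eta = cond$driver_eta, driver_p = cond$driver_p,
                    g = g, seed = config$seed,
                    r_plv = NA_real_, ksd = NA_real_,
                    max_cortical = NA_real_, min_cortical = NA_real_,
                    max_driver = NA_real_, min_driver = NA_real_,
                    peak_freq = NA_real_, snr_driver = NA_real_,
                    relative_power = NA_real_,
                    plv_mean = NA_real_, plv_sd = NA_real_, failed = FALSE,
                    stringsAsFactors = FALSE)
  sim <- tryCatch(
    simulate_network(scv, params, drive, coupling_config(g = g), config),
    error = function(e) e)
  if (inherits(sim, "error")) {
    rec$failed <- TRUE
    attr(rec, "error") <- conditionMessage(sim)
    return(rec)
  }
  x <- post_transient(sim)
  cx <- which(scv$roles == "cortical")
  drv <- which(scv$roles == cond$driver_role)
  rec$max_cortical <- mean(apply(x[cx, , drop = FALSE], 1, max))
  rec$min_cortical <- mean(apply(x[cx, , drop = FALSE], 1, min))
  if (length(drv)) {
    rec$max_driver <- mean(apply(x[drv, , drop = FALSE], 1, max))
    rec$min_driver <- mean(apply(x[drv, , drop = FALSE], 1, min))
    if (cond$driver_eta > 0)
      rec$snr_driver <- snr(x, cond$driver_eta, drv)
  }
  spec <- spectral_summary(x, sim$fs)
  rec$peak_freq <- spec$peak_freq
  if (length(drv))
    rec$relative_power <- relative_power(spec, cx, drv)
  fc_cx <- tryCatch(fc_from_sim(sim)$values[cx, cx, drop = FALSE],
                    error = function(e) NULL)
  if (!is.null(fc_cx)) {
    ut <- fc_cx[upper.tri(fc_cx)]
    rec$plv_mean <- mean(ut)
    rec$plv_sd <- stats::sd(ut)
  }
  if (!is.null(reference_target)) {
    fit <- tryCatch({
      r <- fc_similarity(fc_cx, reference_target$fc)
      dfc <- dfc_from_sim(sim, region_mask = cx)
      k <- ks_distance(dfc, reference_target$dfc_correlations)
      list(r = r, k = k)
    }, error = function(e) NULL)
    # near-flat low-noise runs can yield undefined correlations; keep NA + flag
    if (is.null(fit)) rec$failed <- TRUE else {
      rec$r_plv <- fit$r
      rec$ksd <- fit$k
    }
  }
  rec
}

#' Coupling sweep over a cohort
#'
#' Full factorial sweep (subject x condition x g x repetition). Repetition
#' seeds are split deterministically from the master seed so any single
#' record can be reproduced in isolation via [run_trial()].
#'
#' @param cohort list of `structural_connectome` objects.
#' @param conditions list of [condition()] objects.
#' @param g_grid numeric coupling grid (the study protocol spans 0-60).
#' @param reps repetitions per cell.
#' @param config a [sim_config()] template (seed overridden per record).
#' @param targets list of `pseudo_empirical_target`, one per subject (or a
#'   single target recycled, or NULL).
#' @param seed master seed.
#' @param params a [jr_parameters()].
#' @param verbose print progress.
#' @return long-format data.frame of class `sweep_table`, one row per record,
#'   with a `rep` column.
#' @export
g_sweep <- function(cohort, conditions, g_grid = seq(0, 60, by = 5), reps = 3,
                    config = sim_config(), targets = NULL, seed = 1,
                    params = jr_parameters(), verbose = FALSE) {
  if (length(g_grid) == 0 || length(conditions) == 0)
    stop("empty grid or condition set")
  if (!is.null(targets) && inherits(targets, "pseudo_empirical_target"))
    targets <- rep(list(targets), length(cohort))
  rows <- list()
  for (si in seq_along(cohort)) {
    for (ci in seq_along(conditions)) {
      for (gi in seq_along(g_grid)) {
        for (r in seq_len(reps)) {
          cfg <- config
          cfg$seed <- split_seed(seed, ((si * 100 + ci) * 100 + gi) * 10 + r)
          rec <- run_trial(cohort[[si]], conditions[[ci]], g_grid[gi], cfg,
                           if (!is.null(targets)) targets[[si]], params)
          rec$rep <- r
          rows[[length(rows) + 1]] <- rec
        }
      }
      if (verbose)
        message(sprintf("subject %d/%d condition %s done",
                        si, length(cohort), conditions[[ci]]$name))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Average a sweep table over repetitions
#'
#' @param sweep_table a [g_sweep()] result.
#' @return data.frame with one row per (subject, condition, g), metric columns
#'   repetition-averaged (NA-tolerant).
#' @export
average_reps <- function(sweep_table) {
  metric_cols <- c("r_plv", "ksd", "max_cortical", "min_cortical",
                   "max_driver", "min_driver", "peak_freq", "snr_driver",
                   "relative_power", "plv_mean", "plv_sd")
  agg <- stats::aggregate(
    sweep_table[metric_cols],
    by = sweep_table[c("subject", "condition", "sc_variant", "driver_eta",
                       "driver_p", "g")],
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  agg[order(agg$subject, agg$condition, agg$g), ]
}

#' Two-dimensional drive/coupling exploration
#'
#' Varies the driver drive mean (`driver_p`) or noise (`driver_eta`) against
#' the coupling factor `g` and records the heatmap panel set per cell: fit to
#' the reference, mean and std of simulated PLV entries, spectral peak,
#' driver SNR, and cortical bifurcation extrema.
#'
#' @param sc a `structural_connectome`.
#' @param vary `"driver_p"` or `"driver_eta"`.
#' @param vary_grid grid for the varied drive parameter.
#' @param g_grid coupling grid.
#' @param config a [sim_config()] (10 s with 2 s transient by default,
#'   matching the exploration protocol).
#' @param target optional `pseudo_empirical_target` for `r_plv`/`ksd`.
#' @param cond base [condition()] (parceled, high driver noise by default).
#' @param seed master seed.
#' @param params a [jr_parameters()].
#' @return data.frame, one row per cell, with the varied value in `vary_value`.
#' @export
grid_exploration <- function(sc, vary = c("driver_p", "driver_eta"),
                             vary_grid, g_grid, config = sim_config(),
                             target = NULL, cond = condition("parceled"),
                             seed = 1, params = jr_parameters()) {
  vary <- match.arg(vary)
  rows <- list()
  for (vi in seq_along(vary_grid)) {
    for (gi in seq_along(g_grid)) {
      cnd <- cond
      if (vary == "driver_p") cnd$driver_p <- vary_grid[vi]
      else cnd$driver_eta <- vary_grid[vi]
      cfg <- config
      cfg$seed <- split_seed(seed, vi * 1000 + gi)
      rec <- run_trial(sc, cnd, g_grid[gi], cfg, target, params)
      rec$vary <- vary
      rec$vary_value <- vary_grid[vi]
      rows[[length(rows) + 1]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Recover the coupling factor from a pseudo-empirical target
#'
#' The parameter-recovery experiment: sweeps the coupling grid, and per grid
#' value runs `reps` repetitions, averages their cortical PLV matrices before
#' correlating with the target FC, and pools their dFC correlation samples
#' into one distribution before taking the KS distance to the target's dFC
#' sample. Within the prebifurcation regime the PLV pattern is nearly
#' invariant to `g`, so the dFC distribution (KSD) is the identifying
#' statistic and `g_hat` is its argmin; the argmax-r_PLV estimate is reported
#' alongside.
#'
#' @param sc a `structural_connectome`.
#' @param target a `pseudo_empirical_target`.
#' @param g_grid coupling grid to search.
#' @param reps repetitions per grid value.
#' @param config a [sim_config()] template.
#' @param seed master seed for repetition seeds.
#' @param cond a [condition()] describing variant and drive.
#' @param params a [jr_parameters()].
#' @return list: `table` (per-g r_plv and ksd), `g_hat` (argmin KSD),
#'   `g_hat_rplv` (argmax r_PLV), ties broken toward lower g.
#' @export
recover_coupling <- function(sc, target, g_grid = 0:8, reps = 3,
                             config = sim_config(duration = 20000,
                                                 transient = 2000),
                             seed = 1, cond = condition("parceled"),
                             params = jr_parameters()) {
  scv <- build_variant(sc, cond$driver_role, cond$sc_variant)
  cx <- which(scv$roles == "cortical")
  drive <- drive_config(scv, cond$cortical_p, cond$cortical_eta,
                        driver_role = cond$driver_role,
                        driver_p = cond$driver_p,
                        driver_eta = cond$driver_eta)
  rows <- lapply(seq_along(g_grid), function(gi) {
    fcs <- NULL; dfc_pool <- numeric(0)
    for (r in seq_len(reps)) {
      cfg <- config
      cfg$seed <- split_seed(seed, gi * 100 + r)
      sim <- simulate_network(scv, params, drive,
                              coupling_config(g = g_grid[gi]), cfg)
      fc <- tryCatch(fc_from_sim(sim)$values[cx, cx, drop = FALSE],
                     error = function(e) NULL)
      if (!is.null(fc)) fcs <- if (is.null(fcs)) fc else fcs + fc
      dfc <- tryCatch(.dfc_values(dfc_from_sim(sim, region_mask = cx)),
                      error = function(e) numeric(0))
      dfc_pool <- c(dfc_pool, dfc)
    }
    r_plv <- if (!is.null(fcs))
      tryCatch(fc_similarity(fcs / reps, target$fc), error = function(e) NA_real_)
    else NA_real_
    ksd <- if (length(dfc_pool))
      ks_distance(dfc_pool, target$dfc_correlations) else NA_real_
    data.frame(g = g_grid[gi], r_plv = r_plv, ksd = ksd)
  })
  tab <- do.call(rbind, rows)
  ok_k <- which(!is.na(tab$ksd))
  ok_r <- which(!is.na(tab$r_plv))
  list(table = tab,
       g_hat = tab$g[ok_k[which.min(tab$ksd[ok_k])]],
       g_hat_rplv = tab$g[ok_r[which.max(tab$r_plv[ok_r])]])
}

#' Label sweep records by dynamical regime
#'
#' `fixed_threshold` labels `g < threshold` as prebifurcation (the protocol
#' value for the empirical connectomes is 7). `auto` labels, per
#' subject-condition trace, everything before the first `g` at which the
#' repetition-averaged cortical post-transient peak-to-peak amplitude exceeds
#' `osc_tol` as prebifurcation.
#'
#' @param sweep_table a [g_sweep()] result (or repetition-averaged table).
#' @param method `"fixed_threshold"` or `"auto"`.
#' @param threshold coupling threshold for `fixed_threshold`.
#' @param osc_tol oscillation tolerance (mV peak-to-peak) for `auto`.
#' @return the table with a `regime` column (`"prebifurcation"` /
#'   `"postbifurcation"`).
#' @export
split_regimes <- function(sweep_table, method = c("fixed_threshold", "auto"),
                          threshold = 7, osc_tol = 1) {
  method <- match.arg(method)
  tb <- sweep_table
  if (method == "fixed_threshold") {
    tb$regime <- ifelse(tb$g < threshold, "prebifurcation", "postbifurcation")
    return(tb)
  }
  tb$regime <- "prebifurcation"
  key <- interaction(tb$subject, tb$condition, drop = TRUE)
  for (k in levels(key)) {
    sel <- which(key == k)
    sub <- tb[sel, ]
    p2p <- stats::ave(sub$max_cortical - sub$min_cortical, sub$g,
                      FUN = function(v) mean(v, na.rm = TRUE))
    gs <- sort(unique(sub$g))
    onset <- gs[match(TRUE, vapply(gs, function(gg)
      any(p2p[sub$g == gg] > osc_tol, na.rm = TRUE), logical(1)))]
    if (!is.na(onset))
      tb$regime[sel][sub$g >= onset] <- "postbifurcation"
  }
  tb
}

#' Working point per subject and condition
#'
#' Repetition-averages the table, restricts it to a regime, and returns the
#' best record per subject x condition: the maximum of `r_plv` or the minimum
#' of `ksd`. Ties are broken toward lower `g`.
#'
#' @param sweep_table a regime-labeled [g_sweep()] table (see
#'   [split_regimes()]).
#' @param metric `"r_plv"` (maximized) or `"ksd"` (minimized).
#' @param regime regime to search within.
#' @return data.frame with one row per subject x condition.
#' @export
working_point <- function(sweep_table, metric = c("r_plv", "ksd"),
                          regime = "prebifurcation") {
  metric <- match.arg(metric)
  if (!"regime" %in% names(sweep_table))
    stop("sweep_table must be regime-labeled; see split_regimes()")
  tb <- sweep_table[sweep_table$regime == regime, , drop = FALSE]
  if (nrow(tb) == 0) stop("no records in regime '", regime, "'")
  if ("rep" %in% names(tb)) {
    reg <- unique(tb[c("subject", "condition", "g", "regime")])
    tb <- merge(average_reps(tb), reg,
                by = c("subject", "condition", "g"))
  }
  pick <- function(sub) {
    v <- sub[[metric]]
    if (all(is.na(v))) return(sub[1, , drop = FALSE])
    best <- if (metric == "r_plv") max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
    cand <- sub[!is.na(v) & v == best, , drop = FALSE]
    cand[which.min(cand$g), , drop = FALSE]
  }
  out <- do.call(rbind, by(tb, interaction(tb$subject, tb$condition,
                                           drop = TRUE), pick))
  rownames(out) <- NULL
  out
}
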