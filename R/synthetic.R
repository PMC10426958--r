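#' Specification for a synthetic connectome
#'
#' The generator emulates the structural features the analysis relies on:
#' driver regions (e.g. thalamic nuclei) that connect to a widespread cortical
#' set — normalized degree near or above the global mean — while carrying
#' roughly half the global-mean normalized node strength, and Euclidean
#' distances in a brain-sized box yielding multi-millisecond conduction delays
#' at 15 mm/ms.
#'
#' @param n_cortical number of cortical regions (>= 2).
#' @param n_driver number of driver nuclei (parceled driver structure).
#' @param n_other number of additional regions with role `"other"`.
#' @param spatial_scale extent (mm) of the 3-D box positions are drawn in.
#' @param weight_decay_length exponential decay length (mm) of connection
#'   probability and weight with distance.
#' @param driver_degree_factor target driver degree as a multiple of the
#'   non-driver mean degree.
#' @param driver_strength_factor target driver node strength as a fraction of
#'   the global mean strength, in (0, 1].
#' @param driver_role role tag given to driver regions.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `connectome_gen_spec`.
#' @export
connectome_gen_spec <- function(n_cortical = 20, n_driver = 6, n_other = 0,
                                spatial_scale = 150, weight_decay_length = 75,
                                driver_degree_factor = 1.05,
                                driver_strength_factor = 0.48,
                                driver_role = "thalamic", seed = 1) {
  if (n_cortical < 2) stop("need at least 2 cortical regions")
  if (n_driver < 0 || n_other < 0) stop("counts must be nonnegative")
  if (driver_degree_factor < 1) stop("driver_degree_factor must be >= 1")
  if (driver_strength_factor <= 0 || driver_strength_factor > 1)
    stop("driver_strength_factor must be in (0, 1]")
  structure(list(n_cortical = n_cortical, n_driver = n_driver,
                 n_other = n_other, spatial_scale = spatial_scale,
                 weight_decay_length = weight_decay_length,
                 driver_degree_factor = driver_degree_factor,
                 driver_strength_factor = driver_strength_factor,
                 driver_role = driver_role, seed = as.integer(seed)),
            class = "connectome_gen_spec")
}

#' Generate a synthetic structural connectome
#'
#' Non-driver regions are wired with distance-dependent connection probability
#' and log-normal weights damped by exponential distance decay
#' (`w = LogNormal * exp(-d / decay)`). Driver nuclei are then connected to a
#' uniformly sampled (widespread) set of non-driver regions sized to
#' `driver_degree_factor` times the mean non-driver degree, and their edge
#' weights are rescaled in one shot so the driver-group mean strength is
#' `driver_strength_factor` times the global mean strength. Lengths are
#' Euclidean distances between sampled positions. Region order is cortical
#' first, then driver, then other.
#'
#' @param spec a [connectome_gen_spec()].
#' @return a validated `structural_connectome`.
#' @export
generate_connectome <- function(spec = connectome_gen_spec()) {
  with_seed(spec$seed, {
    n_nd <- spec$n_cortical + spec$n_other
    n <- n_nd + spec$n_driver
    roles <- c(rep("cortical", spec$n_cortical),
               rep(spec$driver_role, spec$n_driver),
               rep("other", spec$n_other))
    # order: cortical, driver, other
    ord <- order(match(roles, c("cortical", spec$driver_role, "other")))
    roles <- roles[ord]
    labels <- paste0(roles, "_", stats::ave(seq_len(n), roles, FUN = seq_along))
    pos <- matrix(stats::runif(3 * n, 0, spec$spatial_scale), n, 3)
    # drivers sit near the centre of the box, like deep-brain structures
    drv <- which(roles == spec$driver_role)
    pos[drv, ] <- matrix(stats::runif(3 * length(drv),
                                      0.35 * spec$spatial_scale,
                                      0.65 * spec$spatial_scale),
                         length(drv), 3)
    d <- as.matrix(stats::dist(pos))
    w <- matrix(0, n, n)
    nd <- which(roles != spec$driver_role)
    # non-driver wiring: dense, distance-decaying probability and weight
    for (i in nd) for (j in nd) if (j > i) {
      p_conn <- 0.55 + 0.45 * exp(-d[i, j] / spec$weight_decay_length)
      if (stats::runif(1) < p_conn)
        w[i, j] <- w[j, i] <- stats::rlnorm(1, 0, 0.5) *
          exp(-d[i, j] / spec$weight_decay_length)
    }
    if (length(drv)) {
      deg_nd <- mean(rowSums(w[nd, nd, drop = FALSE] > 0))
      k_target <- round(min(deg_nd * spec$driver_degree_factor, length(nd)))
      if (deg_nd * spec$driver_degree_factor > n - 1)
        stop("infeasible driver_degree_factor: requested degree exceeds n - 1")
      for (i in drv) {
        targets <- sample(nd, k_target)
        for (j in targets)
          w[i, j] <- w[j, i] <- stats::rlnorm(1, 0, 0.5) *
            exp(-d[i, j] / spec$weight_decay_length)
      }
      # one-shot strength calibration of the driver rows/columns
      s_all <- rowSums(w)
      target <- spec$driver_strength_factor * mean(s_all)
      scale <- target / mean(s_all[drv])
      w[drv, ] <- w[drv, ] * scale
      w[, drv] <- t(w[drv, , drop = FALSE])
    }
    lengths <- d
    lengths[w == 0] <- 0
    structural_connectome(w, lengths, labels, roles,
                          subject_id = sprintf("synthetic_%d", spec$seed))
  })
}

#' Generate a cohort of synthetic connectomes
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' any subject can be regenerated in isolation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param spec a [connectome_gen_spec()] template; its seed is ignored.
#' @param seed master seed.
#' @return list of `structural_connectome` objects.
#' @export
generate_cohort <- function(n_subjects = 10, spec = connectome_gen_spec(),
                            seed = 1) {
  if (n_subjects < 1) stop("need at least one subject")
  lapply(seq_len(n_subjects), function(k) {
    sp <- spec
    sp$seed <- split_seed(seed, k)
    sc <- generate_connectome(sp)
    sc$subject_id <- sprintf("synthetic_subj%02d", k)
    sc
  })
}

#' Generate a pseudo-empirical FC/dFC target
#'
#' Stands in for empirical (e.g. MEG) functional connectivity: runs the
#' network simulator at hidden "truth" parameters, computes the alpha-band
#' PLV matrix and dFC correlation sample over cortical regions, adds
#' independent Gaussian measurement noise to the FC off-diagonals, clips to
#' \[0, 1\] and symmetrizes. The generating parameters are stored alongside
#' for parameter-recovery experiments.
#'
#' @param sc a `structural_connectome`.
#' @param g_true hidden coupling value the target is generated at.
#' @param drive a [drive_config()] for the generating run (default: high
#'   driver noise on thalamic regions).
#' @param noise_sd measurement-noise std added to FC off-diagonal entries.
#' @param seed RNG seed for the generating simulation and the noise.
#' @param sim a [sim_config()] for the generating run.
#' @param params a [jr_parameters()].
#' @param driver_role role tag of the driver group.
#' @return object of class `pseudo_empirical_target`: `fc` (cortical PLV
#'   matrix), `dfc_correlations` (numeric sample), `region_labels`, `truth`
#'   (list: g, drive, seed, sim), `noise_sd`.
#' @export
generate_pseudo_empirical <- function(sc, g_true = 4,
                                      drive = drive_config(
                                        sc, driver_role = driver_role,
                                        driver_eta = 0.022),
                                      noise_sd = 0.02, seed = 1,
                                      sim = sim_config(duration = 20000,
                                                       transient = 2000,
                                                       seed = seed),
                                      params = jr_parameters(),
                                      driver_role = "thalamic") {
  run <- simulate_network(sc, params, drive,
                          coupling_config(g = g_true), sim)
  mask <- which(sc$roles == "cortical")
  fc_full <- fc_from_sim(run)
  fc <- fc_full$values[mask, mask, drop = FALSE]
  dfc <- dfc_from_sim(run, region_mask = mask)
  if (noise_sd > 0) {
    noise <- with_seed(split_seed(seed, 999), {
      m <- matrix(stats::rnorm(length(fc), 0, noise_sd), nrow(fc))
      (m + t(m)) / 2
    })
    diag(noise) <- 0
    fc <- pmin(pmax(fc + noise, 0), 1)
    fc <- (fc + t(fc)) / 2
    diag(fc) <- 1
  }
  structure(list(fc = fc,
                 dfc_correlations = .dfc_values(dfc),
                 region_labels = sc$labels[mask],
                 truth = list(g = g_true, drive = drive, seed = seed,
                              sim = sim),
                 noise_sd = noise_sd),
            class = "pseudo_empirical_target")
}

#' Persist a pseudo-empirical target as text
#'
#' Writes the FC matrix and dFC correlation sample as delimited text plus a
#' JSON metadata file recording the hidden truth parameters and seed.
#'
#' @param target a `pseudo_empirical_target`.
#' @param out_dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
write_pseudo_empirical <- function(target, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fc = file.path(out_dir, "fc.txt"),
             dfc = file.path(out_dir, "dfc_correlations.txt"),
             meta = file.path(out_dir, "meta.json"))
  write.table(format(target$fc, digits = 17, trim = TRUE),
              paths["fc"], sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  writeLines(format(target$dfc_correlations, digits = 17, trim = TRUE),
             paths["dfc"])
  meta <- list(region_labels = target$region_labels,
               noise_sd = target$noise_sd,
               truth = list(g = target$truth$g, seed = target$truth$seed,
                            p = target$truth$drive$p,
                            eta = target$truth$drive$eta))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a persisted pseudo-empirical target
#'
#' @param dir directory written by [write_pseudo_empirical()].
#' @return a `pseudo_empirical_target` (truth restored from metadata).
#' @export
read_pseudo_empirical <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(fc = .read_matrix(file.path(dir, "fc.txt")),
                 dfc_correlations = as.numeric(
                   readLines(file.path(dir, "dfc_correlations.txt"))),
                 region_labels = meta$region_labels,
                 truth = meta$truth,
                 noise_sd = meta$noise_sd),
            class = "pseudo_empirical_target")
}
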