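#' Dwell-interval inventory of a two-state (bound/unbound) trace
#'
#' Container for the alternating bound/unbound dwell durations extracted
#' from a trajectory ([detect_events()]) or generated directly
#' ([gen_telegraph()]). Censored first/last intervals, whose full extent is
#' unobserved, are stored separately and excluded from rate estimation by
#' default.
#'
#' @param bound_dwells,unbound_dwells Complete dwell durations (> 0).
#' @param censored_bound,censored_unbound Censored (partial) dwell
#'   durations.
#' @param total_time Total observation time; must be at least the sum of
#'   all dwells.
#' @return An object of class `event_trace`.
#' @export
event_trace <- function(bound_dwells, unbound_dwells,
                        censored_bound = numeric(0),
                        censored_unbound = numeric(0),
                        total_time) {
  bound_dwells <- as.numeric(bound_dwells)
  unbound_dwells <- as.numeric(unbound_dwells)
  censored_bound <- as.numeric(censored_bound)
  censored_unbound <- as.numeric(censored_unbound)
  if (any(c(bound_dwells, unbound_dwells) <= 0))
    stop("dwell durations must be positive")
  tol <- 1e-8 * max(total_time, 1)
  if (sum(bound_dwells, unbound_dwells, censored_bound, censored_unbound) >
      total_time + tol)
    stop("dwells exceed `total_time`")
  structure(list(bound_dwells = bound_dwells,
                 unbound_dwells = unbound_dwells,
                 censored_bound = censored_bound,
                 censored_unbound = censored_unbound,
                 total_time = total_time),
            class = "event_trace")
}

#' @export
print.event_trace <- function(x, ...) {
  cat(sprintf("Event trace: %d bound / %d unbound complete dwells (+%d censored) over %g time units\n",
              length(x$bound_dwells), length(x$unbound_dwells),
              length(x$censored_bound) + length(x$censored_unbound),
              x$total_time))
  invisible(x)
}

# percentile bootstrap CI for 1/mean of a dwell sample
boot_rate_ci <- function(dwells, n_boot, conf) {
  n <- length(dwells)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  rates <- 1 / colMeans(matrix(dwells[idx], nrow = n))
  unname(quantile(rates, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Estimate on- and off-rates from dwell times
#'
#' Mean-first-passage estimator: `k_on = 1/mean(unbound dwells)`,
#' `k_off = 1/mean(bound dwells)`, with seeded percentile-bootstrap
#' confidence intervals. Censored end intervals are excluded (the default
#' MFPT route) unless `method = "exponential"`, which uses the
#' censoring-aware exponential maximum-likelihood estimator
#' `k = n_complete / (sum of complete + censored durations)`; the two
#' coincide when no interval is censored.
#'
#' @param trace An [event_trace()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param method `"mfpt"` (default) or `"exponential"`.
#' @return An object of class `kinetics_estimate`: `k_on`, `k_off`,
#'   `ci_on`, `ci_off`, `n_on`, `n_off`, `method`.
#' @export
#' @examples
#' tr <- event_trace(bound_dwells = c(1, 1), unbound_dwells = c(2, 2),
#'                   total_time = 6)
#' estimate_rates(tr, n_boot = 50)
estimate_rates <- function(trace, n_boot = 1000, seed = 1, conf = 0.95,
                           method = c("mfpt", "exponential")) {
  stopifnot(inherits(trace, "event_trace"))
  method <- match.arg(method)
  missing_side <- c("bound (off-rate)", "unbound (on-rate)")[
    c(length(trace$bound_dwells) == 0L, length(trace$unbound_dwells) == 0L)]
  if (length(missing_side))
    stop("no complete ", paste(missing_side, collapse = " or "),
         " dwell intervals: cannot estimate rates")
  if (method == "mfpt") {
    k_off <- 1 / mean(trace$bound_dwells)
    k_on <- 1 / mean(trace$unbound_dwells)
  } else {
    k_off <- length(trace$bound_dwells) /
      (sum(trace$bound_dwells) + sum(trace$censored_bound))
    k_on <- length(trace$unbound_dwells) /
      (sum(trace$unbound_dwells) + sum(trace$censored_unbound))
  }
  set.seed(seed)
  ci_off <- boot_rate_ci(trace$bound_dwells, n_boot, conf)
  ci_on <- boot_rate_ci(trace$unbound_dwells, n_boot, conf)
  structure(list(k_on = k_on, k_off = k_off, ci_on = ci_on, ci_off = ci_off,
                 n_on = length(trace$unbound_dwells),
                 n_off = length(trace$bound_dwells),
                 conf = conf, method = method),
            class = "kinetics_estimate")
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  cat(sprintf("k_on  = %.4g [%.4g, %.4g]  (n = %d unbound dwells)\n",
              x$k_on, x$ci_on[1], x$ci_on[2], x$n_on))
  cat(sprintf("k_off = %.4g [%.4g, %.4g]  (n = %d bound dwells)\n",
              x$k_off, x$ci_off[1], x$ci_off[2], x$n_off))
  invisible(x)
}

#' Scale rate estimates against a reference linker
#'
#' Divides each linker's on- and off-rate by the reference linker's rates,
#' so the reference maps to (1, 1). This is how simulated kinetics across
#' polymer lengths are compared: only rate ratios, not absolute rates, are
#' meaningful at coarse-grained resolution.
#'
#' @param estimates Named list of [estimate_rates()] results, or a
#'   data.frame with columns `linker`, `k_on`, `k_off`.
#' @param reference Name of the reference linker (default: the first).
#' @return A data.frame with columns `linker`, `k_on`, `k_off`,
#'   `scaled_kon`, `scaled_koff`.
#' @export
scale_rates <- function(estimates, reference = NULL) {
  if (is.data.frame(estimates)) {
    df <- estimates[, c("linker", "k_on", "k_off")]
  } else {
    if (is.null(names(estimates)) || any(names(estimates) == ""))
      stop("`estimates` must be named by linker")
    df <- data.frame(
      linker = names(estimates),
      k_on = vapply(estimates, function(e) e$k_on %||% NA_real_, numeric(1)),
      k_off = vapply(estimates, function(e) e$k_off %||% NA_real_, numeric(1)))
  }
  if (is.null(reference)) reference <- df$linker[1]
  i <- match(reference, df$linker)
  if (is.na(i)) stop("reference linker '", reference, "' not found")
  if (!isTRUE(df$k_on[i] > 0) || !isTRUE(df$k_off[i] > 0))
    stop("reference linker '", reference, "' has no positive rate estimates")
  df$scaled_kon <- df$k_on / df$k_on[i]
  df$scaled_koff <- df$k_off / df$k_off[i]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Potential of mean force along the terminal-bead height
#'
#' Histogram estimate of the free-energy profile `W(z) = -kT ln p(z)` (in
#' kT units, minimum shifted to 0; empty bins are `NA`). The most probable
#' bound height is the modal bin below `bind_cutoff`, and the force is the
#' central-difference slope of the profile there, converted to pN via
#' `temperature_kT`. When `subtract_potential` is supplied (typically
#' [binding_potential()]), its energy is removed from the profile before
#' differentiating, so the reported force is the tether-chain (entropic)
#' tension at the bound position rather than the near-zero slope of the
#' total profile at its own minimum.
#'
#' @param heights Numeric vector of terminal-bead heights (pooled replicas,
#'   post-equilibration), or a `bd_result`.
#' @param bin_width Histogram bin width in nm (default 0.1).
#' @param bind_cutoff Bound-region threshold in nm (default 1).
#' @param subtract_potential Optional function `f(z)` returning an energy in
#'   kT to subtract from the profile before computing the force.
#' @param temperature_kT Thermal energy in pN nm for force conversion
#'   (default 4.11).
#' @return An object of class `pmf_profile`: `bin_centers`, `free_energy`
#'   (kT), `most_probable_bound_height` (nm), `force_at_minimum` (pN,
#'   magnitude; `NA` with attribute `bound_region_empty` if no samples fall
#'   below `bind_cutoff`).
#' @export
pmf_from_heights <- function(heights, bin_width = 0.1, bind_cutoff = 1,
                             subtract_potential = NULL,
                             temperature_kT = 4.11) {
  if (inherits(heights, "bd_result")) heights <- heights$heights$height
  heights <- heights[is.finite(heights)]
  if (length(heights) < 1e4)
    warning("fewer than 1e4 samples: PMF will be noisy")
  lo <- floor(min(heights) / bin_width) * bin_width
  hi <- ceiling(max(heights) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  hh <- hist(heights, breaks = breaks, plot = FALSE)
  dens <- hh$density
  w <- ifelse(dens > 0, -log(dens), NA_real_)
  w <- w - min(w, na.rm = TRUE)
  centers <- hh$mids
  w_eff <- w
  if (!is.null(subtract_potential)) w_eff <- w - subtract_potential(centers)
  in_bound <- centers < bind_cutoff & !is.na(w)
  if (!any(in_bound)) {
    mode_z <- NA_real_
    force <- NA_real_
    empty <- TRUE
  } else {
    empty <- FALSE
    ib <- which(in_bound)
    i_mode <- ib[which.min(w[ib])]
    mode_z <- centers[i_mode]
    i_lo <- i_mode - 1L
    i_hi <- i_mode + 1L
    slope <- if (i_lo >= 1L && i_hi <= length(w_eff) &&
                 is.finite(w_eff[i_lo]) && is.finite(w_eff[i_hi])) {
      (w_eff[i_hi] - w_eff[i_lo]) / (2 * bin_width)
    } else if (i_hi <= length(w_eff) && is.finite(w_eff[i_hi]) &&
               is.finite(w_eff[i_mode])) {
      (w_eff[i_hi] - w_eff[i_mode]) / bin_width
    } else if (i_lo >= 1L && is.finite(w_eff[i_lo]) &&
               is.finite(w_eff[i_mode])) {
      (w_eff[i_mode] - w_eff[i_lo]) / bin_width
    } else NA_real_
    force <- abs(slope) * temperature_kT
  }
  structure(list(bin_centers = centers, free_energy = w,
                 most_probable_bound_height = mode_z,
                 force_at_minimum = force,
                 bin_width = bin_width, bind_cutoff = bind_cutoff,
                 n_samples = length(heights)),
            class = "pmf_profile", bound_region_empty = empty)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF over [%.2f, %.2f] nm (%d bins of %.2f nm, %d samples)\n",
              min(x$bin_centers), max(x$bin_centers), length(x$bin_centers),
              x$bin_width, x$n_samples))
  if (attr(x, "bound_region_empty")) {
    cat("  no samples in the bound region: force undefined\n")
  } else {
    cat(sprintf("  most probable bound height %.2f nm, force %.2f pN\n",
                x$most_probable_bound_height, x$force_at_minimum))
  }
  invisible(x)
}

#' Simulate binding kinetics across a sweep of chain lengths
#'
#' Runs the tethered-chain simulator for several chain lengths under a
#' common geometry, pools binding events over replicas, estimates on/off
#' rates, extracts the tether tension at the most probable bound height
#' from the PMF (binding well subtracted), and scales rates against the
#' shortest chain. Lengths are reported against the PEO unit count
#' (`units_per_bead` per bead) with the corresponding Flory radius.
#'
#' @param bead_counts Integer vector of chain lengths in beads, including
#'   the fixed tether bead (default `c(15, 30, 60)`).
#' @param units_per_bead PEO units per bead (default 3).
#' @param time_per_replica Production time per replica in tau (default 600).
#' @param n_replicas Replicas per length (default 20).
#' @param equilibration_factor Burn-in, in multiples of the Rouse estimate
#'   (default 2).
#' @param tether_height,binding_depth,binding_range,seed,timestep,thin
#'   Passed to [sim_config()].
#' @param bind_cutoff,unbind_cutoff Passed to [detect_events_all()].
#' @param method Rate estimator (see [estimate_rates()]); default
#'   `"exponential"`, the censoring-aware choice: at desk-scale replica
#'   lengths a large share of dwells is cut off at replica boundaries, and
#'   discarding those censored intervals would bias both rates upward.
#' @param reference Reference bead count for scaling (default: smallest).
#' @param verbose Print per-length progress.
#' @return A data.frame with one row per length: `n_beads`, `n_units`,
#'   `flory_radius`, `k_on`, `k_off`, `scaled_kon`, `scaled_koff`, `n_on`,
#'   `n_off`, `force_pn`, `mode_height`. Lengths with no complete dwell on
#'   one side get `NA` rates.
#' @export
sweep_chain_lengths <- function(bead_counts = c(15, 30, 60),
                                units_per_bead = 3,
                                time_per_replica = 600,
                                n_replicas = 20,
                                equilibration_factor = 2,
                                tether_height = 9,
                                binding_depth = 7,
                                binding_range = 1,
                                bind_cutoff = 1,
                                unbind_cutoff = 1.5,
                                timestep = 1e-3,
                                thin = 50,
                                seed = 1,
                                method = "exponential",
                                reference = NULL,
                                verbose = FALSE) {
  bead_counts <- sort(as.integer(bead_counts))
  b <- units_per_bead * 0.28
  rows <- vector("list", length(bead_counts))
  for (i in seq_along(bead_counts)) {
    n <- bead_counts[i]
    tau_r <- rouse_time_estimate(n, b)
    cfg <- sim_config(
      n_beads = n, segment_length = b, tether_height = tether_height,
      binding_depth = binding_depth, binding_range = binding_range,
      timestep = timestep, thin = thin,
      n_steps = ceiling(time_per_replica / timestep),
      n_replicas = n_replicas,
      equilibration_steps = ceiling(equilibration_factor * tau_r / timestep),
      seed = seed + i)
    res <- run_brownian(build_chain(NULL, cfg))
    trace <- detect_events_all(res, bind_cutoff, unbind_cutoff)
    est <- tryCatch(estimate_rates(trace, seed = seed, method = method),
                    error = function(e) NULL)
    pmf <- pmf_from_heights(
      res$heights$height, bind_cutoff = bind_cutoff,
      subtract_potential = function(z)
        binding_potential(z, binding_depth, binding_range))
    n_units <- (n - 1L) * units_per_bead
    rows[[i]] <- data.frame(
      n_beads = n, n_units = n_units,
      flory_radius = flory_radius(polymer_spec(n_units * 44)),
      k_on = if (is.null(est)) NA_real_ else est$k_on,
      k_off = if (is.null(est)) NA_real_ else est$k_off,
      n_on = length(trace$unbound_dwells),
      n_off = length(trace$bound_dwells),
      force_pn = pmf$force_at_minimum,
      mode_height = pmf$most_probable_bound_height)
    if (verbose)
      message(sprintf("%d beads: %d/%d dwells, k_on=%.3g k_off=%.3g force=%.3g pN",
                      n, rows[[i]]$n_on, rows[[i]]$n_off, rows[[i]]$k_on,
                      rows[[i]]$k_off, rows[[i]]$force_pn))
  }
  df <- do.call(rbind, rows)
  if (is.null(reference)) reference <- df$n_beads[1]
  iref <- match(reference, df$n_beads)
  df$scaled_kon <- df$k_on / df$k_on[iref]
  df$scaled_koff <- df$k_off / df$k_off[iref]
  df
}

#' Equilibrium end-to-end scaling of the free chain
#'
#' Runs the simulator with tether, wall and binding switched off for a set
#' of chain lengths and returns the RMS end-to-end distance of each,
#' together with the fitted power-law exponent of R(N) versus bond count (a
#' self-avoiding chain should show the Flory exponent, about 3/5).
#'
#' @param bead_counts Chain lengths in beads (default `c(10, 20, 40)`).
#' @param segment_length Bond length in nm (default 0.84).
#' @param time_per_replica Production time per replica in tau; by default
#'   each length runs 30 of its own Rouse times.
#' @param n_replicas Replicas per length (default 4).
#' @param timestep Integrator step (default 5e-4; no binding resolution
#'   constraint applies to free chains).
#' @param seed Master seed.
#' @return A list: `table` (data.frame `n_beads`, `rms_ree`), `exponent`
#'   (slope of log RMS vs log bond count), `fit` (the lm object).
#' @export
end_to_end_scaling <- function(bead_counts = c(10, 20, 40),
                               segment_length = 0.84,
                               time_per_replica = NULL,
                               n_replicas = 4,
                               timestep = 5e-4,
                               seed = 1) {
  bead_counts <- sort(as.integer(bead_counts))
  rows <- vector("list", length(bead_counts))
  for (i in seq_along(bead_counts)) {
    n <- bead_counts[i]
    tau_r <- rouse_time_estimate(n, segment_length)
    t_prod <- if (is.null(time_per_replica)) 30 * tau_r else time_per_replica
    cfg <- sim_config(
      n_beads = n, segment_length = segment_length,
      binding_depth = 0, tether = FALSE, wall = FALSE,
      timestep = timestep, thin = max(1L, ceiling(tau_r / 10 / timestep)),
      n_steps = ceiling(t_prod / timestep),
      equilibration_steps = ceiling(5 * tau_r / timestep),
      n_replicas = n_replicas, seed = seed + i)
    res <- run_brownian(build_chain(NULL, cfg))
    rows[[i]] <- data.frame(n_beads = n,
                            rms_ree = sqrt(mean(res$heights$ree^2)))
  }
  df <- do.call(rbind, rows)
  fit <- lm(log(rms_ree) ~ log(n_beads - 1), data = df)
  list(table = df, exponent = unname(coef(fit)[2]), fit = fit)
}
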