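#' Configuration of the tethered-chain Brownian dynamics simulator
#'
#' Collects geometry, potentials and integrator settings for a bead-spring
#' chain whose first bead is fixed at `tether_height` above an implicit
#' planar surface at z = 0. Energies are in units of kT (the integrator runs
#' at fixed reduced temperature kT = 1); lengths in nm; time in reduced units
#' tau with bead diffusion coefficient `bead_diffusion` nm^2/tau.
#' `temperature_kT` (pN nm) is used only to convert energies per nm into
#' piconewtons when reporting forces.
#'
#' The construction check enforces the event-detection resolution contract:
#' the per-coordinate RMS Brownian step `sqrt(2 D dt)` must stay below one
#' tenth of `binding_range`.
#'
#' @param n_beads Number of beads including the fixed tether bead (>= 2).
#' @param segment_length Bond rest length b in nm.
#' @param tether_height Height of the fixed bead above the plane in nm
#'   (default 9).
#' @param bond_stiffness Harmonic bond stiffness in kT/nm^2 (default 100).
#' @param excluded_volume_sigma WCA diameter for the purely repulsive pair
#'   interaction, nm (default `0.8 * segment_length`).
#' @param excluded_volume_eps WCA energy scale in kT (default 1).
#' @param wall_stiffness One-sided harmonic wall stiffness at z = 0, kT/nm^2
#'   (default 100).
#' @param binding_depth Depth of the short-range attractive well acting on
#'   the terminal bead near the plane, in kT (default 7).
#' @param binding_range Range of the attractive well in nm (default 1,
#'   matching the binding event cutoff).
#' @param temperature_kT Thermal energy in pN nm used for force reporting
#'   (default 4.11, i.e. 300 K).
#' @param bead_diffusion Bead diffusion coefficient, nm^2/tau (default 1).
#' @param timestep Integrator timestep in tau (default 1e-3).
#' @param n_steps Production steps per replica.
#' @param n_replicas Number of independently seeded replicas (default 20).
#' @param seed Master seed; per-replica streams are spawned from it.
#' @param thin Record every `thin`-th step (default 50).
#' @param equilibration_steps Burn-in steps discarded before recording;
#'   `NULL` (default) uses 10 Rouse times.
#' @param tether Fix bead 1 at `(0, 0, tether_height)` (default TRUE).
#' @param wall Apply the repulsive wall at z = 0 (default TRUE). Disable
#'   together with `tether` for free-chain reference runs.
#' @return An object of class `sim_config`.
#' @seealso [build_chain()], [run_brownian()], [detect_events()]
#' @export
sim_config <- function(n_beads,
                       segment_length = 0.84,
                       tether_height = 9,
                       bond_stiffness = 100,
                       excluded_volume_sigma = 0.8 * segment_length,
                       excluded_volume_eps = 1,
                       wall_stiffness = 100,
                       binding_depth = 7,
                       binding_range = 1,
                       temperature_kT = 4.11,
                       bead_diffusion = 1,
                       timestep = 1e-3,
                       n_steps = 6e5,
                       n_replicas = 20,
                       seed = 1,
                       thin = 50,
                       equilibration_steps = NULL,
                       tether = TRUE,
                       wall = TRUE) {
  if (n_beads < 2) stop("`n_beads` must be at least 2")
  if (tether_height <= 0) stop("`tether_height` must be positive (nm)")
  if (binding_range <= 0) stop("`binding_range` must be positive (nm)")
  if (binding_depth < 0) stop("`binding_depth` must be non-negative (kT)")
  if (timestep <= 0 || n_steps < 1) stop("invalid integrator settings")
  rms_step <- sqrt(2 * bead_diffusion * timestep)
  if (rms_step >= 0.1 * binding_range)
    stop(sprintf(paste0("timestep too large: per-step RMS displacement %.3g nm ",
                        "must be < 0.1 x binding_range = %.3g nm"),
                 rms_step, 0.1 * binding_range))
  if (bond_stiffness * bead_diffusion * timestep > 0.25)
    warning("`bond_stiffness * timestep` is large; bond integration may be inaccurate")
  if (is.null(equilibration_steps)) {
    tau_r <- rouse_time_estimate(n_beads, segment_length, bead_diffusion)
    equilibration_steps <- ceiling(10 * tau_r / timestep)
  }
  structure(
    list(n_beads = as.integer(n_beads), segment_length = segment_length,
         tether_height = tether_height, bond_stiffness = bond_stiffness,
         excluded_volume_sigma = excluded_volume_sigma,
         excluded_volume_eps = excluded_volume_eps,
         wall_stiffness = wall_stiffness, binding_depth = binding_depth,
         binding_range = binding_range, temperature_kT = temperature_kT,
         bead_diffusion = bead_diffusion, timestep = timestep,
         n_steps = as.integer(n_steps), n_replicas = as.integer(n_replicas),
         seed = as.integer(seed), thin = as.integer(thin),
         equilibration_steps = as.integer(equilibration_steps),
         tether = tether, wall = wall),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Tethered-chain BD config: %d beads (b = %.2f nm), h = %g nm\n",
              x$n_beads, x$segment_length, x$tether_height))
  cat(sprintf("  binding well: depth %g kT, range %g nm; wall %s, tether %s\n",
              x$binding_depth, x$binding_range,
              if (x$wall) "on" else "off", if (x$tether) "on" else "off"))
  cat(sprintf("  dt = %g tau, %d steps x %d replicas (+%d burn-in), seed %d\n",
              x$timestep, x$n_steps, x$n_replicas, x$equilibration_steps,
              x$seed))
  invisible(x)
}

#' Map a PEG linker onto a bead-spring chain
#'
#' Coarse-grains a polymer at `units_per_bead` PEO units per bead: the chain
#' has `round(n_units / units_per_bead) + 1` beads (the first is the fixed
#' tether bead) and segment length `units_per_bead * unit_length`. With
#' `spec = NULL` the chain geometry is taken from `config` unchanged. The
#' initial conformation is a self-avoiding random walk grown from the tether
#' point, rejected on overlap and on wall penetration.
#'
#' @param spec A [polymer_spec()] (or MW in Da), or `NULL`.
#' @param config A [sim_config()]; with `spec` given, `n_beads` and
#'   `segment_length` are derived from the mapping and override the config.
#' @param units_per_bead PEO units per bead (default 3).
#' @return An object of class `chain_system`: initial coordinates, config,
#'   and the mapping used.
#' @export
#' @examples
#' sys <- build_chain(4000, sim_config(n_beads = 2, n_steps = 1000))
#' sys$config$n_beads  # 31 beads for PEG 4000 at 3 units/bead
build_chain <- function(spec = NULL, config, units_per_bead = 3) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(spec)) {
    spec <- as_polymer_spec(spec)
    n_beads <- as.integer(round_half_up(spec$n_units_exact / units_per_bead)) + 1L
    if (n_beads < 2L) n_beads <- 2L
    b <- units_per_bead * spec$unit_length
    config$n_beads <- n_beads
    config$segment_length <- b
    config$excluded_volume_sigma <- 0.8 * b
    tau_r <- rouse_time_estimate(n_beads, b, config$bead_diffusion)
    config$equilibration_steps <- as.integer(ceiling(10 * tau_r / config$timestep))
  }
  mobile_contour <- (config$n_beads - 1L) * config$segment_length
  if (config$tether &&
      mobile_contour < config$tether_height - config$binding_range)
    warning(sprintf(paste0("mobile contour (%.2f nm) is below tether_height - ",
                           "binding_range (%.2f nm): binding is impossible"),
                    mobile_contour, config$tether_height - config$binding_range))
  set.seed(config$seed)
  coords <- init_chain_coords(config)
  structure(list(coords = coords, config = config, spec = spec,
                 units_per_bead = if (is.null(spec)) NA_real_ else units_per_bead),
            class = "chain_system")
}

# Self-avoiding random-walk initial conformation grown from the tether point.
init_chain_coords <- function(config) {
  n <- config$n_beads
  b <- config$segment_length
  sig <- config$excluded_volume_sigma
  z0 <- if (config$tether) config$tether_height else 5 * b
  for (attempt in 1:200) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- c(0, 0, z0)
    ok <- TRUE
    for (i in seq_len(n - 1L) + 1L) {
      placed <- FALSE
      for (try in 1:100) {
        d <- rnorm(3)
        cand <- xyz[i - 1L, ] + d / sqrt(sum(d^2)) * b
        if (config$wall && cand[3] < 0.5 * sig) next
        if (i > 2L) {
          prev <- xyz[seq_len(i - 2L), , drop = FALSE]
          d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          if (min(d2) < sig^2) next
        }
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
      xyz[i, ] <- cand
    }
    if (ok) return(xyz)
  }
  stop("failed to grow a non-overlapping initial conformation")
}

# Independent per-replica RNG streams from the master seed (kept < 2^31).
make_replica_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run overdamped Brownian dynamics of the tethered chain
#'
#' Integrates overdamped Langevin dynamics (Euler-Maruyama, kT = 1, bead
#' diffusion `D`): harmonic bonds, purely repulsive WCA excluded volume
#' between non-bonded beads, a one-sided harmonic wall at z = 0, and a
#' short-range attractive well of depth `binding_depth` acting on the
#' terminal bead within `binding_range` of the plane. Replicas run
#' independently, each with its own seed and freshly grown initial
#' conformation; the burn-in period is discarded before recording. Runs are
#' bit-reproducible for a fixed config.
#'
#' @param system A [build_chain()] result, or a [sim_config()] (a chain is
#'   then grown from it).
#' @return An object of class `bd_result`: `heights`, a data.frame with
#'   columns `time`, `height` (terminal bead height above the plane, nm),
#'   `ree` (end-to-end distance, nm) and `replica`; `seeds`, the per-replica
#'   seeds; `config`. Aborts with a diagnostic if any coordinate exceeds ten
#'   times the contour length (numerical blow-up).
#' @export
run_brownian <- function(system) {
  if (inherits(system, "sim_config")) system <- build_chain(NULL, system)
  stopifnot(inherits(system, "chain_system"))
  cfg <- system$config
  seeds <- make_replica_seeds(cfg$seed, cfg$n_replicas)
  blow_limit <- 10 * max((cfg$n_beads - 1) * cfg$segment_length,
                         cfg$tether_height)
  # cap drift displacement at 0.1 nm/step against rare steep WCA overlaps
  f_max <- 0.1 / (cfg$bead_diffusion * cfg$timestep)
  out <- vector("list", cfg$n_replicas)
  for (r in seq_len(cfg$n_replicas)) {
    set.seed(seeds[r])
    coords <- init_chain_coords(cfg)
    res <- bd_core(coords,
                   n_steps = cfg$n_steps,
                   burn_steps = cfg$equilibration_steps,
                   thin = cfg$thin,
                   dt = cfg$timestep * cfg$bead_diffusion,
                   b = cfg$segment_length,
                   k_bond = cfg$bond_stiffness,
                   sigma_ev = cfg$excluded_volume_sigma,
                   eps_ev = cfg$excluded_volume_eps,
                   k_wall = cfg$wall_stiffness,
                   wall = cfg$wall,
                   eps_bind = cfg$binding_depth,
                   r_bind = cfg$binding_range,
                   tethered = cfg$tether,
                   blow_limit = blow_limit,
                   f_max = f_max,
                   seed = seeds[r])
    if (res$blown)
      stop(sprintf(paste0("numerical blow-up in replica %d (coordinate beyond ",
                          "%.1f nm); reduce `timestep` or stiffnesses"),
                   r, blow_limit))
    out[[r]] <- data.frame(time = res$times, height = res$height,
                           ree = res$ree, replica = r)
  }
  structure(list(heights = do.call(rbind, out), seeds = seeds, config = cfg),
            class = "bd_result")
}

#' Piecewise binding-well potential of the simulator
#'
#' The attractive well felt by the terminal bead:
#' `U(z) = -depth * (1 - (z/range)^2)^2` for `0 <= z < range`, `-depth` for
#' `z < 0`, and 0 beyond the range. In kT units. Useful for reweighting
#' checks and for subtracting the well from a PMF (see
#' [pmf_from_heights()]).
#'
#' @param z Height(s) above the plane in nm.
#' @param depth Well depth in kT.
#' @param range Well range in nm.
#' @return Potential energy in kT, vectorised over `z`.
#' @export
binding_potential <- function(z, depth = 7, range = 1) {
  u <- numeric(length(z))
  inside <- z >= 0 & z < range
  u[inside] <- -depth * (1 - (z[inside] / range)^2)^2
  u[z < 0] <- -depth
  u
}

#' Detect binding events in a terminal-height series
#'
#' Two-threshold state machine over a regularly sampled height series:
#' unbound -> bound when the height drops below `bind_cutoff`; bound ->
#' unbound when it rises above `unbind_cutoff`. With
#' `unbind_cutoff = bind_cutoff` this reduces to the single-cutoff
#' definition (binding = terminal bead within `bind_cutoff` of the surface);
#' the default hysteresis (1.0/1.5 nm) suppresses recrossing chatter at the
#' threshold. The first and last dwell intervals are censored (their full
#' extent is unobserved) and kept separately.
#'
#' @param series A data.frame with columns `time` and `height` (one
#'   replica), or a numeric height vector with `dt` supplied.
#' @param bind_cutoff Binding threshold in nm (default 1).
#' @param unbind_cutoff Unbinding threshold in nm (default 1.5); must be
#'   `>= bind_cutoff`.
#' @param dt Sampling interval, required when `series` is a bare vector.
#' @return An [event_trace()] with complete bound/unbound dwell durations,
#'   censored end intervals, and the total observation time.
#' @export
#' @examples
#' detect_events(c(3, 0.8, 0.9, 2, 3), dt = 1)
detect_events <- function(series, bind_cutoff = 1, unbind_cutoff = 1.5,
                          dt = NULL) {
  if (is.data.frame(series)) {
    h <- series$height
    if (is.null(dt)) {
      if (nrow(series) < 2L) stop("height series too short")
      dt <- series$time[2] - series$time[1]
    }
  } else {
    h <- as.numeric(series)
    if (is.null(dt)) stop("`dt` must be given for a bare height vector")
  }
  if (length(h) == 0L) stop("empty height series")
  if (unbind_cutoff < bind_cutoff)
    stop("`unbind_cutoff` must be >= `bind_cutoff`")
  state <- h[1] < bind_cutoff          # TRUE = bound
  run_len <- 0L
  bound <- numeric(0); unbound <- numeric(0)
  cens_first <- NA_real_; first_state <- state
  first_done <- FALSE
  for (i in seq_along(h)) {
    new_state <- if (state) !(h[i] > unbind_cutoff) else h[i] < bind_cutoff
    if (new_state == state) {
      run_len <- run_len + 1L
    } else {
      if (!first_done) {
        cens_first <- run_len * dt
        first_done <- TRUE
      } else if (state) bound <- c(bound, run_len * dt)
      else unbound <- c(unbound, run_len * dt)
      state <- new_state
      run_len <- 1L
    }
  }
  cens_last <- run_len * dt
  if (!first_done) {
    # never switched: the whole series is one censored interval
    cens_b <- if (state) cens_last else numeric(0)
    cens_u <- if (state) numeric(0) else cens_last
  } else {
    cens_b <- c(if (first_state) cens_first, if (state) cens_last)
    cens_u <- c(if (!first_state) cens_first, if (!state) cens_last)
  }
  event_trace(
    bound_dwells = bound, unbound_dwells = unbound,
    censored_bound = cens_b, censored_unbound = cens_u,
    total_time = length(h) * dt)
}

#' Pool binding events across replicas
#'
#' Applies [detect_events()] to each replica of a [run_brownian()] result
#' and concatenates the dwell inventories into one [event_trace()] (censored
#' intervals at replica boundaries stay censored).
#'
#' @param result A `bd_result` from [run_brownian()].
#' @inheritParams detect_events
#' @return An [event_trace()].
#' @export
detect_events_all <- function(result, bind_cutoff = 1, unbind_cutoff = 1.5) {
  stopifnot(inherits(result, "bd_result"))
  traces <- lapply(split(result$heights, result$heights$replica),
                   detect_events, bind_cutoff = bind_cutoff,
                   unbind_cutoff = unbind_cutoff)
  event_trace(
    bound_dwells = unlist(lapply(traces, `[[`, "bound_dwells")),
    unbound_dwells = unlist(lapply(traces, `[[`, "unbound_dwells")),
    censored_bound = unlist(lapply(traces, `[[`, "censored_bound")),
    censored_unbound = unlist(lapply(traces, `[[`, "censored_unbound")),
    total_time = sum(vapply(traces, `[[`, numeric(1), "total_time")))
}
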