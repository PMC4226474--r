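#' Two-state telegraph trace with known rates
#'
#' Generates alternating exponential unbound/bound dwells (rates `k_on` out
#' of unbound, `k_off` out of bound) until `duration` is filled, starting
#' unbound. The final partial dwell is censored. Ground truth is retained.
#' Optionally emits a surrogate terminal-height series (bound level 0.5 nm,
#' unbound 3 nm, Gaussian jitter) far from the detection cutoffs, so both
#' single- and dual-cutoff [detect_events()] classify it identically.
#'
#' @param k_on,k_off Transition rates (per unit time), positive.
#' @param duration Total trace duration. A warning is issued below
#'   `10 / min(k_on, k_off)` (few events).
#' @param seed RNG seed.
#' @param bound_level,unbound_level Surrogate height levels in nm.
#' @param jitter_sd Surrogate height noise sd in nm (default 0.05).
#' @param dt Surrogate sampling interval; default a twentieth of the
#'   shorter mean dwell.
#' @param emit_heights Emit the surrogate series (default TRUE; disable for
#'   large event counts where only dwells are needed).
#' @return A list of class `telegraph_sim`: `trace` (an [event_trace()]),
#'   `events` (data.frame `state`, `start`, `end`, `censored`), `heights`
#'   (data.frame `time`, `height`, or NULL), and the generating parameters
#'   under `params`.
#' @export
#' @examples
#' sim <- gen_telegraph(k_on = 1, k_off = 5, duration = 50, seed = 7)
#' sim$trace
gen_telegraph <- function(k_on, k_off, duration, seed = 1,
                          bound_level = 0.5, unbound_level = 3,
                          jitter_sd = 0.05, dt = NULL,
                          emit_heights = TRUE) {
  if (k_on <= 0 || k_off <= 0) stop("rates must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  if (duration < 10 / min(k_on, k_off))
    warning("`duration` is short relative to the slower rate: few events expected")
  set.seed(seed)
  mean_cycle <- 1 / k_on + 1 / k_off
  dwells <- numeric(0)
  states <- logical(0)           # FALSE = unbound, TRUE = bound
  repeat {
    n_cyc <- max(16L, ceiling(1.3 * (duration - sum(dwells)) / mean_cycle))
    chunk <- as.vector(rbind(rexp(n_cyc, k_on), rexp(n_cyc, k_off)))
    dwells <- c(dwells, chunk)
    states <- c(states, rep(c(FALSE, TRUE), n_cyc))
    if (sum(dwells) >= duration) break
  }
  n_keep <- which(cumsum(dwells) >= duration)[1]  # dwell reaching `duration`
  dwells <- dwells[seq_len(n_keep)]
  states <- states[seq_len(n_keep)]
  starts <- cumsum(c(0, dwells[-length(dwells)]))
  ends <- starts + dwells
  censored <- ends > duration
  ends[censored] <- duration
  dwells_obs <- ends - starts
  events <- data.frame(
    state = ifelse(states, "bound", "unbound"),
    start = starts, end = ends, censored = censored)
  trace <- event_trace(
    bound_dwells = dwells_obs[states & !censored],
    unbound_dwells = dwells_obs[!states & !censored],
    censored_bound = dwells_obs[states & censored],
    censored_unbound = dwells_obs[!states & censored],
    total_time = duration)
  heights <- NULL
  if (emit_heights) {
    if (is.null(dt)) dt <- min(1 / k_on, 1 / k_off) / 20
    times <- seq(dt, duration, by = dt)
    idx <- findInterval(times, starts)
    lev <- ifelse(states[idx], bound_level, unbound_level)
    heights <- data.frame(time = times,
                          height = lev + rnorm(length(times), 0, jitter_sd))
  }
  structure(list(trace = trace, events = events, heights = heights,
                 params = list(k_on = k_on, k_off = k_off,
                               duration = duration, seed = seed)),
            class = "telegraph_sim")
}

#' Synthetic acceptor-photobleaching intensity pairs
#'
#' Donor intensities after photobleach drawn around a base level with
#' multiplicative Gaussian noise; intensities before photobleach are the
#' after values quenched by the true efficiency, with independent
#' multiplicative noise. With `noise_sd = 0` the estimator
#' [fret_from_photobleach()] recovers `true_efficiency` exactly.
#'
#' @param true_efficiency True FRET efficiency, in `[0, 1)`.
#' @param noise_sd Relative (multiplicative) noise sd (default 0.05).
#' @param n Number of intensity pairs (default 100).
#' @param base_level Mean donor intensity after photobleach (default 1000).
#' @param seed RNG seed.
#' @return A data.frame `donor_before`, `donor_after` with the truth kept
#'   in attribute `"true_efficiency"`.
#' @export
gen_fret_intensities <- function(true_efficiency, noise_sd = 0.05, n = 100,
                                 base_level = 1000, seed = 1) {
  if (true_efficiency < 0 || true_efficiency >= 1)
    stop("`true_efficiency` must be in [0, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  set.seed(seed)
  after <- base_level * (1 + rnorm(n, 0, noise_sd))
  after <- pmax(after, 1e-6 * base_level)
  before <- after * (1 - true_efficiency) * (1 + rnorm(n, 0, noise_sd))
  before <- pmax(before, 0)
  structure(data.frame(donor_before = before, donor_after = after),
            true_efficiency = true_efficiency)
}

#' Synthetic linear IL2 response curves
#'
#' Emulates hourly sampling of the fraction of responding T cells over a
#' stimulation time course, for several linkers and independent
#' experiments: normalized response `slope * t` plus additive Gaussian
#' noise, clipped to `[0, 1]`. With the default slopes and noise the clip
#' bias on fitted slopes stays below 1%. Ground-truth slopes are retained.
#'
#' @param slopes Named numeric vector of response rates per hour (names =
#'   linker labels); all non-negative. Default: six linkers from 0.15 down
#'   to 0.05.
#' @param flory_radii Optional numeric vector (same length) of linker Flory
#'   radii carried into the table.
#' @param noise_sd Additive noise sd (default 0.02).
#' @param timepoints Sampling times in hours (default `1:6`).
#' @param n_experiments Independent experiments (default 3).
#' @param seed RNG seed.
#' @return A data.frame `linker`, `experiment_id`, `time_h`, `response`
#'   (and `flory_radius` if given), with attribute `"true_slopes"`.
#' @export
gen_response_curves <- function(slopes = setNames(seq(0.15, 0.05, length.out = 6),
                                                  paste0("linker_", 1:6)),
                                flory_radii = NULL,
                                noise_sd = 0.02, timepoints = 1:6,
                                n_experiments = 3, seed = 1) {
  if (any(slopes < 0)) stop("slopes must be non-negative")
  if (is.null(names(slopes))) names(slopes) <- paste0("linker_", seq_along(slopes))
  if (!is.null(flory_radii) && length(flory_radii) != length(slopes))
    stop("`flory_radii` must match `slopes` in length")
  set.seed(seed)
  grid <- expand.grid(time_h = timepoints,
                      experiment_id = paste0("exp", seq_len(n_experiments)),
                      linker = names(slopes),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- slopes[grid$linker] * grid$time_h
  grid$response <- pmin(1, pmax(0, mu + rnorm(nrow(grid), 0, noise_sd)))
  if (!is.null(flory_radii))
    grid$flory_radius <- setNames(flory_radii, names(slopes))[grid$linker]
  grid <- grid[, c("linker", "experiment_id", "time_h",
                   intersect("flory_radius", names(grid)), "response")]
  structure(grid, true_slopes = slopes)
}

#' Properties of the nine PEG linkers (88 Da to 60 kDa)
#'
#' The packaged linker property table: molecular weight, PEO unit count,
#' contour length, Flory radius, and the measured acceptor-photobleaching
#' FRET efficiency (percent; `NA` for the three longest linkers, whose
#' transfer was unmeasurable).
#'
#' @return A data.frame with columns `linker`, `mw`, `n_units`,
#'   `contour_length_nm`, `flory_radius_nm`, `fret_pct` (9 rows).
#' @export
#' @examples
#' peg_linker_table()
peg_linker_table <- function() {
  path <- system.file("extdata", "peg_linkers.csv", package = "pegtether",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
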