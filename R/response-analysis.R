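#' Normalize response measurements within each experiment
#'
#' Divides each measurement by the maximum of its own experiment, so every
#' experiment's peak maps to 1. Averaging across experiments, when wanted,
#' happens after this per-experiment normalization. Idempotent and
#' order-preserving within an experiment.
#'
#' @param table A data.frame with at least the grouping and value columns.
#' @param value_col Name of the response column (default `"response"`).
#' @param group_col Name of the experiment identifier column (default
#'   `"experiment_id"`).
#' @return The input table with the value column replaced by its normalized
#'   version.
#' @export
normalize_response <- function(table, value_col = "response",
                               group_col = "experiment_id") {
  stopifnot(is.data.frame(table))
  if (!all(c(value_col, group_col) %in% names(table)))
    stop("`table` must contain columns '", value_col, "' and '", group_col, "'")
  v <- table[[value_col]]
  if (any(!is.finite(v)) || any(v < 0))
    stop("responses must be finite and non-negative")
  for (g in unique(table[[group_col]])) {
    sel <- table[[group_col]] == g
    m <- max(v[sel])
    if (m <= 0)
      stop("experiment '", g, "' has no positive response: cannot normalize")
    v[sel] <- v[sel] / m
  }
  table[[value_col]] <- v
  table
}

#' Linear response-rate fit
#'
#' Ordinary least squares of normalized response against time with a free
#' intercept; the slope is the response rate (normalized response per
#' hour).
#'
#' @param timepoints Numeric vector of times (hours); at least 3 distinct
#'   values.
#' @param response Numeric vector of normalized responses, same length.
#' @return An object of class `rate_fit`: `slope`, `intercept`, `se_slope`,
#'   `r_squared`, `n`.
#' @export
#' @examples
#' fit_rate(1:6, 0.1 * (1:6))$slope  # 0.1
fit_rate <- function(timepoints, response) {
  if (length(timepoints) != length(response))
    stop("`timepoints` and `response` must have equal length")
  if (length(timepoints) < 3)
    stop("at least 3 timepoints are required for a rate fit")
  if (length(unique(timepoints)) < 2)
    stop("degenerate design: all timepoints identical")
  fit <- lm(response ~ timepoints)
  s <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se_slope = s$coefficients[2, 2],
                 r_squared = s$r.squared,
                 n = length(timepoints),
                 fit = fit),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("response rate %.4g +/- %.2g per hour (intercept %.3g, R^2 %.3f, n = %d)\n",
              x$slope, x$se_slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Response rates for every linker of a response table
#'
#' Applies [fit_rate()] per linker to the pooled (already per-experiment
#' normalized) measurements.
#'
#' @param table A data.frame with columns `linker`, a time column and a
#'   value column (see [gen_response_curves()] for the schema).
#' @param time_col,value_col Column names (defaults `"time_h"`,
#'   `"response"`).
#' @return A data.frame with columns `linker`, `slope`, `se_slope`,
#'   `intercept`, `r_squared`, plus `flory_radius` if present in `table`.
#' @export
fit_rates <- function(table, time_col = "time_h", value_col = "response") {
  stopifnot(is.data.frame(table), "linker" %in% names(table))
  linkers <- unique(table$linker)
  out <- lapply(linkers, function(l) {
    sub <- table[table$linker == l, ]
    f <- fit_rate(sub[[time_col]], sub[[value_col]])
    data.frame(linker = l, slope = f$slope, se_slope = f$se_slope,
               intercept = f$intercept, r_squared = f$r_squared,
               flory_radius = if ("flory_radius" %in% names(sub))
                 sub$flory_radius[1] else NA_real_)
  })
  do.call(rbind, out)
}

#' Association between response rates and a paired kinetic quantity
#'
#' Pearson and Spearman correlation between per-linker response rates and a
#' paired quantity (Flory radius, or scaled on/off rates), matched by
#' linker label. Also emits the response rates scaled against a reference
#' linker (default: the first, by convention the shortest for which a rate
#' was fitted). Degenerate (constant) inputs yield `NA` correlations with
#' attribute `degenerate = TRUE`.
#'
#' @param fits A data.frame from [fit_rates()] (columns `linker`, `slope`).
#' @param paired A data.frame with columns `linker` and `value`, or a named
#'   numeric vector.
#' @param reference Reference linker for the scaled-rate table (default:
#'   first row of `fits`).
#' @return A list of class `rate_association`: `pearson`, `spearman`,
#'   `p_pearson`, `p_spearman`, `n`, `scaled` (data.frame `linker`,
#'   `slope`, `scaled_slope`, `value`).
#' @export
correlate_rates <- function(fits, paired, reference = NULL) {
  stopifnot(is.data.frame(fits), all(c("linker", "slope") %in% names(fits)))
  if (is.numeric(paired) && !is.null(names(paired)))
    paired <- data.frame(linker = names(paired), value = unname(paired))
  stopifnot(is.data.frame(paired),
            all(c("linker", "value") %in% names(paired)))
  unmatched <- setdiff(fits$linker, paired$linker)
  if (length(unmatched))
    stop("no paired value for linker(s): ", paste(unmatched, collapse = ", "))
  x <- fits$slope
  y <- paired$value[match(fits$linker, paired$linker)]
  if (length(x) < 3) stop("at least 3 paired observations are required")
  if (is.null(reference)) reference <- fits$linker[1]
  iref <- match(reference, fits$linker)
  if (is.na(iref)) stop("reference linker '", reference, "' not found")
  scaled <- data.frame(linker = fits$linker, slope = x,
                       scaled_slope = x / x[iref], value = y)
  degenerate <- sd(x) == 0 || sd(y) == 0
  if (degenerate) {
    res <- list(pearson = NA_real_, spearman = NA_real_,
                p_pearson = NA_real_, p_spearman = NA_real_,
                n = length(x), scaled = scaled)
  } else {
    pe <- cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    res <- list(pearson = unname(pe$estimate), spearman = unname(sp$estimate),
                p_pearson = pe$p.value, p_spearman = sp$p.value,
                n = length(x), scaled = scaled)
  }
  structure(res, class = "rate_association", degenerate = degenerate)
}

#' @export
print.rate_association <- function(x, ...) {
  if (attr(x, "degenerate")) {
    cat("correlation undefined: constant input\n")
  } else {
    cat(sprintf("Pearson r = %.3f (p = %.3g); Spearman rho = %.3f (p = %.3g); n = %d\n",
                x$pearson, x$p_pearson, x$spearman, x$p_spearman, x$n))
  }
  invisible(x)
}
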