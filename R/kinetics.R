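# Reporter kinetics: population-mean traces, logistic fits, the
# doubling-time induction statistic T_ind, and the CV heterogeneity
# measure.

#' Population mean and SD of area-normalized traces
#'
#' @param traces data.frame (cell_id, t_min, intensity_au, area_px);
#'   all cells must share one uniform time grid
#' @return data.frame: t_min, mean, sd, n_cells
#' @export
mean_trace <- function(traces) {
  stopifnot(all(c("cell_id", "t_min", "intensity_au", "area_px") %in%
                  names(traces)),
            all(traces$area_px > 0))
  grids <- split(traces$t_min, traces$cell_id)
  ref <- grids[[1]]
  if (is.unsorted(ref, strictly = TRUE)) stop("time must be strictly increasing")
  if (!all(vapply(grids, function(g) identical(g, ref), logical(1)))) {
    stop("cells do not share a common time grid; resample upstream")
  }
  norm <- traces$intensity_au / traces$area_px
  m <- do.call(cbind, split(norm, traces$cell_id))
  data.frame(t_min = ref, mean = rowMeans(m),
             sd = if (ncol(m) == 1) 0 else apply(m, 1, sd),
             n_cells = ncol(m))
}

#' Sum of squares of a 4-parameter logistic against data
#' @noRd
logistic4 <- function(t, b, A, r, t0) b + A / (1 + exp(-r * (t - t0)))

#' Fit a 4-parameter logistic to a mean induction profile
#'
#' Model F(t) = b + A / (1 + exp(-r (t - t0))), fitted by bounded
#' least squares (b, A >= 0; 0 < r <= 10) from a data-driven
#' initialization plus `n_start - 1` deterministically perturbed
#' restarts; the best SSE wins. `converged` is TRUE only when
#' R^2 exceeds `r2_gate`; flat series (SST ~ 0) are degenerate and
#' reported unconverged.
#'
#' @param time numeric vector (>= 8 points)
#' @param values mean normalized intensities
#' @param r2_gate goodness-of-fit gate on R^2
#' @param n_start number of optimization starts
#' @return list of class `logistic_fit`: b, A, r, t0, r2, sse,
#'   converged
#' @export
fit_logistic <- function(time, values, r2_gate = 0.95, n_start = 5L) {
  stopifnot(length(time) == length(values))
  if (length(time) < 8) stop("need >= 8 time points")
  if (!all(is.finite(time)) || !all(is.finite(values))) {
    stop("non-finite values in input")
  }
  # optimize on a unit scale so the fit is exactly equivariant under
  # intensity rescaling (and well conditioned)
  scale <- max(abs(values))
  if (scale == 0) scale <- 1
  values <- values / scale
  sst <- sum((values - mean(values))^2)
  lo <- c(b = 0, A = 0, r = 1e-6, t0 = min(time) - diff(range(time)))
  hi <- c(b = Inf, A = Inf, r = 10, t0 = max(time) + diff(range(time)))

  vmin <- min(values); vmax <- max(values)
  rise <- vmax - vmin
  half <- vmin + rise / 2
  t_half <- time[which.min(abs(values - half))]
  i25 <- which(values >= vmin + 0.25 * rise)[1]
  i75 <- which(values >= vmin + 0.75 * rise)[1]
  span <- if (!is.na(i25) && !is.na(i75) && time[i75] > time[i25]) {
    time[i75] - time[i25]
  } else {
    diff(range(time)) / 4
  }
  r0 <- min(10, max(1e-3, 2.2 / span)) # logit(0.75)-logit(0.25) = 2.2
  init <- c(b = max(vmin, 1e-9), A = max(rise, 1e-9), r = r0, t0 = t_half)

  sse_fun <- function(par) {
    pred <- logistic4(time, par[1], par[2], par[3], par[4])
    sum((pred - values)^2)
  }
  set.seed(20260918L) # deterministic multi-start perturbations
  perturb <- rbind(rep(1, 4),
                   matrix(exp(rnorm(4 * (n_start - 1), 0, 0.3)),
                          ncol = 4))
  best <- NULL
  for (i in seq_len(nrow(perturb))) {
    p0 <- pmin(pmax(init * perturb[i, ], lo + 1e-9), c(1e9, 1e9, 10, hi[4]))
    fit <- tryCatch(
      optim(p0, sse_fun, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("logistic fit failed from every start")
  par <- best$par
  r2 <- if (sst > 1e-12) 1 - best$value / sst else NA_real_
  structure(list(b = unname(par[1]) * scale, A = unname(par[2]) * scale,
                 r = unname(par[3]), t0 = unname(par[4]),
                 r2 = r2, sse = best$value * scale^2,
                 converged = isTRUE(r2 > r2_gate)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: b=%.3g A=%.3g r=%.3g t0=%.3g R2=%.4f (%s)\n",
              x$b, x$A, x$r, x$t0, x$r2,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Induction time: time to doubling of the initial mean intensity
#'
#' Solves b + A/(1 + exp(-r (T - t0))) = 2 F0 for the fitted logistic.
#' Censored when the fit did not converge, when the plateau b + A
#' never reaches 2 F0, or when the crossing lies before t = 0. When a
#' censored profile still rises, the time of the fitted maximum slope
#' (t0) is reported as `t_max_rise` so near-threshold profiles remain
#' comparable.
#'
#' @param fit a `logistic_fit`
#' @param F0 observed mean normalized intensity at t = 0
#' @return list of class `induction_result`: T_ind (NA when censored),
#'   censored, reason, t_max_rise, threshold
#' @export
induction_time <- function(fit, F0) {
  stopifnot(inherits(fit, "logistic_fit"), is.finite(F0), F0 > 0)
  thr <- 2 * F0
  res <- list(T_ind = NA_real_, censored = TRUE, reason = NA_character_,
              t_max_rise = fit$t0, threshold = thr)
  class(res) <- "induction_result"
  if (!fit$converged) {
    res$reason <- "poor fit"
    return(res)
  }
  if (fit$b + fit$A <= thr) {
    res$reason <- "threshold never reached"
    return(res)
  }
  if (thr <= fit$b) {
    # already above threshold at the baseline: boundary case
    res$T_ind <- 0
    res$censored <- FALSE
    res$reason <- "threshold at or below baseline"
    return(res)
  }
  T_ind <- fit$t0 - (1 / fit$r) * log(fit$A / (thr - fit$b) - 1)
  if (T_ind < 0) {
    res$T_ind <- 0
    res$censored <- FALSE
    res$reason <- "crossing before t = 0, clamped"
    return(res)
  }
  res$T_ind <- T_ind
  res$censored <- FALSE
  res
}

#' @export
print.induction_result <- function(x, ...) {
  if (x$censored) {
    cat("T_ind: censored (", x$reason, "), max rise at ",
        round(x$t_max_rise, 1), " min\n", sep = "")
  } else {
    cat("T_ind:", round(x$T_ind, 2), "min\n")
  }
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, n >= 2, nonzero mean
#' @return CV
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  sd(values) / m
}

#' Full kinetics analysis of one trace set
#'
#' Mean trace, logistic fit, T_ind, and the across-cell CV of
#' normalized intensity at the final frame.
#'
#' @param traces trace data.frame (see [mean_trace()])
#' @param r2_gate R^2 gate for the fit
#' @return list: mean (data.frame), fit, induction, cv_final
#' @export
analyze_traces <- function(traces, r2_gate = 0.95) {
  mt <- mean_trace(traces)
  fit <- fit_logistic(mt$t_min, mt$mean, r2_gate = r2_gate)
  ind <- induction_time(fit, mt$mean[1])
  last <- traces$t_min == max(traces$t_min)
  cv <- coefficient_of_variation(traces$intensity_au[last] /
                                   traces$area_px[last])
  list(mean = mt, fit = fit, induction = ind, cv_final = cv)
}
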