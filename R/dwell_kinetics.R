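#' Classify and filter dwells between detected steps
#'
#' A dwell is the interval between two consecutive stepping transitions
#' within one trace. Dwells are classified by the signs of the flanking
#' steps (\code{"+/+"}, \code{"-/-"}, \code{"+/-"}, \code{"-/+"}) and
#' filtered by the instrument dead time: dwells shorter than 20 ms are
#' excluded at ATP concentrations of 5 uM and below, shorter than 7 ms at
#' 10 uM and above (the fast-acquisition condition).
#'
#' @param steps A \code{"step_records"} data frame, time-ordered within
#'   traces (output of \code{\link{extract_steps}}, possibly row-bound over
#'   traces).
#' @param atp ATP concentration (uM); defaults to the per-step \code{atp}
#'   column.
#' @return Data frame of class \code{"dwell_records"}: \code{t} (s),
#'   \code{class}, \code{d} (succeeding step size, bp), \code{atp},
#'   \code{force}, \code{trace_id}.
#' @export
classify_and_filter_dwells <- function(steps, atp = NULL) {
  if (!nrow(steps)) {
    out <- data.frame(t = numeric(0), class = character(0), d = numeric(0),
                      atp = numeric(0), force = numeric(0),
                      trace_id = character(0))
    return(structure(out, class = c("dwell_records", "data.frame")))
  }
  if (is.null(atp)) atp <- steps$atp
  atp <- rep_len(atp, nrow(steps))
  out <- do.call(rbind, lapply(split(seq_len(nrow(steps)), steps$trace_id),
  function(ix) {
    st <- steps[ix, ]
    a <- atp[ix]
    if (nrow(st) < 2) return(NULL)
    i <- seq_len(nrow(st) - 1)
    cls <- paste0(ifelse(st$s[i] > 0, "+", "-"), "/",
                  ifelse(st$s[i + 1] > 0, "+", "-"))
    data.frame(t = st$dwell_after[i], class = cls, d = st$s[i + 1],
               atp = a[i + 1], force = st$force[i + 1],
               trace_id = st$trace_id[i + 1], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(t = numeric(0), class = character(0),
                                      d = numeric(0), atp = numeric(0),
                                      force = numeric(0),
                                      trace_id = character(0))
  cutoff <- ifelse(out$atp >= 10, 0.007, 0.020)
  out <- out[out$t >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("dwell_records", "data.frame"))
}

#' Boxcar-averaged dwell statistics versus step size
#'
#' Sorts dwells of one class by the size of the succeeding step and slides a
#' boxcar window, returning windowed means of the dwell time, its square,
#' and the step size, each with standard error sd/sqrt(window).
#'
#' @param dwells A \code{"dwell_records"} data frame.
#' @param class Dwell class to analyze (\code{"+/+"} or \code{"-/-"}).
#' @param window Boxcar window size; the field convention is 25--45 points
#'   and the default sits at the midpoint.
#' @return Data frame \code{d}, \code{d_sd}, \code{t_mean}, \code{t_se},
#'   \code{t2_mean}, \code{t2_se}, one row per window position.
#' @export
dwell_vs_step <- function(dwells, class = "+/+", window = 35) {
  if (window < 2) stop("'window' must be >= 2")
  sub <- dwells[dwells$class == class, , drop = FALSE]
  if (nrow(sub) < window)
    stop(sprintf("need >= %d dwells of class %s (have %d)",
                 window, class, nrow(sub)))
  o <- order(sub$d)
  t <- sub$t[o]; d <- sub$d[o]
  n <- length(t)
  roll <- function(v, f) vapply(seq_len(n - window + 1),
                                function(i) f(v[i:(i + window - 1)]),
                                numeric(1))
  data.frame(
    d = roll(d, mean), d_sd = roll(d, stats::sd),
    t_mean = roll(t, mean), t_se = roll(t, stats::sd) / sqrt(window),
    t2_mean = roll(t^2, mean), t2_se = roll(t^2, stats::sd) / sqrt(window)
  )
}

#' Fit a linear trendline kappa (d + d0) to dwell statistics vs step size
#'
#' Weighted least squares of a windowed mean (dwell time or n_min) against
#' step size in the parameterization \eqn{y = \kappa (d + d_0)}. Fitting is
#' linear in \eqn{(\kappa, \kappa d_0)}; \eqn{d_0} and its standard error
#' follow by the delta method.
#'
#' @param d Step sizes (window means, bp).
#' @param y Windowed statistic (mean dwell time or n_min).
#' @param se Optional standard errors for weights \eqn{1/se^2}.
#' @return Object of class \code{"trendline_fit"}: \code{kappa}, \code{d0},
#'   their SEs, \code{degenerate} flag (TRUE when the curve is flat and
#'   \eqn{d_0} is unidentifiable).
#' @export
fit_trendline <- function(d, y, se = NULL) {
  if (length(d) < 3) stop("need >= 3 window points")
  w <- if (is.null(se) || any(se <= 0)) rep(1, length(d)) else 1 / se^2
  fit <- stats::lm(y ~ d, weights = w)
  kappa <- unname(stats::coef(fit)["d"])
  b <- unname(stats::coef(fit)["(Intercept)"])
  # an exactly linear input has zero residual variance; the "perfect fit"
  # warning from summary.lm is expected there
  V <- suppressWarnings(stats::vcov(fit))
  kappa_se <- sqrt(V["d", "d"])
  scale <- max(abs(y), 1e-12) / max(abs(d), 1)
  if (!is.finite(kappa) || abs(kappa) < .Machine$double.eps^0.5 * scale) {
    d0 <- NA_real_; d0_se <- NA_real_; degenerate <- TRUE
  } else {
    d0 <- b / kappa
    # delta method on d0 = b / kappa
    g <- c(1 / kappa, -b / kappa^2)
    d0_se <- sqrt(drop(t(g) %*% V[c("(Intercept)", "d"), c("(Intercept)", "d")] %*% g))
    degenerate <- FALSE
  }
  structure(list(kappa = kappa, kappa_se = kappa_se, d0 = d0, d0_se = d0_se,
                 degenerate = degenerate, fit = fit),
            class = "trendline_fit")
}

#' @export
print.trendline_fit <- function(x, ...) {
  if (x$degenerate)
    cat("Trendline fit: flat curve, kappa ~ 0, d0 unidentifiable\n")
  else
    cat(sprintf("Trendline y = kappa (d + d0): kappa = %.4g +/- %.2g /bp, d0 = %.4g +/- %.2g bp\n",
                x$kappa, x$kappa_se, x$d0, x$d0_se))
  invisible(x)
}

#' @export
coef.trendline_fit <- function(object, ...) {
  c(kappa = object$kappa, d0 = object$d0)
}

#' Minimum number of rate-limiting kinetic events per dwell
#'
#' The inverse randomness parameter
#' \deqn{n_{min} = \left(\langle t^2\rangle / \langle t\rangle^2 - 1\right)^{-1}
#'   = \frac{\langle t\rangle^2}{\mathrm{Var}(t)},}
#' a lower bound on the number of rate-limiting kinetic events composing
#' each dwell (equals k for an Erlang-k dwell built from k equal-rate
#' exponential events; heterogeneous rates push it below k). The standard
#' error is propagated from the standard errors of \eqn{\langle t\rangle}
#' and \eqn{\langle t^2\rangle} by the delta method, including their sample
#' covariance.
#'
#' @param t Dwell times (s), at least 10 unless \code{min_n} is lowered.
#' @param min_n Minimum sample size.
#' @return Object of class \code{"nmin_result"}: \code{t_mean}, \code{t2_mean},
#'   \code{n_min}, \code{se}, \code{n}, \code{degenerate} (TRUE when the
#'   sample variance is zero and n_min is infinite).
#' @export
n_min <- function(t, min_n = 10) {
  n <- length(t)
  if (n < min_n) stop(sprintf("need >= %d dwells", min_n))
  m1 <- mean(t); m2 <- mean(t^2)
  vr <- m2 - m1^2
  if (vr <= 0) {
    return(structure(list(t_mean = m1, t2_mean = m2, n_min = Inf,
                          se = NA_real_, n = n, degenerate = TRUE),
                     class = "nmin_result"))
  }
  nm <- m1^2 / vr
  # delta method: gradient of m1^2/(m2 - m1^2) wrt (m1, m2)
  g <- c(2 * m1 * m2 / vr^2, -m1^2 / vr^2)
  S <- stats::cov(cbind(t, t^2)) / n
  se <- sqrt(drop(t(g) %*% S %*% g))
  structure(list(t_mean = m1, t2_mean = m2, n_min = nm, se = se, n = n,
                 degenerate = FALSE),
            class = "nmin_result")
}

#' @export
print.nmin_result <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("n_min: infinite (zero dwell-time variance, n = %d)\n", x$n))
  else
    cat(sprintf("n_min = %.3f +/- %.3f  (<t> = %.4g s, <t^2> = %.4g s^2, n = %d)\n",
                x$n_min, x$se, x$t_mean, x$t2_mean, x$n))
  invisible(x)
}

#' Bootstrap outlier scan for n_min
#'
#' Because the dwell-time variance grows much faster with a long outlier
#' dwell than the squared mean, a single aberrant dwell can depress n_min.
#' The scan bootstraps n_min, tests the bootstrap distribution for
#' bimodality with a two-component Gaussian mixture (flagged when the minor
#' weight is at least \code{w_min} and the mode separation is at least
#' \code{sep_sd} pooled standard deviations), and identifies dwells whose
#' occurrence count among low-mode resamples exceeds its expectation by
#' \code{z_flag} binomial standard deviations. Flagged dwells are removed
#' and n_min recomputed.
#'
#' @param t Dwell times (s), at least 30.
#' @param n_boot Bootstrap iterations.
#' @param seed Optional integer seed.
#' @param w_min,sep_sd,z_flag Detection thresholds (see above).
#' @return List with \code{outliers} (indices into \code{t}, possibly
#'   empty), \code{result} (n_min after removal), \code{result_raw},
#'   \code{multimodal}, \code{boot} (bootstrap n_min values).
#' @export
nmin_outlier_scan <- function(t, n_boot = 2000, seed = NULL,
                              w_min = 0.1, sep_sd = 4, z_flag = 3) {
  n <- length(t)
  if (n < 30) stop("need >= 30 dwells for the outlier scan")
  if (!is.null(seed)) set.seed(seed)
  raw <- n_min(t)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  nm <- apply(idx, 2, function(ii) {
    ti <- t[ii]; m1 <- mean(ti); v <- mean(ti^2) - m1^2
    if (v <= 0) Inf else m1^2 / v
  })
  ok <- is.finite(nm)
  nmf <- nm[ok]
  multimodal <- FALSE
  outliers <- integer(0)
  if (length(nmf) >= 50 && stats::sd(nmf) > 0) {
    gm <- tryCatch(fit_double_gaussian(nmf), error = function(e) NULL)
    if (!is.null(gm) && !gm$singular) {
      pooled <- sqrt(sum(gm$weights * gm$sds^2))
      if (min(gm$weights) >= w_min &&
          abs(diff(gm$means)) >= sep_sd * pooled) {
        multimodal <- TRUE
        low <- which.min(gm$means)
        # posterior assignment of each resample to the low mode
        p_low <- gm$weights[low] * stats::dnorm(nm, gm$means[low], gm$sds[low])
        p_hi <- gm$weights[3 - low] *
          stats::dnorm(nm, gm$means[3 - low], gm$sds[3 - low])
        in_low <- ok & (p_low > p_hi)
        B_low <- sum(in_low)
        if (B_low > 0) {
          counts <- tabulate(idx[, in_low, drop = FALSE], nbins = n)
          expect <- B_low               # each dwell appears once per resample on average
          sdev <- sqrt(B_low * (1 - 1 / n))
          outliers <- which(counts > expect + z_flag * sdev)
        }
      }
    }
  }
  cleaned <- if (length(outliers)) n_min(t[-outliers]) else raw
  list(outliers = outliers, result = cleaned, result_raw = raw,
       multimodal = multimodal, boot = nm)
}

#' Unwinding / re-zipping speed estimates
#'
#' Two estimators: \code{"step_over_dwell"} divides the mean step magnitude
#' of one direction by the mean dwell time of the matching class (+/+ for
#' unwinding, -/- for re-zipping; backstep classes are ignored), the
#' estimator used at the low ATP concentrations where steps are resolved.
#' \code{"line_fit"} fits straight lines to intervals of uninterrupted
#' motion, for saturating ATP where dwells are unresolvable.
#'
#' @param steps A \code{"step_records"} data frame (step_over_dwell).
#' @param dwells A \code{"dwell_records"} data frame (step_over_dwell).
#' @param direction \code{"unwinding"} or \code{"rezipping"}.
#' @param method Estimator (see above).
#' @param trace An \code{"hp_trace"} (line_fit).
#' @param intervals List of \code{c(t0, t1)} time intervals (line_fit);
#'   when NULL, maximal monotone runs of at least \code{min_run} seconds of
#'   the boxcar-smoothed trace are auto-selected.
#' @param smooth_window Boxcar width (samples) for auto-selection.
#' @param min_run Minimum run duration (s) for auto-selection.
#' @return List with \code{speed} (bp/s, signed: negative for re-zipping),
#'   \code{se}, \code{n}.
#' @export
speeds <- function(steps = NULL, dwells = NULL,
                   direction = c("unwinding", "rezipping"),
                   method = c("step_over_dwell", "line_fit"),
                   trace = NULL, intervals = NULL,
                   smooth_window = 25, min_run = 0.5) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (method == "step_over_dwell") {
    cls <- if (direction == "unwinding") "+/+" else "-/-"
    keep_s <- if (direction == "unwinding") steps$s > 0 else steps$s < 0
    s <- abs(steps$s[keep_s])
    t <- dwells$t[dwells$class == cls]
    if (!length(s) || !length(t))
      stop("no steps/dwells for direction ", direction)
    ms <- mean(s); mt <- mean(t)
    v <- ms / mt
    rel <- sqrt((stats::sd(s) / sqrt(length(s)) / ms)^2 +
                  (stats::sd(t) / sqrt(length(t)) / mt)^2)
    sgn <- if (direction == "unwinding") 1 else -1
    list(speed = sgn * v, se = v * rel, n = length(t))
  } else {
    if (is.null(trace)) stop("line_fit needs a trace")
    sr <- attr(trace, "sample_rate")
    if (is.null(sr)) sr <- 1 / stats::median(diff(trace$time))
    if (is.null(intervals)) {
      k <- min(smooth_window, nrow(trace) %/% 2)
      sm <- stats::filter(trace$position, rep(1 / k, k), sides = 2)
      dsm <- sign(diff(as.numeric(sm)))
      dsm[is.na(dsm)] <- 0
      want <- if (direction == "unwinding") 1 else -1
      r <- rle(dsm == want)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      sel <- which(r$values & r$lengths >= min_run * sr)
      intervals <- lapply(sel, function(i)
        trace$time[c(starts[i], ends[i])])
    }
    if (!length(intervals)) stop("no qualifying intervals found")
    sl <- vapply(intervals, function(iv) {
      keep <- trace$time >= iv[1] & trace$time <= iv[2]
      if (sum(keep) < 5) return(NA_real_)
      unname(stats::coef(stats::lm(position ~ time, data = trace[keep, ]))[2])
    }, numeric(1))
    sl <- sl[is.finite(sl)]
    if (!length(sl)) stop("no usable intervals")
    list(speed = mean(sl),
         se = if (length(sl) > 1) stats::sd(sl) / sqrt(length(sl)) else NA_real_,
         n = length(sl))
  }
}

#' Michaelis-Menten fit of speed versus ATP
#'
#' Nonlinear least squares of \eqn{v = V_{max} [ATP]/(K_M + [ATP])},
#' weighted by \eqn{1/se^2} when standard errors are supplied
#' (Levenberg-Marquardt).
#'
#' @param atp ATP concentrations (uM), at least 3 levels.
#' @param v Speeds (bp/s); magnitudes are fit, the sign of the input is
#'   reported back.
#' @param se Optional standard errors of \code{v}.
#' @return Object of class \code{"mm_fit"}: \code{Vmax}, \code{KM}, their
#'   SEs, the underlying \code{nls} fit, and \code{saturated} flag (TRUE
#'   when KM is indistinguishable from 0 and the curve is flat).
#' @export
fit_michaelis_menten <- function(atp, v, se = NULL) {
  if (length(unique(atp)) < 3) stop("need >= 3 ATP levels")
  sgn <- if (mean(v) < 0) -1 else 1
  vv <- abs(v)
  w <- if (is.null(se)) rep(1, length(v)) else 1 / se^2
  start <- list(Vmax = max(vv),
                KM = max(min(atp[vv >= max(vv) / 2][1], max(atp)), min(atp)))
  if (!is.finite(start$KM)) start$KM <- stats::median(atp)
  df <- data.frame(atp = atp, vv = vv)
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ Vmax * atp / (KM + atp), data = df,
                      start = start, weights = w,
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      # a flat speed-vs-ATP curve leaves KM unidentified (saturation):
      # report the plateau with KM ~ 0 and flag it
      if (stats::sd(vv) < 1e-3 * mean(vv)) NULL else stop(e)
    })
  if (is.null(fit)) {
    return(structure(list(Vmax = sgn * mean(vv), KM = 0,
                          Vmax_se = stats::sd(vv) / sqrt(length(vv)),
                          KM_se = NA_real_, sign = sgn, fit = NULL,
                          saturated = TRUE),
                     class = "mm_fit"))
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(NA_real_, NA_real_))
  saturated <- cf["KM"] < 1e-6 * max(atp) ||
    (is.finite(ses[2]) && cf["KM"] < ses[2] / 10)
  structure(list(Vmax = sgn * unname(cf["Vmax"]), KM = unname(cf["KM"]),
                 Vmax_se = unname(ses[1]), KM_se = unname(ses[2]),
                 sign = sgn, fit = fit, saturated = saturated),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g +/- %.2g bp/s, KM = %.4g +/- %.2g uM%s\n",
              x$Vmax, x$Vmax_se, x$KM, x$KM_se,
              if (x$saturated) "  [KM ~ 0: saturation degeneracy]" else ""))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Vmax = object$Vmax, KM = object$KM)

#' @export
predict.mm_fit <- function(object, atp, ...) {
  object$Vmax * atp / (object$KM + atp)
}
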