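#' Error-weighted kernel density estimate of step sizes
#'
#' Builds the step-size distribution as a normalized sum of Gaussian kernels,
#' one per detected step, centered at the measured step size and with width
#' equal to its standard error, so poorly determined steps contribute
#' diffusely. Evaluated on a 0.01-bp grid spanning 0 to
#' \eqn{\max(s+3\sigma)} for unwinding steps or \eqn{\min(s-3\sigma)} to 0
#' for re-zipping steps.
#'
#' @param steps A \code{"step_records"} data frame (or any data frame with
#'   columns \code{s}, \code{sigma_s}); supply only steps of one sign.
#' @param side \code{"unwinding"} or \code{"rezipping"}; inferred from the
#'   sign of the mean step when missing.
#' @param grid_by Grid spacing (bp).
#' @return Object of class \code{"step_kde"}: \code{grid}, \code{density}
#'   (integrates to 1), \code{se} (NULL until \code{\link{bootstrap_kde}}),
#'   \code{n_steps}, \code{side}, and the kernel centers/widths.
#' @export
step_size_kde <- function(steps, side = NULL, grid_by = 0.01) {
  s <- steps$s; sig <- steps$sigma_s
  if (length(s) < 1) stop("no steps supplied")
  if (any(sig <= 0)) stop("all steps need sigma_s > 0")
  if (is.null(side)) side <- if (mean(s) >= 0) "unwinding" else "rezipping"
  grid <- if (side == "unwinding")
    seq(0, max(s + 3 * sig), by = grid_by)
  else
    seq(min(s - 3 * sig), 0, by = grid_by)
  K <- kernel_matrix(grid, s, sig)
  dens <- rowMeans(K)
  dens <- dens / trapz(grid, dens)
  structure(list(grid = grid, density = dens, se = NULL,
                 n_steps = length(s), side = side, s = s, sigma_s = sig),
            class = "step_kde")
}

kernel_matrix <- function(grid, centers, widths) {
  # grid x steps matrix of kernel values
  G <- matrix(grid, nrow = length(grid), ncol = length(centers))
  C <- matrix(centers, nrow = length(grid), ncol = length(centers),
              byrow = TRUE)
  W <- matrix(widths, nrow = length(grid), ncol = length(centers),
              byrow = TRUE)
  stats::dnorm(G, C, W)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Bootstrap standard-error band for a step-size KDE
#'
#' Resamples the step set with replacement, rebuilds the KDE for each
#' resample, and records the pointwise standard deviation across resamples
#' as the significance band.
#'
#' @param kde A \code{"step_kde"}.
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param seed Optional integer seed.
#' @return The \code{kde} with \code{se} (pointwise standard error) and
#'   \code{boot_mean} filled in.
#' @export
bootstrap_kde <- function(kde, n_boot = 10000, seed = NULL) {
  stopifnot(inherits(kde, "step_kde"))
  n <- kde$n_steps
  if (n < 2) stop("need >= 2 steps to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  K <- kernel_matrix(kde$grid, kde$s, kde$sigma_s)
  W <- stats::rmultinom(n_boot, n, rep(1 / n, n)) / n
  D <- K %*% W                                     # grid x n_boot densities
  norms <- apply(D, 2, function(col) trapz(kde$grid, col))
  D <- sweep(D, 2, norms, "/")
  mu <- rowMeans(D)
  se <- sqrt(pmax(rowMeans(D^2) - mu^2, 0) * n_boot / (n_boot - 1))
  kde$se <- se
  kde$boot_mean <- mu
  kde$n_boot <- n_boot
  kde
}

#' Peak spacing (periodicity) of a step-size KDE
#'
#' Finds local maxima of the density that exceed twice the bootstrap
#' standard error at their location and returns the median spacing between
#' adjacent significant peaks. On low-noise data from a half-integer step
#' lattice with mixed odd/even nucleotide releases the spacing is 0.5 bp.
#'
#' @param kde A \code{"step_kde"} that has been through
#'   \code{\link{bootstrap_kde}} (peaks are unfiltered if \code{se} is
#'   missing).
#' @param se_factor Significance multiple of the bootstrap SE.
#' @return List with \code{peaks} (grid positions), \code{spacing} (median
#'   adjacent spacing, NA if fewer than two peaks).
#' @export
kde_periodicity <- function(kde, se_factor = 2) {
  stopifnot(inherits(kde, "step_kde"))
  d <- kde$density
  n <- length(d)
  if (n < 3) return(list(peaks = numeric(0), spacing = NA_real_))
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n],
              FALSE)
  pk_ix <- which(is_max)
  if (!is.null(kde$se) && length(pk_ix)) {
    # a significant peak must both exceed se_factor * SE and rise by at
    # least se_factor * SE above the deeper flanking trough
    keep <- vapply(seq_along(pk_ix), function(i) {
      p <- pk_ix[i]
      lo <- if (i == 1) 1L else pk_ix[i - 1]
      hi <- if (i == length(pk_ix)) n else pk_ix[i + 1]
      trough <- max(min(d[lo:p]), min(d[p:hi]))
      d[p] > se_factor * kde$se[p] &&
        (d[p] - trough) > se_factor * kde$se[p]
    }, logical(1))
    pk_ix <- pk_ix[keep]
  }
  peaks <- kde$grid[pk_ix]
  is_max <- seq_len(n) %in% pk_ix
  # structure finer than one kernel width cannot be resolved: collapse
  # groups of maxima closer than the median kernel width to the highest one
  if (length(peaks) >= 2) {
    minsep <- stats::median(kde$sigma_s)
    hts <- d[is_max]
    keep <- logical(length(peaks))
    grp_start <- 1
    for (i in seq_along(peaks)) {
      last <- i == length(peaks) || peaks[i + 1] - peaks[i] > minsep
      if (last) {
        g <- grp_start:i
        keep[g[which.max(hts[g])]] <- TRUE
        grp_start <- i + 1
      }
    }
    peaks <- peaks[keep]
  }
  list(peaks = peaks,
       spacing = if (length(peaks) >= 2) stats::median(diff(peaks))
                 else NA_real_)
}

#' @export
print.step_kde <- function(x, ...) {
  cat(sprintf("Step-size KDE (%s): %d steps, grid %.3g..%.3g bp%s\n",
              x$side, x$n_steps, min(x$grid), max(x$grid),
              if (is.null(x$se)) "" else sprintf(", %d bootstrap iterations",
                                                 x$n_boot)))
  invisible(x)
}

#' @export
plot.step_kde <- function(x, ...) {
  plot(x$grid, x$density, type = "l", xlab = "step size (bp)",
       ylab = "probability density", ...)
  if (!is.null(x$se)) {
    graphics::polygon(c(x$grid, rev(x$grid)),
                      c(x$density + x$se, rev(x$density - x$se)),
                      border = NA, col = grDevices::adjustcolor("blue", 0.2))
    graphics::lines(x$grid, x$density)
  }
  invisible(x)
}

#' Two-component Gaussian mixture fit of step sizes
#'
#' Maximum-likelihood fit by expectation-maximization, deterministically
#' initialized at the sample mean and at twice the mean -- the double-step
#' reading of the second component. Components are reported with means in
#' ascending magnitude.
#'
#' When the double-step component carries only a few percent of the mass
#' and the main component is heavy-tailed (as for merged event-log steps on
#' the half-integer lattice), the fully heteroscedastic fit tends to spread
#' its second component over the main component's tail instead of the
#' double-step peak; \code{equal_var = TRUE} pools the two variances, the
#' standard robustification for that regime.
#'
#' @param s Step sizes (bp), at least 20.
#' @param equal_var Share one pooled variance between the components
#'   (default FALSE: free per-component variances).
#' @param max_iter,tol EM iteration controls.
#' @return Object of class \code{"gmix_fit"}: \code{means}, \code{sds},
#'   \code{weights}, \code{loglik}, \code{converged}, \code{singular}
#'   (TRUE if the fit collapsed and a single Gaussian was reported).
#' @export
fit_double_gaussian <- function(s, equal_var = FALSE, max_iter = 500,
                                tol = 1e-8) {
  n <- length(s)
  if (n < 20) stop("need >= 20 steps for a mixture fit")
  mu <- c(mean(s), 2 * mean(s))
  sg <- rep(stats::sd(s), 2)
  w <- c(0.7, 0.3)
  ll_old <- -Inf
  converged <- FALSE
  singular <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(s, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(s, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) { singular <- TRUE; break }
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 2 || n2 < 2) { singular <- TRUE; break }
    mu <- c(sum(g * s) / n1, sum((1 - g) * s) / n2)
    if (equal_var) {
      v <- (sum(g * (s - mu[1])^2) + sum((1 - g) * (s - mu[2])^2)) / n
      sg <- rep(sqrt(v), 2)
    } else {
      sg <- sqrt(c(sum(g * (s - mu[1])^2) / n1,
                   sum((1 - g) * (s - mu[2])^2) / n2))
    }
    sg <- pmax(sg, 1e-4)
    w <- c(n1, n2) / n
  }
  if (!singular) {
    # model selection guard: if a single Gaussian explains the data as
    # well (by BIC), the two-component split is spurious; report the
    # flagged single-Gaussian fallback instead
    sd1 <- stats::sd(s) * sqrt((n - 1) / n)
    ll1 <- sum(stats::dnorm(s, mean(s), sd1, log = TRUE))
    k2 <- if (equal_var) 4 else 5
    if (2 * ll1 - 2 * log(n) >= 2 * ll_old - k2 * log(n)) singular <- TRUE
  }
  if (singular) {
    mu <- c(mean(s), NA); sg <- c(stats::sd(s), NA); w <- c(1, 0)
    ll_old <- sum(stats::dnorm(s, mu[1], sg[1], log = TRUE))
  } else {
    o <- order(abs(mu))
    mu <- mu[o]; sg <- sg[o]; w <- w[o]
  }
  structure(list(means = mu, sds = sg, weights = w, loglik = ll_old,
                 converged = converged, singular = singular, n = n),
            class = "gmix_fit")
}

#' @export
print.gmix_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit\n")
  for (k in 1:2)
    cat(sprintf("  component %d: mean %.3f bp, sd %.3f, weight %.3f\n",
                k, x$means[k], x$sds[k], x$weights[k]))
  if (x$singular) cat("  [collapsed to a single Gaussian]\n")
  invisible(x)
}

#' @export
coef.gmix_fit <- function(object, ...) {
  c(mean1 = object$means[1], mean2 = object$means[2],
    sd1 = object$sds[1], sd2 = object$sds[2],
    w1 = object$weights[1], w2 = object$weights[2])
}

#' Signed pairwise distance distribution of a trace segment
#'
#' Computes later-minus-earlier position differences over every ordered pair
#' of samples, histograms them with the sign retained (positive differences
#' correspond to unwinding, negative to re-zipping), and estimates the
#' dominant periodicity as the median spacing between local maxima of the
#' lightly smoothed histogram.
#'
#' @param x Position samples (bp) of one trace segment (uniform sampling).
#' @param bin Histogram bin width (bp); the default is coarse enough to
#'   suppress sub-bp lattice structure and resolve the multi-bp stepping
#'   period.
#' @param max_points Pairs are computed on at most this many samples
#'   (uniform thinning keeps memory bounded).
#' @return List with \code{mids}, \code{counts} (signed-distance histogram),
#'   \code{periodicity} (bp, from the positive side unless it is empty) and
#'   the per-side estimates.
#' @export
pairwise_distance_distribution <- function(x, bin = 0.25, max_points = 3000) {
  n <- length(x)
  if (n < 2) stop("need >= 2 samples")
  if (n > max_points) x <- x[round(seq(1, n, length.out = max_points))]
  n <- length(x)
  d <- as.vector(outer(x, x, "-"))
  idx <- as.vector(outer(seq_len(n), seq_len(n), "-"))
  d <- d[idx > 0]                         # later minus earlier
  rng <- range(d)
  breaks <- seq(floor(rng[1] / bin) * bin - bin / 2,
                ceiling(rng[2] / bin) * bin + bin / 2, by = bin)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  # light Gaussian smoothing before peak finding
  if (length(cnt) >= 9) {
    w <- stats::dnorm(-4:4, 0, 1.5); w <- w / sum(w)
    sm <- stats::filter(cnt, w, sides = 2)
    sm[is.na(sm)] <- 0
  } else sm <- cnt
  per_side <- function(keep) {
    m <- h$mids[keep]; y <- as.numeric(sm)[keep]
    if (length(y) < 3) return(NA_real_)
    pk <- which(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                  y[2:(length(y) - 1)] >= y[3:length(y)]) + 1L
    pk <- pk[y[pk] > 0.05 * max(y)]
    if (length(pk) < 2) return(NA_real_)
    stats::median(diff(m[pk]))
  }
  pos <- per_side(h$mids >= -bin / 2)
  neg <- per_side(h$mids <= bin / 2)
  list(mids = h$mids, counts = cnt,
       periodicity = if (!is.na(pos)) pos else abs(neg),
       periodicity_pos = pos, periodicity_neg = abs(neg))
}

#' Correlation of step magnitude with an experimental covariate
#'
#' Pearson correlation of \eqn{|s|} with a covariate (force, stem position,
#' or ATP), with a two-sided permutation p-value.
#'
#' @param steps A \code{"step_records"} data frame.
#' @param covariate Column name: \code{"force"}, \code{"position"}, or
#'   \code{"atp"} (any numeric column works).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
covariate_independence <- function(steps, covariate, n_perm = 10000,
                                   seed = NULL) {
  if (nrow(steps) < 10) stop("need >= 10 steps")
  v <- steps[[covariate]]
  if (is.null(v)) stop("unknown covariate column: ", covariate)
  if (stats::sd(v) == 0) stop("covariate is constant")
  if (!is.null(seed)) set.seed(seed)
  a <- abs(steps$s)
  r <- stats::cor(a, v)
  ac <- a - mean(a)
  denom <- sqrt(sum(ac^2))
  rp <- replicate(n_perm, {
    vp <- sample(v)
    sum(ac * (vp - mean(vp))) / (denom * sqrt(sum((vp - mean(vp))^2)))
  })
  p <- (1 + sum(abs(rp) >= abs(r))) / (n_perm + 1)
  list(r = r, p = p, n = nrow(steps))
}
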