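#' Per-strand strand-release size distribution
#'
#' Probability mass function over the number of nucleotides released from one
#' sequestered loop (3' or 5') per release event. The default pmf on
#' \{1,2,3,4\} nt has mean 3 and mode 3, matching the description of the
#' loop-size-change distributions obtained from enhanced-sampling MD
#' (releases range from 1 to 4 nt with 3 nt most likely). Exact values are a
#' package calibration, not digitized figure data.
#'
#' @param strand \code{"3p"} or \code{"5p"}.
#' @param support Positive integer release sizes (nt).
#' @param pmf Probabilities, same length as \code{support}, summing to 1.
#' @return An object of class \code{"release_dist"}.
#' @export
release_distribution <- function(strand = c("3p", "5p"),
                                 support = 1:4,
                                 pmf = c(0.05, 0.20, 0.45, 0.30)) {
  strand <- match.arg(strand)
  if (length(support) == 0L) stop("empty support")
  if (any(support <= 0) || any(support != round(support)))
    stop("'support' must be positive integers")
  if (length(pmf) != length(support))
    stop("'pmf' and 'support' lengths differ")
  check_pmf(pmf, "pmf")
  structure(list(strand = strand, support = as.integer(support), pmf = pmf),
            class = "release_dist")
}

#' @export
print.release_dist <- function(x, ...) {
  cat(sprintf("Release distribution (%s strand): mean %.3g nt\n",
              x$strand, sum(x$support * x$pmf)))
  print(stats::setNames(x$pmf, x$support))
  invisible(x)
}

#' Release distribution from event counts
#'
#' Normalizes a table of observed release-size counts (e.g. loop-size changes
#' tallied from MD post-processing, or from a generator event log) into a
#' \code{\link{release_distribution}}.
#'
#' @param counts Non-negative counts, one per size in \code{support}.
#' @param support Release sizes (nt).
#' @param strand \code{"3p"} or \code{"5p"}.
#' @return A \code{"release_dist"}.
#' @export
release_dist_from_counts <- function(counts, support = seq_along(counts),
                                     strand = "3p") {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  release_distribution(strand, support, counts / sum(counts))
}

#' Theoretical step-size distribution from independent strand releases
#'
#' Exact discrete convolution of the 3' and 5' release-size distributions,
#' mapped to base pairs by halving the total nucleotides released: an
#' observed step of \eqn{s} bp collects every combination with
#' \eqn{r_3 + r_5 = 2s} nt. The support is the half-integer bp lattice; odd
#' nucleotide totals produce the half-integer step sizes.
#'
#' @param d3,d5 \code{\link{release_distribution}} objects.
#' @return An object of class \code{"step_pmf"} with fields \code{support}
#'   (bp), \code{pmf}, \code{mean}, \code{sd}.
#' @export
step_pmf_from_release <- function(d3, d5) {
  stopifnot(inherits(d3, "release_dist"), inherits(d5, "release_dist"))
  tot <- outer(d3$support, d5$support, "+")
  pr <- outer(d3$pmf, d5$pmf)
  agg <- tapply(as.vector(pr), as.vector(tot), sum)
  nt <- as.numeric(names(agg))
  bp <- nt / 2
  p <- as.numeric(agg)
  m <- sum(bp * p)
  structure(list(support = bp, pmf = p, mean = m,
                 sd = sqrt(sum((bp - m)^2 * p))),
            class = "step_pmf")
}

#' @export
print.step_pmf <- function(x, ...) {
  cat(sprintf("Theoretical step-size pmf: mean %.3f bp, sd %.3f bp\n",
              x$mean, x$sd))
  print(stats::setNames(round(x$pmf, 4), x$support))
  invisible(x)
}

#' Sample step sizes from the independent-release model
#'
#' @param d3,d5 \code{\link{release_distribution}} objects.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return List with \code{samples} (bp, on the half-integer lattice),
#'   \code{mean}, \code{sd}.
#' @export
sample_theoretical_steps <- function(d3, d5, n = 500, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- (draw_pmf(d3$support, d3$pmf, n) + draw_pmf(d5$support, d5$pmf, n)) / 2
  list(samples = s, mean = mean(s), sd = stats::sd(s))
}
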