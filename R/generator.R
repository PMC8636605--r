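#' Configuration for the delayed-release stepping trace generator
#'
#' Builds and validates the parameter set of the kinetic Monte-Carlo model in
#' which a helicase unwinds (or re-zips) a DNA hairpin one base pair per
#' catalytic cycle while sequestering the two nascent single strands as loops,
#' releasing them in bursts of 1--4 nt per strand only after a variable number
#' of cycles. Observed position jumps are therefore multiples of 0.5 bp
#' (half the total number of nucleotides released).
#'
#' The two-step kinetic scheme -- ATP binding at rate \code{k_on * [ATP]}
#' followed by catalysis at rate \code{k_cat} -- makes the mean unwinding
#' speed exactly Michaelis-Menten: \eqn{v = V_{max}[ATP]/(K_M + [ATP])} with
#' \eqn{V_{max} = k_{cat} \cdot 1\,bp} and \eqn{K_M = k_{cat}/k_{on}}.
#' Defaults correspond to the measured unwinding kinetics
#' (\eqn{V_{max} = 220} bp/s, \eqn{K_M = 39} uM).
#'
#' @param k_cat Catalytic rate (1/s).
#' @param k_on ATP binding rate (1/uM/s).
#' @param cycles_per_release Probability mass function over the number of
#'   catalytic cycles between strand-release events; support is
#'   \code{1:length(cycles_per_release)}. The default pmf on \{1,2,3,4\}
#'   has mean exactly 3 and mode 3.
#' @param release_3p,release_5p \code{\link{release_distribution}} objects
#'   giving the number of nucleotides released per event from the 3' and 5'
#'   loops.
#' @param loop_cap Maximum sequestered nucleotides per strand; a scheduled
#'   release is enlarged as needed to pull an over-long loop back under the
#'   cap, keeping the carry-over random walk bounded.
#' @param noise_sd Gaussian measurement noise, bp rms per sample.
#' @param sample_rate Sampling rate in Hz (100 Hz, or 267 Hz for the
#'   fast-acquisition condition).
#' @param backstep_prob Probability that a scheduled event has inverted sign
#'   (a backstep).
#' @param burst_mean_bp Mean burst length (bp) before a strand switch in
#'   alternating mode.
#' @param loop_init Initial loop contents (nt per strand) in re-zipping mode,
#'   set at the stationary post-event loop level so traces start in steady
#'   state; unwinding always starts with empty loops.
#' @return An object of class \code{"gen_config"}.
#' @seealso \code{\link{simulate_trace}}, \code{\link{mean_speed_theoretical}}
#' @export
generator_config <- function(k_cat = 220,
                             k_on = 220 / 39,
                             cycles_per_release = c(0.05, 0.20, 0.45, 0.30),
                             release_3p = release_distribution("3p"),
                             release_5p = release_distribution("5p"),
                             loop_cap = 8,
                             noise_sd = 0.3,
                             sample_rate = 100,
                             backstep_prob = 0.08,
                             burst_mean_bp = 20,
                             loop_init = 6) {
  stopifnot(is.numeric(k_cat), length(k_cat) == 1L,
            is.numeric(k_on), length(k_on) == 1L)
  if (k_cat <= 0 || k_on <= 0)
    stop("kinetic rates 'k_cat' and 'k_on' must be positive")
  check_pmf(cycles_per_release, "cycles_per_release")
  if (!inherits(release_3p, "release_dist") ||
      !inherits(release_5p, "release_dist"))
    stop("'release_3p' and 'release_5p' must be release_distribution objects")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (sample_rate <= 0) stop("'sample_rate' must be positive")
  if (backstep_prob < 0 || backstep_prob >= 1)
    stop("'backstep_prob' must lie in [0, 1)")
  if (loop_cap < max(release_3p$support, release_5p$support))
    stop("'loop_cap' must be at least the largest release size")
  structure(list(
    k_cat = k_cat, k_on = k_on,
    cycles_per_release = cycles_per_release / sum(cycles_per_release),
    release_3p = release_3p, release_5p = release_5p,
    loop_cap = loop_cap, noise_sd = noise_sd, sample_rate = sample_rate,
    backstep_prob = backstep_prob, burst_mean_bp = burst_mean_bp,
    loop_init = loop_init
  ), class = "gen_config")
}

check_pmf <- function(p, name) {
  if (!is.numeric(p) || length(p) < 1L || any(p < 0))
    stop(sprintf("'%s' must be a non-negative numeric vector", name))
  if (abs(sum(p) - 1) > 1e-12)
    stop(sprintf("'%s' must sum to 1 (got %.15g)", name, sum(p)))
  invisible(TRUE)
}

#' @export
print.gen_config <- function(x, ...) {
  cat("Delayed-release stepping generator\n")
  cat(sprintf("  k_cat = %g /s, k_on = %g /uM/s  (Vmax = %g bp/s, KM = %g uM)\n",
              x$k_cat, x$k_on, x$k_cat, x$k_cat / x$k_on))
  cat(sprintf("  cycles/release pmf on 1..%d: %s (mean %.2f)\n",
              length(x$cycles_per_release),
              paste(format(x$cycles_per_release), collapse = " "),
              sum(seq_along(x$cycles_per_release) * x$cycles_per_release)))
  cat(sprintf("  noise %.3g bp rms @ %g Hz, backstep prob %.2g, loop cap %d nt\n",
              x$noise_sd, x$sample_rate, x$backstep_prob, x$loop_cap))
  invisible(x)
}

#' Theoretical mean speed of the two-step kinetic scheme
#'
#' Closed form used to validate the generator: one base pair advanced per
#' cycle of mean duration \eqn{1/(k_{on}[ATP]) + 1/k_{cat}}, i.e.
#' \eqn{v = V_{max}[ATP]/(K_M+[ATP])}.
#'
#' @param config A \code{\link{generator_config}}.
#' @param atp ATP concentration (uM).
#' @return Mean speed in bp/s.
#' @export
mean_speed_theoretical <- function(config, atp) {
  stopifnot(inherits(config, "gen_config"))
  if (any(atp <= 0)) stop("'atp' must be positive")
  1 / (1 / (config$k_on * atp) + 1 / config$k_cat)
}

#' Draw per-cycle waiting times from the binding + catalysis scheme
#'
#' @inheritParams mean_speed_theoretical
#' @param n Number of cycles to draw.
#' @return Numeric vector of cycle durations (s).
#' @export
simulate_cycle_times <- function(config, atp, n) {
  stopifnot(inherits(config, "gen_config"), n >= 1, atp > 0)
  stats::rexp(n, config$k_on * atp) + stats::rexp(n, config$k_cat)
}

#' Monte-Carlo estimate of mean speed at one ATP concentration
#'
#' @inheritParams simulate_cycle_times
#' @return List with \code{speed} (bp/s), its standard error \code{se}
#'   (delta method on the mean cycle time), and \code{n} cycles.
#' @export
simulate_speed <- function(config, atp, n = 2000) {
  w <- simulate_cycle_times(config, atp, n)
  m <- mean(w)
  se_m <- stats::sd(w) / sqrt(n)
  list(speed = 1 / m, se = se_m / m^2, n = n)
}

draw_pmf <- function(support, pmf, n = 1L) {
  support[sample.int(length(support), n, replace = TRUE, prob = pmf)]
}

#' Simulate a stepping trace under the delayed-release looping model
#'
#' Runs the kinetic Monte-Carlo engine: each catalytic cycle advances the
#' hairpin by 1 bp and feeds 1 nt into each sequestered loop (unwinding), or
#' re-anneals 1 bp and drains 1 nt from each loop (re-zipping). After a
#' random number of cycles drawn from \code{cycles_per_release}, a release
#' (unwinding) or incorporation (re-zipping) event changes the observed
#' extension by \eqn{(r_3+r_5)/2} bp, where \eqn{r_3, r_5} are drawn
#' independently from the per-strand release distributions, truncated to
#' the current loop contents (and enlarged when a loop would exceed
#' \code{loop_cap}); the remainder carries over to later events, which is
#' what decouples the observed jump from the cycle count and produces
#' half-integer steps. With probability \code{backstep_prob} a scheduled
#' event is instead a sign-flipped excursion outside the loop bookkeeping.
#' The latent piecewise-constant position is sampled on a uniform grid with
#' i.i.d. Gaussian noise.
#'
#' @param config A \code{\link{generator_config}}.
#' @param atp ATP concentration (uM).
#' @param duration Trace duration (s); must be positive.
#' @param mode One of \code{"unwinding"}, \code{"rezipping"},
#'   \code{"alternating"}.
#' @param force Applied force (pN), recorded as metadata.
#' @param id Trace identifier.
#' @param seed Optional integer seed for this trace's RNG stream.
#' @return A list with elements \code{trace} (class \code{"hp_trace"}:
#'   data frame of \code{time}, \code{position} plus metadata attributes) and
#'   \code{events} (class \code{"event_log"}: per-event and per-cycle
#'   ground-truth tables).
#' @export
simulate_trace <- function(config, atp, duration,
                           mode = c("unwinding", "rezipping", "alternating"),
                           force = 12, id = "trace", seed = NULL) {
  stopifnot(inherits(config, "gen_config"))
  mode <- match.arg(mode)
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive")
  if (atp <= 0) stop("'atp' must be positive")
  if (!is.null(seed)) set.seed(seed)

  k_bind <- config$k_on * atp
  k_cat <- config$k_cat
  nc_supp <- seq_along(config$cycles_per_release)
  nc_pmf <- config$cycles_per_release
  r3 <- config$release_3p; r5 <- config$release_5p
  cap <- config$loop_cap

  max_nc <- length(nc_pmf)
  dir <- if (mode == "rezipping") -1L else 1L
  L3 <- if (dir == 1L) 0L else as.integer(max(config$loop_init, max_nc))
  L5 <- L3
  h <- 0L                      # hairpin bp unwound relative to start
  tnow <- 0
  cum_rel <- 0L                # cumulative nucleotides released (signed)
  burst_target <- if (mode == "alternating")
    stats::rexp(1, 1 / config$burst_mean_bp) else Inf
  burst_h0 <- 0L

  nc_target <- draw_pmf(nc_supp, nc_pmf)
  cyc_since <- 0L

  # growable event / cycle logs
  ev_t <- ev_r3 <- ev_r5 <- ev_dx <- numeric(0)
  ev_type <- character(0)
  ev_cyc <- ev_L3 <- ev_L5 <- ev_h <- ev_cum <- integer(0)
  cy_t <- numeric(0); cy_dh <- cy_L3 <- cy_L5 <- cy_h <- integer(0)

  log_event <- function(type, a3, a5, dx) {
    ev_t[length(ev_t) + 1L] <<- tnow
    ev_type[length(ev_type) + 1L] <<- type
    ev_cyc[length(ev_cyc) + 1L] <<- cyc_since
    ev_r3[length(ev_r3) + 1L] <<- a3
    ev_r5[length(ev_r5) + 1L] <<- a5
    ev_dx[length(ev_dx) + 1L] <<- dx
    ev_L3[length(ev_L3) + 1L] <<- L3
    ev_L5[length(ev_L5) + 1L] <<- L5
    ev_h[length(ev_h) + 1L] <<- h
    ev_cum[length(ev_cum) + 1L] <<- cum_rel
  }

  while (tnow < duration) {
    # one catalytic cycle: ATP binding then catalysis
    tnow <- tnow + stats::rexp(1, k_bind) + stats::rexp(1, k_cat)
    if (tnow >= duration) break

    if (dir == 1L) {
      h <- h + 1L; L3 <- L3 + 1L; L5 <- L5 + 1L
    } else {
      # re-zipping transfers 1 nt from each loop back into the duplex;
      # an empty loop forces an incorporation event before the transfer
      if (L3 < 1L || L5 < 1L) {
        a3 <- min(draw_pmf(r3$support, r3$pmf), cap - L3)
        a5 <- min(draw_pmf(r5$support, r5$pmf), cap - L5)
        L3 <- L3 + a3; L5 <- L5 + a5
        cum_rel <- cum_rel - (a3 + a5)
        log_event("incorporation", -a3, -a5, -(a3 + a5) / 2)
        cyc_since <- 0L
        nc_target <- draw_pmf(nc_supp, nc_pmf)
      }
      h <- h - 1L; L3 <- L3 - 1L; L5 <- L5 - 1L
    }
    cyc_since <- cyc_since + 1L
    cy_t[length(cy_t) + 1L] <- tnow
    cy_dh[length(cy_dh) + 1L] <- dir
    cy_L3[length(cy_L3) + 1L] <- L3
    cy_L5[length(cy_L5) + 1L] <- L5
    cy_h[length(cy_h) + 1L] <- h

    if (cyc_since >= nc_target) {
      back <- stats::runif(1) < config$backstep_prob
      if (back) {
        # spontaneous excursion opposite to the processive direction
        # (transient unlooping/looping), outside the loop bookkeeping:
        # loops, hairpin position and the released-nt tally are untouched
        a3 <- draw_pmf(r3$support, r3$pmf)
        a5 <- draw_pmf(r5$support, r5$pmf)
        log_event("backstep", -dir * a3, -dir * a5, -dir * (a3 + a5) / 2)
      } else if (dir == 1L) {
        # release amount = pmf draw truncated to the loop, enlarged when
        # needed to pull an over-long loop back under the cap, so release
        # events stay in lockstep with the drawn cycle counts
        a3 <- min(L3, max(draw_pmf(r3$support, r3$pmf), L3 - cap))
        a5 <- min(L5, max(draw_pmf(r5$support, r5$pmf), L5 - cap))
        if (a3 + a5 > 0L) {
          L3 <- L3 - a3; L5 <- L5 - a5
          cum_rel <- cum_rel + a3 + a5
          log_event("release", a3, a5, (a3 + a5) / 2)
        }
      } else {
        # incorporation = pmf draw, enlarged when the loop is too short to
        # survive the next drain, truncated at the cap
        a3 <- min(max(draw_pmf(r3$support, r3$pmf), max_nc - L3), cap - L3)
        a5 <- min(max(draw_pmf(r5$support, r5$pmf), max_nc - L5), cap - L5)
        if (a3 + a5 > 0L) {
          L3 <- L3 + a3; L5 <- L5 + a5
          cum_rel <- cum_rel - (a3 + a5)
          log_event("incorporation", -a3, -a5, -(a3 + a5) / 2)
        }
      }
      cyc_since <- 0L
      nc_target <- draw_pmf(nc_supp, nc_pmf)
    }

    if (mode == "alternating" && abs(h - burst_h0) >= burst_target) {
      dir <- -dir
      burst_h0 <- h
      burst_target <- stats::rexp(1, 1 / config$burst_mean_bp)
      cyc_since <- 0L
      nc_target <- draw_pmf(nc_supp, nc_pmf)
    }
  }

  events <- data.frame(
    time = ev_t, type = ev_type, cycles = ev_cyc,
    r3 = ev_r3, r5 = ev_r5, dx_bp = ev_dx,
    L3 = ev_L3, L5 = ev_L5, h_bp = ev_h, cum_released_nt = ev_cum,
    stringsAsFactors = FALSE
  )
  cycles <- data.frame(time = cy_t, dh = cy_dh, L3 = cy_L3, L5 = cy_L5,
                       h_bp = cy_h)
  log <- structure(list(events = events, cycles = cycles, mode = mode),
                   class = "event_log")

  tgrid <- seq(0, duration, by = 1 / config$sample_rate)
  latent <- c(0, cumsum(events$dx_bp))[findInterval(tgrid, events$time) + 1L]
  pos <- latent + stats::rnorm(length(tgrid), 0, config$noise_sd)
  trace <- structure(
    data.frame(time = tgrid, position = pos),
    class = c("hp_trace", "data.frame"),
    force = force, atp = atp, sample_rate = config$sample_rate,
    id = id, mode = mode
  )
  list(trace = trace, events = log)
}

#' @export
print.hp_trace <- function(x, ...) {
  cat(sprintf("Hairpin trace '%s': %d samples @ %g Hz (%.3g s), %g pN, %g uM ATP\n",
              attr(x, "id"), nrow(x), attr(x, "sample_rate"),
              max(x$time), attr(x, "force"), attr(x, "atp")))
  invisible(x)
}

#' @export
plot.hp_trace <- function(x, ...) {
  plot(x$time, x$position, type = "l", col = "grey40",
       xlab = "time (s)", ylab = "position (bp unwound)",
       main = attr(x, "id"), ...)
  invisible(x)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log (%s): %d events, %d catalytic cycles\n",
              x$mode, nrow(x$events), nrow(x$cycles)))
  if (nrow(x$events)) {
    tb <- table(x$events$type)
    cat("  ", paste(names(tb), tb, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Verify nucleotide conservation in an event log
#'
#' In unwinding mode every unwound base pair feeds one nucleotide into each
#' loop, so at every event the cumulative released nucleotides must equal
#' \eqn{2 \Delta h - (L_3 + L_5)} exactly.
#'
#' @param log An \code{"event_log"} from \code{\link{simulate_trace}}.
#' @return \code{TRUE} invisibly if conservation holds; otherwise an error.
#' @export
check_conservation <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  if (!nrow(ev)) return(invisible(TRUE))
  if (any(ev$L3 < 0) || any(ev$L5 < 0))
    stop("negative loop contents in event log")
  lhs <- ev$cum_released_nt
  rhs <- 2 * ev$h_bp - (ev$L3 + ev$L5)
  if (log$mode == "unwinding" && any(lhs != rhs))
    stop("conservation violated: released nt != 2*bp - loops")
  invisible(TRUE)
}

#' Merge release events separated by less than a dead time
#'
#' Emulates the finite time resolution of step detection on an event log:
#' consecutive same-direction events closer together than \code{dead_time}
#' are unresolvable and merge into a single observed step whose size is the
#' sum of the individual jumps. Used to study the double-step artifact at
#' high ATP, where a fraction of dwells falls below the detection limit.
#'
#' @param log An \code{"event_log"}.
#' @param dead_time Detection dead time (s), e.g. 0.015.
#' @param direction \code{"unwinding"} (positive jumps) or
#'   \code{"rezipping"} (negative jumps).
#' @return Numeric vector of merged observed step sizes (bp).
#' @export
merge_unresolved_events <- function(log, dead_time,
                                    direction = c("unwinding", "rezipping")) {
  stopifnot(inherits(log, "event_log"))
  direction <- match.arg(direction)
  ev <- log$events
  ev <- if (direction == "unwinding") ev[ev$dx_bp > 0, , drop = FALSE]
        else ev[ev$dx_bp < 0, , drop = FALSE]
  if (nrow(ev) == 0) return(numeric(0))
  if (nrow(ev) == 1) return(ev$dx_bp)
  gap <- diff(ev$time)
  out <- numeric(0)
  cur <- ev$dx_bp[1]
  for (j in seq_along(gap)) {
    if (gap[j] < dead_time) {
      cur <- cur + ev$dx_bp[j + 1]
    } else {
      out <- c(out, cur)
      cur <- ev$dx_bp[j + 1]
    }
  }
  c(out, cur)
}

#' Write a reproducible set of synthetic trace fixtures
#'
#' @param config A \code{\link{generator_config}}.
#' @param atp_list ATP concentrations (uM), one group of traces per value.
#' @param n_traces_per_atp Integer vector (recycled) of traces per level.
#' @param out_dir Output directory (created if needed).
#' @param seed Base integer seed; trace i of level j uses a stream derived
#'   from it, so the same seed reproduces the files byte for byte.
#' @param duration Trace duration (s).
#' @param mode Passed to \code{\link{simulate_trace}}.
#' @return Invisibly, the manifest (also written as \code{manifest.json}).
#' @export
make_fixture_set <- function(config, atp_list, n_traces_per_atp, out_dir,
                             seed = 1L, duration = 25, mode = "unwinding") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(atp_list) == 0) {
    manifest <- list(seed = seed, traces = list())
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  n_traces_per_atp <- rep_len(n_traces_per_atp, length(atp_list))
  entries <- list()
  k <- 0L
  for (j in seq_along(atp_list)) {
    for (i in seq_len(n_traces_per_atp[j])) {
      k <- k + 1L
      id <- sprintf("atp%g_trace%02d", atp_list[j], i)
      sim <- simulate_trace(config, atp_list[j], duration, mode = mode,
                            id = id, seed = (seed + 7919L * k) %% .Machine$integer.max)
      tsv <- file.path(out_dir, paste0(id, ".tsv"))
      js <- file.path(out_dir, paste0(id, "_events.json"))
      write_trace(sim$trace, tsv)
      jsonlite::write_json(sim$events$events, js, digits = NA, pretty = TRUE)
      entries[[k]] <- list(id = id, atp = atp_list[j], trace = basename(tsv),
                           events = basename(js))
    }
  }
  manifest <- list(seed = seed, duration = duration, mode = mode,
                   traces = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
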