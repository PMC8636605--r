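#' Run the full stepping-analysis pipeline
#'
#' Orchestrates simulate (optional) -> step detection -> step statistics ->
#' dwell kinetics -> loop-model comparison, writing a JSON summary and TSV
#' step tables when \code{out_dir} is given. Every random stage derives its
#' stream from the global seed, so reruns with the same configuration give
#' identical summaries.
#'
#' Configuration fields (list or YAML): either \code{traces} (character
#' vector of trace TSV paths) or \code{simulate} (list with \code{atp}
#' vector, \code{n_traces}, \code{duration}, optional \code{mode} and
#' generator overrides); optional \code{detection$sensitivity},
#' \code{boxcar_window}, \code{n_boot}, \code{seed}, \code{out_dir}.
#'
#' @param config Configuration list or YAML path (see
#'   \code{\link{read_config}}).
#' @return Object of class \code{"helisteps_run"}: \code{steps},
#'   \code{dwells}, \code{kde}, \code{periodicity}, \code{gaussians},
#'   \code{speeds}, \code{mm}, \code{loop_model}, \code{summary}.
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  traces <- stage("input", {
    if (!is.null(config$traces)) {
      lapply(config$traces, read_trace)
    } else {
      sim <- config$simulate
      gc_args <- sim$generator
      gcfg <- if (is.null(gc_args)) generator_config()
              else do.call(generator_config, gc_args)
      atp <- rep(sim$atp, each = sim$n_traces)
      out <- vector("list", length(atp))
      for (i in seq_along(atp)) {
        out[[i]] <- simulate_trace(
          gcfg, atp[i], sim$duration,
          mode = if (is.null(sim$mode)) "unwinding" else sim$mode,
          id = sprintf("sim%03d_atp%g", i, atp[i]),
          seed = (config$seed + 104729L * i) %% .Machine$integer.max)$trace
      }
      out
    }
  })

  steps <- stage("detect", {
    recs <- lapply(traces, function(tr) {
      fit <- detect_steps(tr, sensitivity = config$detection$sensitivity)
      extract_steps(fit)
    })
    out <- do.call(rbind, lapply(recs, as.data.frame))
    structure(out, class = c("step_records", "data.frame"))
  })
  if (!nrow(steps)) stop("[detect] no steps detected in any trace")

  stepstats <- stage("stepstats", {
    up <- steps[steps$s > 0, , drop = FALSE]
    res <- list(mean_unwinding = if (nrow(up)) mean(up$s) else NA_real_,
                mean_rezipping = if (any(steps$s < 0))
                  mean(steps$s[steps$s < 0]) else NA_real_)
    if (nrow(up) >= 2) {
      kde <- step_size_kde(up)
      kde <- bootstrap_kde(kde, n_boot = config$n_boot,
                           seed = config$seed + 11L)
      res$kde <- kde
      res$periodicity <- kde_periodicity(kde)
    }
    if (nrow(up) >= 20)
      res$gaussians <- fit_double_gaussian(up$s)
    res
  })

  dwells <- stage("dwellstats", classify_and_filter_dwells(steps))

  kinetics <- stage("dwellstats", {
    out <- list()
    atps <- sort(unique(steps$atp))
    sp <- lapply(atps, function(a) {
      st <- steps[steps$atp == a, , drop = FALSE]
      dw <- dwells[dwells$atp == a, , drop = FALSE]
      up <- tryCatch(speeds(st, dw, "unwinding"), error = function(e) NULL)
      dn <- tryCatch(speeds(st, dw, "rezipping"), error = function(e) NULL)
      list(atp = a, unwinding = up, rezipping = dn)
    })
    out$speeds <- sp
    va <- vapply(sp, function(z) z$atp, numeric(1))
    vu <- vapply(sp, function(z)
      if (is.null(z$unwinding)) NA_real_ else z$unwinding$speed, numeric(1))
    vs <- vapply(sp, function(z)
      if (is.null(z$unwinding)) NA_real_ else z$unwinding$se, numeric(1))
    ok <- is.finite(vu)
    if (sum(ok) >= 3)
      out$mm_unwinding <- tryCatch(
        fit_michaelis_menten(va[ok], vu[ok], vs[ok]),
        error = function(e) NULL)
    nplus <- sum(dwells$class == "+/+")
    if (nplus >= config$boxcar_window) {
      curve <- dwell_vs_step(dwells, "+/+", config$boxcar_window)
      out$trend_dwell <- fit_trendline(curve$d, curve$t_mean, curve$t_se)
      nm <- (curve$t2_mean / curve$t_mean^2 - 1)^-1
      out$trend_nmin <- tryCatch(fit_trendline(curve$d, nm),
                                 error = function(e) NULL)
    }
    if (nplus >= 10)
      out$nmin_plus <- n_min(dwells$t[dwells$class == "+/+"])
    out
  })

  loop <- stage("loopmodel", {
    pmf <- step_pmf_from_release(release_distribution("3p"),
                                 release_distribution("5p"))
    up <- steps$s[steps$s > 0]
    list(pmf = pmf,
         mean_theory = pmf$mean, sd_theory = pmf$sd,
         mean_observed = if (length(up)) mean(up) else NA_real_,
         sd_observed = if (length(up) > 1) stats::sd(up) else NA_real_)
  })

  summary <- list(
    version = as.character(utils::packageVersion("helisteps")),
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    n_traces = length(traces),
    n_steps = nrow(steps),
    mean_unwinding_step_bp = stepstats$mean_unwinding,
    mean_rezipping_step_bp = stepstats$mean_rezipping,
    periodicity_bp = if (!is.null(stepstats$periodicity))
      stepstats$periodicity$spacing else NA_real_,
    double_gaussian = if (!is.null(stepstats$gaussians))
      list(means = stepstats$gaussians$means,
           sds = stepstats$gaussians$sds,
           weights = stepstats$gaussians$weights) else NULL,
    n_min_plus_plus = if (!is.null(kinetics$nmin_plus))
      kinetics$nmin_plus$n_min else NA_real_,
    michaelis_menten = if (!is.null(kinetics$mm_unwinding))
      list(Vmax = kinetics$mm_unwinding$Vmax,
           KM = kinetics$mm_unwinding$KM) else NULL,
    loop_model = list(mean_theory_bp = loop$mean_theory,
                      sd_theory_bp = loop$sd_theory,
                      mean_observed_bp = loop$mean_observed)
  )

  if (!is.null(config$out_dir)) {
    stage("output", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_steps(steps, file.path(config$out_dir, "steps.tsv"))
      utils::write.table(as.data.frame(dwells),
                         file.path(config$out_dir, "dwells.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_summary(summary, file.path(config$out_dir, "summary.json"))
    })
  }

  structure(list(steps = steps, dwells = dwells, stepstats = stepstats,
                 kinetics = kinetics, loop_model = loop, summary = summary,
                 config = config),
            class = "helisteps_run")
}

#' @export
print.helisteps_run <- function(x, ...) {
  s <- x$summary
  cat("helisteps pipeline run\n")
  cat(sprintf("  %d traces, %d steps (mean unwinding %.2f bp, re-zipping %.2f bp)\n",
              s$n_traces, s$n_steps, s$mean_unwinding_step_bp,
              s$mean_rezipping_step_bp))
  if (!is.null(s$michaelis_menten))
    cat(sprintf("  MM fit: Vmax %.3g bp/s, KM %.3g uM\n",
                s$michaelis_menten$Vmax, s$michaelis_menten$KM))
  if (!is.na(s$periodicity_bp))
    cat(sprintf("  KDE peak spacing: %.2f bp\n", s$periodicity_bp))
  invisible(x)
}
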