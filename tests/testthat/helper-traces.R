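# build an hp_trace from a raw position vector
make_trace <- function(x, rate = 100, force = 12, atp = 0.5, id = "fixture") {
  structure(data.frame(time = seq_along(x) / rate, position = x),
            class = c("hp_trace", "data.frame"),
            sample_rate = rate, force = force, atp = atp, id = id)
}

# noise-free (or noisy) staircase with given dwell lengths (samples) and
# step sizes (bp); returns trace plus true transition indices
make_staircase <- function(dwells, sizes, noise = 0, rate = 100, ...) {
  stopifnot(length(dwells) == length(sizes) + 1)
  pos <- rep(cumsum(c(0, sizes)), dwells)
  x <- pos + if (noise > 0) rnorm(length(pos), 0, noise) else 0
  list(trace = make_trace(x, rate = rate, ...),
       transitions = cumsum(dwells)[seq_along(sizes)] + 1L)
}

# step_records constructor for synthetic step sets
make_steps <- function(s, sigma_s = 0.1, atp = 0.5, force = 12,
                       id = "fixture") {
  n <- length(s)
  structure(data.frame(s = s, sigma_s = rep_len(sigma_s, n),
                       time = seq_len(n),
                       dwell_before = rep_len(1, n),
                       dwell_after = rep_len(1, n), position = cumsum(s),
                       trace_id = rep_len(id, n), force = rep_len(force, n),
                       atp = rep_len(atp, n)),
            class = c("step_records", "data.frame"))
}

# trapezoid integral used by density checks
trapz_test <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
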