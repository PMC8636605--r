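#' Write a trace to TSV with metadata header
#'
#' Format: '#'-prefixed \code{key = value} metadata lines (force_pN, atp_uM,
#' sample_rate_hz, id), then tab-separated columns \code{time_s},
#' \code{position_bp} with '.' decimal separator.
#'
#' @param trace An \code{"hp_trace"}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- function(a) attr(trace, a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# force_pN = %.10g", meta("force")),
    sprintf("# atp_uM = %.10g", meta("atp")),
    sprintf("# sample_rate_hz = %.10g", meta("sample_rate")),
    sprintf("# id = %s", meta("id")),
    "time_s\tposition_bp"), con)
  utils::write.table(
    data.frame(time_s = sprintf("%.10g", trace$time),
               position_bp = sprintf("%.10g", trace$position)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_meta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' Read a trace TSV written by \code{\link{write_trace}}
#'
#' Tolerates CRLF line endings. Missing required columns raise a named
#' error.
#'
#' @param path Input file.
#' @return An \code{"hp_trace"}.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta(lines[is_meta])
  body <- lines[!is_meta]
  hdr <- strsplit(body[1], "\t")[[1]]
  need <- c("time_s", "position_bp")
  if (!all(need %in% hdr))
    stop("missing required column(s): ",
         paste(setdiff(need, hdr), collapse = ", "))
  df <- utils::read.table(text = body[-1], sep = "\t",
                          col.names = hdr, colClasses = "numeric")
  num <- function(k, d = NA_real_) {
    v <- meta[[k]]; if (is.null(v)) d else as.numeric(v)
  }
  structure(
    data.frame(time = df$time_s, position = df$position_bp),
    class = c("hp_trace", "data.frame"),
    force = num("force_pN"), atp = num("atp_uM"),
    sample_rate = num("sample_rate_hz",
                      1 / stats::median(diff(df$time_s))),
    id = if (is.null(meta$id)) basename(path) else meta$id
  )
}

#' Write step records to TSV
#' @param steps A \code{"step_records"} data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_steps <- function(steps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_steps = %d", nrow(steps)), con)
  utils::write.table(as.data.frame(steps), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read step records written by \code{\link{write_steps}}
#' @param path Input file.
#' @return A \code{"step_records"} data frame.
#' @export
read_steps <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("s", "sigma_s")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  structure(df, class = c("step_records", "data.frame"))
}

#' Write an analysis summary as JSON
#' @param x A named list of results.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read and validate an analysis configuration
#'
#' Accepts a YAML file path or a ready-made list. Referenced trace files
#' must exist; validation happens before any computation.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(config$traces)) {
    missing <- config$traces[!file.exists(config$traces)]
    if (length(missing))
      stop("trace file(s) not found: ", paste(missing, collapse = ", "))
  } else if (is.null(config$simulate)) {
    stop("config needs either 'traces' (file paths) or a 'simulate' block")
  }
  if (is.null(config$detection)) config$detection <- list()
  if (is.null(config$detection$sensitivity)) config$detection$sensitivity <- 5
  if (is.null(config$boxcar_window)) config$boxcar_window <- 35
  if (config$boxcar_window < 25 || config$boxcar_window > 45)
    stop("'boxcar_window' must lie in [25, 45]")
  if (is.null(config$n_boot)) config$n_boot <- 2000
  config
}

# tiny rolling hash so outputs can embed a config fingerprint without extra deps
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
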