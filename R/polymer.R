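#' Polymer elasticity parameters for dsDNA handles and released ssDNA
#'
#' Defaults are the extensible worm-like chain (XWLC) constants for the
#' hairpin assay: persistence lengths \eqn{P_{ds} = 53} nm and
#' \eqn{P_{ss} = 1} nm, inter-phosphate distances \eqn{h_{ds} = 0.34} nm/bp
#' and \eqn{h_{ss} = 0.59} nm/nt, stretch moduli \eqn{S_{ds} = 1100} pN and
#' \eqn{S_{ss} = 1000} pN, at 22 degrees C.
#'
#' @param P_ds,P_ss Persistence lengths (nm).
#' @param h_ds,h_ss Contour length per monomer (nm per bp / nm per nt).
#' @param S_ds,S_ss Stretch moduli (pN).
#' @param temperature Temperature (K).
#' @return An object of class \code{"polymer_params"}; \code{kT} (pN nm) is
#'   derived from the temperature.
#' @export
polymer_params <- function(P_ds = 53, P_ss = 1, h_ds = 0.34, h_ss = 0.59,
                           S_ds = 1100, S_ss = 1000, temperature = 295.15) {
  vals <- c(P_ds, P_ss, h_ds, h_ss, S_ds, S_ss, temperature)
  if (any(vals <= 0)) stop("all polymer parameters must be positive")
  structure(list(P_ds = P_ds, P_ss = P_ss, h_ds = h_ds, h_ss = h_ss,
                 S_ds = S_ds, S_ss = S_ss, temperature = temperature,
                 kT = 1.380649e-2 * temperature),   # pN nm
            class = "polymer_params")
}

#' Extensible worm-like chain extension per monomer
#'
#' High-force Odijk interpolation
#' \deqn{x(F) = h \left(1 - \frac{1}{2}\sqrt{kT/(F P)} + F/S\right),}
#' returning the extension per base pair (\code{kind = "ds"}) or per
#' nucleotide (\code{kind = "ss"}) at force \code{F}.
#'
#' @param force Force (pN), positive (vectorized).
#' @param params A \code{\link{polymer_params}}.
#' @param kind \code{"ss"} or \code{"ds"}.
#' @return Extension in nm per nt (ss) or per bp (ds). The interpolation is
#'   a high-force expansion; below the force where it would turn negative
#'   (about 1 pN for ssDNA) the extension is clamped at zero.
#' @export
xwlc_extension <- function(force, params = polymer_params(),
                           kind = c("ss", "ds")) {
  kind <- match.arg(kind)
  if (any(force <= 0)) stop("'force' must be positive")
  P <- if (kind == "ss") params$P_ss else params$P_ds
  S <- if (kind == "ss") params$S_ss else params$S_ds
  h <- if (kind == "ss") params$h_ss else params$h_ds
  pmax(0, h * (1 - 0.5 * sqrt(params$kT / (force * P)) + force / S))
}

#' Convert an extension change to base pairs unwound
#'
#' Unwinding one base pair releases two nucleotides of ssDNA, so the change
#' in extension (nm) at force \code{F} is divided by twice the ssDNA XWLC
#' extension per nucleotide.
#'
#' @param delta_x Extension change (nm); sign is preserved.
#' @param force Force (pN).
#' @param params A \code{\link{polymer_params}}.
#' @return Base pairs unwound.
#' @export
delta_x_to_bp <- function(delta_x, force, params = polymer_params()) {
  x <- xwlc_extension(force, params, "ss")
  if (any(x == 0))
    stop("force below the validity range of the ssDNA extension model")
  delta_x / (2 * x)
}

#' Forward conversion: base pairs unwound to extension change (nm)
#' @inheritParams delta_x_to_bp
#' @param bp Base pairs unwound.
#' @return Extension change in nm.
#' @export
bp_to_delta_x <- function(bp, force, params = polymer_params()) {
  bp * 2 * xwlc_extension(force, params, "ss")
}

#' Stretching free energy of released ssDNA
#'
#' The free-energy credit for releasing one nucleotide of ssDNA at force
#' \eqn{F}, \eqn{\int_0^F x_{ss}(F')\,dF'}, in units of kT per nt, using the
#' clamped XWLC extension (zero below its validity threshold), so the
#' result is non-negative and increasing. The integral has a closed form;
#' only the clamping threshold is found numerically.
#'
#' @param force Force (pN), positive (vectorized).
#' @param params A \code{\link{polymer_params}}.
#' @return Free energy in kT per nucleotide.
#' @export
ss_stretch_free_energy <- function(force, params = polymer_params()) {
  if (any(force <= 0)) stop("'force' must be positive")
  h <- params$h_ss; P <- params$P_ss; S <- params$S_ss; kT <- params$kT
  anti <- function(f) h * (f - sqrt(kT / P) * sqrt(f) + f^2 / (2 * S)) / kT
  # force below which the interpolated extension is clamped to zero
  ext <- function(f) 1 - 0.5 * sqrt(kT / (f * P)) + f / S
  f0 <- if (ext(1e-12) >= 0) 0 else
    stats::uniroot(ext, c(1e-12, 100), tol = 1e-12)$root
  vapply(force, function(f)
    if (f <= f0) 0 else anti(f) - anti(f0), numeric(1))
}

# ---- hairpin nearest-neighbor thermodynamics --------------------------------

#' Unified nearest-neighbor DNA parameter table
#'
#' Reads the packaged table of nearest-neighbor stacking enthalpies and
#' entropies (kcal/mol and cal/mol/K at 1 M NaCl) for the 16 dinucleotide
#' stacks plus duplex initiation terms.
#'
#' @return Data frame with columns \code{stack}, \code{dH_kcal},
#'   \code{dS_cal}.
#' @export
nn_table <- function() {
  path <- system.file("extdata", "nn_unified.tsv", package = "helisteps")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Hairpin model: sequence, per-bp opening free energies
#'
#' Builds the thermodynamic model of a hairpin stem: for each stem position
#' (1-based from the fork toward the loop) the free-energy cost (kT) of
#' opening that base pair, from nearest-neighbor stacking parameters with a
#' logarithmic monovalent-salt entropy correction
#' (\eqn{\Delta S + 0.368 \ln[Na^+]} cal/mol/K per stack). The stack
#' spanning bps \eqn{i, i+1} is assigned to position \eqn{i}; the final stem
#' position carries the duplex initiation term. The tetraloop is treated as
#' a fixed cap excluded from opening sums.
#'
#' @param stem Stem sequence, 5' to 3', one strand (character scalar,
#'   A/C/G/T).
#' @param loop Tetraloop sequence (metadata only).
#' @param na_molar Monovalent salt concentration (mol/L).
#' @param temperature Temperature (K).
#' @param dg_open_kT Optional explicit per-bp opening costs (kT), overriding
#'   the sequence-derived values (used for toy stems).
#' @return Object of class \code{"hairpin_model"} with fields \code{stem},
#'   \code{loop}, \code{dg_open_kT} (length = stem length).
#' @export
hairpin_model <- function(stem, loop = "TTTT", na_molar = 0.055,
                          temperature = 295.15, dg_open_kT = NULL) {
  stem <- toupper(stem)
  bases <- strsplit(stem, "")[[1]]
  L <- length(bases)
  if (L < 1) stop("stem length must be >= 1")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("stem must contain only A/C/G/T")
  if (is.null(dg_open_kT)) {
    tb <- nn_table()
    dH <- stats::setNames(tb$dH_kcal, tb$stack)
    dS <- stats::setNames(tb$dS_cal, tb$stack)
    kT_kcal <- 1.9872e-3 * temperature
    dg_stack <- function(key) {
      if (is.na(dH[key])) stop(sprintf("no NN entry for stack '%s'", key))
      ds <- dS[key] + 0.368 * log(na_molar)   # salt correction per stack
      dH[key] - temperature * ds / 1000
    }
    dg <- numeric(L)
    if (L > 1) {
      for (i in seq_len(L - 1)) {
        key <- paste0(bases[i], bases[i + 1])
        dg[i] <- -dg_stack(key) / kT_kcal     # cost of opening = -stack dG
      }
    }
    init_key <- if (bases[L] %in% c("G", "C")) "init_GC" else "init_AT"
    dg[L] <- -(dH[init_key] - temperature * dS[init_key] / 1000) / kT_kcal
    dg_open_kT <- dg
  } else {
    if (length(dg_open_kT) != L)
      stop("'dg_open_kT' must have one entry per stem position")
  }
  structure(list(stem = stem, loop = loop, length = L,
                 dg_open_kT = dg_open_kT, na_molar = na_molar,
                 temperature = temperature),
            class = "hairpin_model")
}

#' Read a hairpin stem from a FASTA file
#'
#' The first record's sequence is the stem strand (5' to 3'); if the
#' description line contains \code{loop=XXXX} that loop sequence is used.
#'
#' @param path FASTA file path.
#' @param ... Passed to \code{\link{hairpin_model}}.
#' @return A \code{"hairpin_model"}.
#' @export
read_hairpin_fasta <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA record in ", path)
  end <- if (length(hdr) > 1) hdr[2] - 1 else length(lines)
  seq <- paste(lines[(hdr[1] + 1):end], collapse = "")
  loop <- regmatches(lines[hdr[1]],
                     regexpr("loop=[ACGTacgt]+", lines[hdr[1]]))
  loop <- if (length(loop)) toupper(sub("loop=", "", loop)) else "TTTT"
  hairpin_model(seq, loop = loop, ...)
}

#' @export
print.hairpin_model <- function(x, ...) {
  cat(sprintf("Hairpin: %d-bp stem + %s tetraloop, [Na+] %g M, %g K\n",
              x$length, x$loop, x$na_molar, x$temperature))
  cat(sprintf("  per-bp opening cost: %.2f-%.2f kT (mean %.2f)\n",
              min(x$dg_open_kT), max(x$dg_open_kT), mean(x$dg_open_kT)))
  invisible(x)
}

#' Probability that base pairs downstream of a stem position open thermally
#'
#' Equilibrium probability that one or more base pairs beyond position
#' \code{n} are open at force \code{F}:
#' \deqn{P_{open}(n,F) = \frac{\sum_{m\ge1} e^{-\Delta G(m)}}{\sum_{m\ge0} e^{-\Delta G(m)}},\quad
#'   \Delta G(m) = \sum_{j=n}^{n+m-1} \Delta G_{bp}(j) - 2m\,\Delta G_{stretch}(F),}
#' in kT, where opening one bp releases 2 nt of stretched ssDNA. The sum
#' runs over the full remaining stem; full unfolding past the tetraloop is
#' excluded.
#'
#' @param hairpin A \code{\link{hairpin_model}}.
#' @param n Stem position (1-based from the fork); bp \code{n} is the first
#'   that can open.
#' @param force Force (pN).
#' @param params A \code{\link{polymer_params}}.
#' @return Probability in [0, 1] (vectorized over \code{n}).
#' @export
p_open <- function(hairpin, n, force, params = polymer_params()) {
  stopifnot(inherits(hairpin, "hairpin_model"))
  if (any(n < 1) || any(n > hairpin$length)) stop("'n' out of range")
  gs <- ss_stretch_free_energy(force, params)
  vapply(n, function(ni) {
    p_open_core(hairpin$dg_open_kT[ni:hairpin$length], gs)
  }, numeric(1))
}

#' Opening probability from explicit per-bp costs
#'
#' Workhorse behind \code{\link{p_open}}: given the per-bp opening costs (kT)
#' of the remaining stem and the per-nucleotide stretching credit (kT/nt),
#' returns the probability that at least one bp is open.
#'
#' @param dg_open_kT Per-bp opening free energies (kT), fork-proximal first.
#' @param dg_stretch_kT_per_nt Stretching free energy credit per released nt.
#' @return Probability in [0, 1].
#' @export
p_open_core <- function(dg_open_kT, dg_stretch_kT_per_nt) {
  m <- seq_along(dg_open_kT)
  dG <- cumsum(dg_open_kT) - 2 * m * dg_stretch_kT_per_nt
  lw <- c(0, -dG)                     # m = 0 state has dG = 0
  lmax <- max(lw)
  w <- exp(lw - lmax)
  sum(w[-1]) / sum(w)
}

#' Predicted force-extension branches for a hairpin construct
#'
#' Folded branch: dsDNA handles only; unfolded branch adds the ssDNA of the
#' fully opened stem (2 nt/bp) plus the loop. Used for fixture validation.
#'
#' @param hairpin A \code{\link{hairpin_model}}.
#' @param params A \code{\link{polymer_params}}.
#' @param force_grid Positive ascending forces (pN).
#' @param handles_bp Total handle length (bp).
#' @return Data frame \code{force}, \code{ext_folded}, \code{ext_unfolded}
#'   (nm).
#' @export
fec_predict <- function(hairpin, params = polymer_params(),
                        force_grid = seq(1, 20, by = 0.25),
                        handles_bp = 3000) {
  if (any(diff(force_grid) <= 0) || any(force_grid <= 0))
    stop("'force_grid' must be positive ascending")
  xds <- xwlc_extension(force_grid, params, "ds")
  xss <- xwlc_extension(force_grid, params, "ss")
  nt_unfolded <- 2 * hairpin$length + nchar(hairpin$loop)
  data.frame(force = force_grid,
             ext_folded = handles_bp * xds,
             ext_unfolded = handles_bp * xds + nt_unfolded * xss)
}
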