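#' Instrument and correction constants for a FRET experiment
#'
#' Bundles the quantities shared by burst analysis and photon simulation:
#' the Forster radius of the dye pair, the gamma detection/quantum-yield
#' correction, background count rates, donor-to-acceptor spectral
#' crosstalk, acceptor direct excitation, and the intrinsic donor
#' lifetime. Defaults are neutral (no corrections) with `r0 = 5.4` nm,
#' a typical value for the Alexa 488/594 pair.
#'
#' @param r0 Forster radius in nm. Must be positive.
#' @param gamma Detection-efficiency/quantum-yield correction factor
#'   applied to donor counts. Must be positive; 1 means balanced channels.
#' @param bg_donor,bg_acceptor Background count rates (Hz) in the donor
#'   and acceptor channels under donor excitation.
#' @param crosstalk Fraction of donor photons detected in the acceptor
#'   channel, in `[0, 1)`.
#' @param direct_excitation Fraction of acceptor-excitation signal leaking
#'   into donor-excitation acceptor counts, in `[0, 1)`.
#' @param donor_lifetime_ns Intrinsic donor fluorescence lifetime (ns),
#'   used by lifetime diagnostics.
#'
#' @return An object of class `fret_setup` (a named list).
#' @examples
#' fret_setup()
#' fret_setup(r0 = 5.4, gamma = 1.1, bg_donor = 800, bg_acceptor = 400)
#' @export
fret_setup <- function(r0 = 5.4, gamma = 1,
                       bg_donor = 0, bg_acceptor = 0,
                       crosstalk = 0, direct_excitation = 0,
                       donor_lifetime_ns = 4) {
  stopifnot(is.numeric(r0), length(r0) == 1, is.finite(r0))
  if (r0 <= 0) abort("`r0` must be positive.")
  if (gamma <= 0) abort("`gamma` must be positive.")
  if (bg_donor < 0 || bg_acceptor < 0) abort("background rates must be >= 0.")
  if (crosstalk < 0 || crosstalk >= 1) abort("`crosstalk` must be in [0, 1).")
  if (direct_excitation < 0 || direct_excitation >= 1) {
    abort("`direct_excitation` must be in [0, 1).")
  }
  structure(
    list(
      r0 = r0, gamma = gamma,
      bg_donor = bg_donor, bg_acceptor = bg_acceptor,
      crosstalk = crosstalk, direct_excitation = direct_excitation,
      donor_lifetime_ns = donor_lifetime_ns
    ),
    class = "fret_setup"
  )
}

#' @export
print.fret_setup <- function(x, ...) {
  cat("<fret_setup>\n")
  cat(sprintf("  R0: %.2f nm, gamma: %.3f\n", x$r0, x$gamma))
  cat(sprintf("  background D/A: %.0f / %.0f Hz\n", x$bg_donor, x$bg_acceptor))
  cat(sprintf("  crosstalk: %.3f, direct excitation: %.3f\n",
              x$crosstalk, x$direct_excitation))
  cat(sprintf("  donor lifetime: %.2f ns\n", x$donor_lifetime_ns))
  invisible(x)
}

is_fret_setup <- function(x) inherits(x, "fret_setup")

as_fret_setup <- function(x) {
  if (is_fret_setup(x)) return(x)
  if (is.list(x)) return(do.call(fret_setup, x))
  abort("expected a `fret_setup` object or a named list of its fields.")
}
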