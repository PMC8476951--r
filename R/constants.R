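#' Mass difference between 13C and 12C
#'
#' Monoisotopic mass difference between carbon-13 and carbon-12, in Da.
#' A ring-\eqn{{}^{13}C_6} labeled phenyl ring shifts a feature's m/z by
#' 6 times this constant (about 6.0201 Th for a singly charged ion).
#'
#' @format A length-one numeric.
#' @export
C13C12_MASS_DIFF <- 1.0033548

# monoisotopic atomic masses (Da) and the proton mass used for [M-H]- ions
.ATOM <- c(
  H = 1.00782503207,
  C = 12.0,
  C13 = 13.00335483507,
  N = 14.0030740048,
  O = 15.9949146196
)
.PROTON <- 1.00727646688

#' Predicted m/z of a ring-labeled isotopologue
#'
#' Shifts an unlabeled feature m/z by \code{n} fully ring-labeled
#' \eqn{{}^{13}C_6} phenyl rings (n * 6 * \code{\link{C13C12_MASS_DIFF}}).
#'
#' @param mz Numeric vector of unlabeled (M-H) m/z values, in Th.
#' @param n Integer number of labeled rings (1-3).
#' @return Numeric vector of predicted labeled m/z values.
#' @examples
#' ringShiftMz(310.0935, 1)  # dhurrin +6 isotopologue, ~316.114
#' @export
ringShiftMz <- function(mz, n = 1L) {
  stopifnot(is.numeric(mz), all(is.finite(mz)), n >= 1)
  mz + n * 6 * C13C12_MASS_DIFF
}

#' M-H masses of the fed amino-acid precursors
#'
#' Negative-mode (M-H) m/z values of phenylalanine (C9H11NO2), tyrosine
#' (C9H11NO3) and their ring-\eqn{{}^{13}C_6} isotopologues, computed from
#' monoisotopic atomic masses. These are the default exclusion masses for
#' \code{\link{excludeFedPrecursors}}: the fed substrates themselves are
#' removed before any downstream labeling analysis.
#'
#' @return Named numeric vector of four m/z values.
#' @examples
#' fedPrecursorMasses()
#' @export
fedPrecursorMasses <- function() {
  a <- .ATOM
  phe <- 9 * a[["C"]] + 11 * a[["H"]] + a[["N"]] + 2 * a[["O"]]
  tyr <- 9 * a[["C"]] + 11 * a[["H"]] + a[["N"]] + 3 * a[["O"]]
  ring6 <- 6 * (a[["C13"]] - a[["C"]])
  out <- c(
    Phe = phe - .PROTON,
    Tyr = tyr - .PROTON,
    Phe_13C6 = phe + ring6 - .PROTON,
    Tyr_13C6 = tyr + ring6 - .PROTON
  )
  out
}

# ppm distance between two m/z values, relative to the reference mass
.ppm <- function(mz, ref) abs(mz - ref) / ref * 1e6
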