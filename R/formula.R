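#' Standard atomic masses
#'
#' Conventional atomic weights (IUPAC 2021) for the elements that occur in
#' metabolite formulas of genome-scale reconstructions. The pseudo-element
#' \code{"R"} (undetermined acyl chain or generic residue) is not listed
#' here; its mass is supplied per call (see [formula_weight()]).
#'
#' @format Named numeric vector, g/mol.
#' @keywords internal
ATOMIC_MASSES <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403162, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, K = 39.0983, Ar = 39.95,
  Ca = 40.078, Cr = 51.9961, Mn = 54.938043, Fe = 55.845, Co = 58.933194,
  Ni = 58.6934, Cu = 63.546, Zn = 65.38, As = 74.921595, Se = 78.971,
  Br = 79.904, Mo = 95.95, Ag = 107.8682, Cd = 112.414, Sn = 118.71,
  I = 126.90447, W = 183.84, Hg = 200.592
)

#' Molecular weight of a chemical formula
#'
#' Parses a Hill-style formula string (e.g. \code{"C10H12N5O13P3"}) and sums
#' standard atomic masses. Formulas of generic lipids may carry the
#' pseudo-element \code{"R"} standing in for an acyl chain of unknown
#' length; each occurrence contributes \code{r_mass} g/mol. When a formula
#' contains \code{"R"} and no \code{r_mass} is given the weight is reported
#' as unresolved (\code{NA}) rather than silently guessed.
#'
#' @param formula Character vector of formula strings. \code{NA} or empty
#'   strings yield \code{NA} weights.
#' @param r_mass Mass in g/mol contributed by each \code{"R"} pseudo-element,
#'   or \code{NA} (default) to leave such formulas unresolved.
#' @return Numeric vector of weights in g/mol; \code{NA} where unresolved.
#' @examples
#' formula_weight("H2O")
#' formula_weight("C2H3RO2", r_mass = 100)
#' @export
formula_weight <- function(formula, r_mass = NA_real_) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(f)) {
      stop("cannot parse chemical formula: '", f, "'", call. = FALSE)
    }
    w <- 0
    for (tok in toks) {
      el <- sub("[0-9.]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      m <- if (el == "R") r_mass else unname(ATOMIC_MASSES[el])
      if (el != "R" && is.na(m)) {
        stop("unknown element '", el, "' in formula '", f, "'",
             call. = FALSE)
      }
      w <- w + n * m
    }
    unname(w)
  }, numeric(1), USE.NAMES = FALSE)
}
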