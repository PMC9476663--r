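# Covalent radii (Angstrom), single-bond values from Cordero et al. 2008.
# One value per element: sp3 value for carbon; high-spin values for Mn/Fe/Co.
.cordero <- c(
  H  = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B  = 0.84, C  = 0.76, N  = 0.71, O  = 0.66,
  F  = 0.57, Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P  = 1.07, S  = 1.05,
  Cl = 1.02, Ar = 1.06,
  K  = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V  = 1.53, Cr = 1.39,
  Mn = 1.61, Fe = 1.52, Co = 1.50, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  I  = 1.39
)

#' Covalent radius table
#'
#' Single-bond covalent radii in Angstrom (Cordero et al. 2008 compilation;
#' one value per element, the sp3 value for carbon and high-spin values for
#' Mn, Fe, Co). These radii drive bond perception, the DCRR nonbonded
#' cutoff and cap-hydrogen placement. The table is immutable during a run.
#'
#' @return named numeric vector, element symbol to radius (Angstrom).
#' @seealso [covalentRadius()]
#' @examples
#' corderoRadii()[["C"]]  # 0.76
#' @export
corderoRadii <- function() .cordero

#' Look up a covalent radius
#'
#' @param element element symbol (e.g. \code{"C"}).
#' @param table named radius vector; defaults to [corderoRadii()].
#' @return covalent radius in Angstrom.
#' @examples
#' covalentRadius("H")  # 0.31
#' @export
covalentRadius <- function(element, table = corderoRadii()) {
  stopifnot(is.character(element))
  r <- table[element]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(element[is.na(r)], collapse = ", "),
         "; supported symbols: ", paste(names(table), collapse = " "))
  unname(r)
}
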