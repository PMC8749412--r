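## Elemental mass tables and formula arithmetic.
##
## Monoisotopic masses are those of the principal isotope (CODATA/IUPAC);
## nominal masses are the integer mass numbers. Precision well below the
## 1e-4 Da tolerance used by the residue-registry validity checks.

.MONO <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

.NOMINAL <- c(H = 1L, C = 12L, N = 14L, O = 16L, S = 32L, P = 31L)

## Mass of the proton used for m/z arithmetic; the electron mass is
## neglected (quadrupole-scale precision).
.PROTON <- 1.00728

## Acetyl modification: +C2H2O on a primary amine.
.ACETYL_MONO <- 2 * .MONO[["C"]] + 2 * .MONO[["H"]] + .MONO[["O"]]
.ACETYL_NOMINAL <- 42L

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as \code{"C4H8N2O2"} into a
#' named integer vector of element counts. Only elements with tabulated
#' masses (C, H, N, O, S, P) are accepted.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C4H8N2O2")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty string")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("unparseable formula: '", formula, "'")
  }
  el <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Za-z]+", "", tokens)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  bad <- setdiff(el, names(.MONO))
  if (length(bad)) {
    stop("unparseable formula: '", formula, "' (unknown element: ",
         paste(bad, collapse = ", "), ")")
  }
  counts <- stats::setNames(integer(length(.MONO)), names(.MONO))
  for (i in seq_along(el)) counts[el[i]] <- counts[el[i]] + n[i]
  counts[counts > 0L]
}

#' Mass of an elemental formula
#'
#' @param formula Formula string (see [parseFormula()]).
#' @param mode `"monoisotopic"` (default) or `"nominal"`.
#' @return Mass in Da (numeric for monoisotopic, integer-valued for nominal).
#' @examples
#' formulaMass("C4H8N2O2")            # Dab(bOH) residue
#' formulaMass("C4H12N2", "nominal")  # the free Dbt diamine, 88 Da
#' @export
formulaMass <- function(formula, mode = c("monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  counts <- parseFormula(formula)
  tab <- if (mode == "monoisotopic") .MONO else .NOMINAL
  sum(tab[names(counts)] * counts)
}

#' Constants used by the mass calculus
#'
#' Returns the proton mass and acetyl-group masses used throughout the
#' package (monoisotopic acetyl 42.0106 Da, nominal 42 Da; proton
#' 1.00728 Da).
#'
#' @return Named list with `proton`, `acetyl_mono`, `acetyl_nominal`.
#' @export
massConstants <- function() {
  list(proton = .PROTON, acetyl_mono = .ACETYL_MONO,
       acetyl_nominal = .ACETYL_NOMINAL)
}
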