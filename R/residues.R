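#' @include atoms.R AllClasses.R
NULL

## Package-level residue registry. Populated from the shipped residue
## table at load time; user additions go through registerResidue().
.registry <- new.env(parent = emptyenv())

.emptyRegistry <- function() {
  data.frame(code = character(), name = character(), formula = character(),
             amine_sites = character(), mono = numeric(),
             nominal = integer(), stringsAsFactors = FALSE)
}

#' Read a residue-chemistry table
#'
#' Reads a tab-delimited residue table with columns `code`, `name`,
#' `formula` and `amine_sites` (comma-separated primary-amine labels, may
#' be empty; `alpha` marks the backbone amine, free only at position 1).
#' Monoisotopic and nominal residue masses are derived from the formula.
#' If the file carries a `mono` column, each value is checked against the
#' formula sum to within 1e-4 Da.
#'
#' @param path Path to the table.
#' @return A registry `data.frame` (code, name, formula, amine_sites,
#'   mono, nominal).
#' @export
readResidueTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("code", "name", "formula", "amine_sites")
  if (!all(need %in% names(tab)))
    stop("residue table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$code))
    stop("duplicate residue code in table: ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "))
  tab$amine_sites[is.na(tab$amine_sites)] <- ""
  mono <- vapply(tab$formula, formulaMass, numeric(1), mode = "monoisotopic")
  nominal <- vapply(tab$formula, formulaMass, numeric(1), mode = "nominal")
  if ("mono" %in% names(tab)) {
    supplied <- as.numeric(tab$mono)
    off <- which(!is.na(supplied) & abs(supplied - mono) > 1e-4)
    if (length(off))
      stop("supplied monoisotopic mass disagrees with formula for: ",
           paste(tab$code[off], collapse = ", "))
  }
  data.frame(code = tab$code, name = tab$name, formula = tab$formula,
             amine_sites = tab$amine_sites, mono = unname(mono),
             nominal = as.integer(nominal), stringsAsFactors = FALSE)
}

#' The active residue registry
#'
#' @return The registry `data.frame` currently in force.
#' @export
residueRegistry <- function() {
  if (is.null(.registry$table)) .registry$table <- .emptyRegistry()
  .registry$table
}

#' Register a residue
#'
#' Adds a residue to the active registry. Masses are derived from the
#' elemental formula; a supplied monoisotopic mass is cross-checked
#' against the formula sum (1e-4 Da tolerance).
#'
#' @param code Short unique residue token, e.g. `"Dab(bOH)"`.
#' @param name Full residue name.
#' @param formula Elemental composition of the residue as incorporated in
#'   the chain (amino acid minus water), e.g. `"C4H8N2O2"`.
#' @param amineSites Character vector of primary-amine site labels
#'   (`"alpha"`, `"epsilon"`, `"gamma"`, `"delta"`, ...). Empty if the
#'   residue offers no acetylatable primary amine.
#' @param mono Optional monoisotopic mass to validate against the formula.
#' @return Invisibly, the new registry row.
#' @examples
#' \dontrun{registerResidue("Hse", "Homoserine", "C4H7NO2", "alpha")}
#' @export
registerResidue <- function(code, name, formula, amineSites = character(),
                            mono = NULL) {
  reg <- residueRegistry()
  if (code %in% reg$code) stop("residue code already registered: ", code)
  m <- formulaMass(formula, "monoisotopic")
  if (!is.null(mono) && abs(mono - m) > 1e-4)
    stop("supplied monoisotopic mass ", mono,
         " disagrees with formula sum ", round(m, 5))
  row <- data.frame(code = code, name = name, formula = formula,
                    amine_sites = paste(amineSites, collapse = ","),
                    mono = m,
                    nominal = as.integer(formulaMass(formula, "nominal")),
                    stringsAsFactors = FALSE)
  .registry$table <- rbind(reg, row)
  invisible(row)
}

#' Look up a residue by code
#'
#' @param code Residue token.
#' @return A one-row registry `data.frame`.
#' @export
residueSpec <- function(code) {
  reg <- residueRegistry()
  i <- match(code, reg$code)
  if (is.na(i)) stop("unknown residue code: '", code, "'")
  reg[i, , drop = FALSE]
}

#' Reset the registry to the shipped residue table
#'
#' Reloads the residue table distributed with the package (the
#' odilorhabdin residues plus the 20 proteinogenic amino acids), dropping
#' any session additions.
#'
#' @param path Optional path to an alternative residue table.
#' @return Invisibly, the registry `data.frame`.
#' @export
resetResidueRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residues.tsv", package = "odltools",
                        mustWork = TRUE)
  .registry$table <- readResidueTable(path)
  invisible(.registry$table)
}

.residueAmineLabels <- function(row) {
  s <- row$amine_sites
  if (!nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
}
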