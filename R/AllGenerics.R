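#' @include AllClasses.R
NULL

#' Accessors for odltools classes
#'
#' Small accessor generics: `peptideName()`, `residues()`, `cterm()`,
#' `nResidues()`, `acetylSites()`, `acetylCount()`, `ions()`, `peaks()`,
#' `precursorMz()` and `precursorCharge()` read the corresponding parts of
#' [OdlPeptide-class], [AcetylConfig-class], [TheoreticalSpectrum-class]
#' and [ObservedSpectrum-class] objects.
#'
#' @param x An odltools object.
#' @return The slot contents (a `data.frame`, scalar, or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptideName", function(x) standardGeneric("peptideName"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("cterm", function(x) standardGeneric("cterm"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("acetylSites", function(x) standardGeneric("acetylSites"))
#' @rdname accessors
#' @export
setGeneric("acetylCount", function(x) standardGeneric("acetylCount"))
#' @rdname accessors
#' @export
setGeneric("ions", function(x) standardGeneric("ions"))
#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname accessors
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

setMethod("peptideName", "OdlPeptide", function(x) x@name)
setMethod("residues", "OdlPeptide", function(x) x@residues)
setMethod("cterm", "OdlPeptide", function(x) x@cterm)
setMethod("nResidues", "OdlPeptide", function(x) nrow(x@residues))
setMethod("acetylSites", "AcetylConfig", function(x) x@sites)
setMethod("acetylCount", "AcetylConfig", function(x) nrow(x@sites))
setMethod("ions", "TheoreticalSpectrum", function(x) x@ions)
setMethod("peaks", "ObservedSpectrum", function(x) x@peaks)
setMethod("precursorMz", "ObservedSpectrum", function(x) x@precursorMz)
setMethod("precursorCharge", "ObservedSpectrum", function(x) x@precursorCharge)

setMethod("show", "OdlPeptide", function(object) {
  cat("OdlPeptide:", object@name, "\n")
  cat(" ", paste(object@residues$code, collapse = "-"),
      if (object@cterm == "dbt-amide") "-Dbt (C-terminal amide)"
      else "(free acid)", "\n")
  cat("  residues:", nrow(object@residues),
      " neutral monoisotopic mass:",
      sprintf("%.4f Da\n", neutralMass(object)))
})

setMethod("show", "AcetylConfig", function(object) {
  k <- nrow(object@sites)
  cat("AcetylConfig: k =", k, "\n")
  if (k) cat(" ", paste0(object@sites$position, "(", object@sites$label, ")",
                         collapse = ", "), "\n")
})

setMethod("show", "TheoreticalSpectrum", function(object) {
  cat("TheoreticalSpectrum:", nrow(object@ions), "ions for",
      object@peptide@name, "(k =", nrow(object@config@sites), ")\n")
  if (nrow(object@ions))
    cat("  m/z range:", sprintf("%.2f", min(object@ions$mz)), "-",
        sprintf("%.2f", max(object@ions$mz)), "\n")
})

setMethod("show", "ObservedSpectrum", function(object) {
  cat("ObservedSpectrum:", nrow(object@peaks), "peaks")
  if (!is.na(object@precursorMz))
    cat(", precursor m/z", object@precursorMz,
        if (!is.na(object@precursorCharge))
          paste0("(", object@precursorCharge, "+)") else "")
  cat("\n")
})
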