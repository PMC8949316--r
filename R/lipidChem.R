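#' Elemental formula of a sum-composition lipid species
#'
#' Computes the neutral-molecule elemental formula for a lipid species given
#' only its class, total chain carbons and total chain double bonds (the "sum
#' composition" shorthand, e.g. PI 38:4). No chain-level (sn-1/sn-2) isomer is
#' assumed: the formula depends on the totals only. For the PE plasmalogen
#' class (`PE_P`) the formula reflects the 1-O-alk-1'-enyl vinyl-ether linkage
#' (one oxygen fewer than the diacyl species with the same listed double-bond
#' count; the ether linkage gains 2 H and the vinyl double bond, which is not
#' counted in the shorthand, removes them again). For sphingolipids the
#' formula depends on the sphingoid-base hydroxylation (`"d"` di-, `"t"`
#' tri-hydroxy).
#'
#' @param class Lipid class, one of [lipidClasses()].
#' @param carbons Total acyl/alkenyl chain carbons (integer).
#' @param doubleBonds Total chain C=C count (excluding the plasmalogen vinyl
#'   ether, which is tracked by the class).
#' @param hydroxylation `"none"`, `"d"` or `"t"`; `"d"`/`"t"` are valid only
#'   for sphingolipid classes (SM, Sulf, HexCer, Cer), `"none"` only for
#'   glycerolipids and glycerophospholipids.
#' @return Named integer vector over elements C, H, O, N, P, S.
#' @export
#' @examples
#' lipidFormula("PI", 38, 4)            # C47 H83 O13 P
#' lipidFormula("SM", 36, 1, "d")
lipidFormula <- function(class, carbons, doubleBonds, hydroxylation = "none") {
  class <- match.arg(class, LIPID_CLASS_TABLE$class)
  info <- LIPID_CLASS_TABLE[LIPID_CLASS_TABLE$class == class, ]
  carbons <- as.integer(carbons)
  doubleBonds <- as.integer(doubleBonds)
  if (is.na(carbons) || is.na(doubleBonds))
    stop("carbons and doubleBonds must be integers")
  if (info$sphingoid) {
    if (!hydroxylation %in% c("d", "t"))
      stop("unsupported species: sphingolipid class ", class,
           " requires hydroxylation 'd' or 't'")
  } else {
    if (hydroxylation != "none")
      stop("unsupported species: hydroxylation '", hydroxylation,
           "' is not defined for class ", class)
  }
  if (carbons < info$min_carbons)
    stop("unsupported species: ", class, " ", carbons, ":", doubleBonds,
         " has fewer than ", info$min_carbons, " chain carbons")
  if (doubleBonds < 0 || doubleBonds > carbons / 2)
    stop("unsupported species: double bonds out of range for ",
         class, " ", carbons, ":", doubleBonds)

  n <- carbons; d <- doubleBonds
  f <- switch(class,
    PC     = c(C = n + 8, H = 2 * n - 2 * d + 16, O = 8,  N = 1, P = 1, S = 0),
    PE     = c(C = n + 5, H = 2 * n - 2 * d + 10, O = 8,  N = 1, P = 1, S = 0),
    PE_P   = c(C = n + 5, H = 2 * n - 2 * d + 10, O = 7,  N = 1, P = 1, S = 0),
    PS     = c(C = n + 6, H = 2 * n - 2 * d + 10, O = 10, N = 1, P = 1, S = 0),
    PG     = c(C = n + 6, H = 2 * n - 2 * d + 11, O = 10, N = 0, P = 1, S = 0),
    PI     = c(C = n + 9, H = 2 * n - 2 * d + 15, O = 13, N = 0, P = 1, S = 0),
    SM     = c(C = n + 5, H = 2 * n - 2 * d + 13, O = 6,  N = 2, P = 1, S = 0),
    Cer    = c(C = n,     H = 2 * n - 2 * d + 1,  O = if (hydroxylation == "d") 3 else 4,
               N = 1, P = 0, S = 0),
    HexCer = c(C = n + 6, H = 2 * n - 2 * d + 11, O = if (hydroxylation == "d") 8 else 9,
               N = 1, P = 0, S = 0),
    Sulf   = c(C = n + 6, H = 2 * n - 2 * d + 11, O = if (hydroxylation == "d") 11 else 12,
               N = 1, P = 0, S = 1),
    DG     = c(C = n + 3, H = 2 * n - 2 * d + 4,  O = 5,  N = 0, P = 0, S = 0),
    TG     = c(C = n + 3, H = 2 * n - 2 * d + 2,  O = 6,  N = 0, P = 0, S = 0)
  )
  storage.mode(f) <- "integer"
  f
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named vector of element counts over C, H, O, N, P, S, as
#'   returned by [lipidFormula()].
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' formulaMass(lipidFormula("PI", 38, 4))
formulaMass <- function(formula) {
  bad <- setdiff(names(formula), names(ELEMENT_MASS))
  if (length(bad)) stop("unknown elements: ", paste(bad, collapse = ", "))
  sum(formula * ELEMENT_MASS[names(formula)])
}

#' Theoretical adduct m/z of a lipid species
#'
#' @inheritParams lipidFormula
#' @param adduct One of `"M-H"`, `"M+H"`, `"M+Na"`, `"M+K"`. The adduct
#'   polarity must be compatible with the class detection-mode convention
#'   unless `checkPolarity = FALSE`.
#' @param checkPolarity Enforce the class/adduct polarity convention.
#' @return Monoisotopic ion m/z in Da.
#' @export
#' @examples
#' theoreticalMz("PI", 38, 4, adduct = "M-H")  # 885.5499
theoreticalMz <- function(class, carbons, doubleBonds, hydroxylation = "none",
                          adduct = NULL, checkPolarity = TRUE) {
  info <- LIPID_CLASS_TABLE[LIPID_CLASS_TABLE$class == class, ]
  if (nrow(info) == 0L) stop("unknown lipid class: ", class)
  if (is.null(adduct))
    adduct <- if (info$polarity == "negative") "M-H" else "M+H"
  arow <- ADDUCT_TABLE[ADDUCT_TABLE$adduct == adduct, ]
  if (nrow(arow) == 0L) stop("unknown adduct: ", adduct)
  if (checkPolarity && arow$polarity != info$polarity)
    stop("adduct ", adduct, " (", arow$polarity,
         " mode) is incompatible with class ", class,
         " (", info$polarity, " mode convention)")
  formulaMass(lipidFormula(class, carbons, doubleBonds, hydroxylation)) +
    arow$mass_shift
}

#' Species shorthand notation
#'
#' Formats and parses the field's sum-composition shorthand, e.g. `"PE 36:1"`,
#' `"PE P-36:2"`, `"SM d36:1"`, `"Sulf t42:1"`.
#'
#' @param class,carbons,doubleBonds,hydroxylation Species fields.
#' @return `speciesShorthand`: a character vector.
#' @export
#' @examples
#' speciesShorthand("PE_P", 36, 2)
#' parseSpeciesShorthand("SM d36:1")
speciesShorthand <- function(class, carbons, doubleBonds,
                             hydroxylation = "none") {
  prefix <- ifelse(class == "PE_P", "PE P-", paste0(class, " "))
  hyd <- ifelse(hydroxylation %in% c("d", "t"), hydroxylation, "")
  paste0(prefix, hyd, carbons, ":", doubleBonds)
}

#' @rdname speciesShorthand
#' @param x Character vector of shorthand species names.
#' @return `parseSpeciesShorthand`: a data.frame with columns `class`,
#'   `carbons`, `double_bonds`, `hydroxylation`.
#' @export
parseSpeciesShorthand <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z]+)\\s*(P-)?([dt]?)(\\d+):(\\d+)$", x))
  bad <- lengths(m) == 0L
  if (any(bad)) stop("unparseable species shorthand: ",
                     paste(x[bad], collapse = ", "))
  out <- do.call(rbind, lapply(m, function(g) {
    cls <- if (identical(g[3], "P-")) paste0(g[2], "_P") else g[2]
    data.frame(class = cls,
               carbons = as.integer(g[5]),
               double_bonds = as.integer(g[6]),
               hydroxylation = if (nzchar(g[4])) g[4] else "none",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
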