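## Monoisotopic element masses (CODATA/IUPAC), Da. Single source of truth for
## all mass arithmetic in the package.

ELEMENT_MASS <- c(
  C = 12.000000,
  H = 1.007825,
  O = 15.994915,
  N = 14.003074,
  P = 30.973762,
  S = 31.972071
)

## Mass of a proton (H minus one electron); used for [M+H]+/[M-H]-.
PROTON_MASS <- 1.007276
ELECTRON_MASS <- 0.000549

## Adduct table: monoisotopic shift applied to the neutral mass, with the
## electron mass folded into the cation masses.
ADDUCT_TABLE <- data.frame(
  adduct = c("M-H", "M+H", "M+Na", "M+K"),
  polarity = c("negative", "positive", "positive", "positive"),
  mass_shift = c(
    -1.007276,
    +1.007276,
    +22.989770 - 0.000549,
    +38.963707 - 0.000549
  ),
  stringsAsFactors = FALSE
)

## Supported lipid classes. `sphingoid` marks classes whose formula depends on
## the d/t hydroxylation of the sphingoid base; `polarity` is the detection
## mode convention used throughout (negative-mode classes ionize as [M-H]-,
## positive-mode classes as [M+H]+ by default, [M+Na]+/[M+K]+ selectable).
LIPID_CLASS_TABLE <- data.frame(
  class = c("PE", "PE_P", "PC", "PI", "PS", "PG",
            "SM", "Sulf", "HexCer", "Cer", "DG", "TG"),
  sphingoid = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
  polarity = c("negative", "negative", "positive", "negative", "negative",
               "negative", "positive", "negative", "positive", "positive",
               "positive", "positive"),
  min_carbons = c(20L, 20L, 20L, 20L, 20L, 20L,
                  20L, 20L, 20L, 20L, 10L, 15L),
  stringsAsFactors = FALSE
)

#' Supported lipid classes
#'
#' @return Character vector of lipid class identifiers understood by the
#'   sum-composition formula rules (`PE_P` denotes the PE plasmalogen,
#'   1-O-alk-1'-enyl, subclass).
#' @export
#' @examples
#' lipidClasses()
lipidClasses <- function() LIPID_CLASS_TABLE$class

#' Adduct definitions
#'
#' @return A data.frame with one row per supported adduct ion giving its
#'   polarity and exact monoisotopic mass shift in Da (electron mass folded
#'   into the cation masses; `M-H`/`M+H` use the proton mass).
#' @export
#' @examples
#' adductTable()
adductTable <- function() ADDUCT_TABLE
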