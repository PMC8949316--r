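#' Build an annotated lipid panel
#'
#' Expands a panel configuration (one row per species) into a panel table with
#' one row per (species, adduct) pair, carrying the elemental formula and
#' theoretical adduct m/z, sorted by m/z.
#'
#' @param config A data.frame with columns `class`, `carbons`, `double_bonds`,
#'   `hydroxylation` (`"none"`, `"d"` or `"t"`) and `ion_mode` (`"negative"`
#'   or `"positive"`), and optionally `adduct` (defaults to `"M-H"` in
#'   negative mode and `"M+H"` in positive mode).
#' @return A data.frame with columns `species` (shorthand), `class`,
#'   `carbons`, `double_bonds`, `hydroxylation`, `ion_mode`, `adduct`,
#'   `formula` and `mz`, sorted by `mz`.
#' @seealso [defaultLipidPanel()], [readPanelConfig()]
#' @export
#' @examples
#' cfg <- data.frame(class = "PI", carbons = 38, double_bonds = 4,
#'                   hydroxylation = "none", ion_mode = "negative")
#' buildPanel(cfg)
buildPanel <- function(config) {
  if (nrow(config) == 0L) {
    return(data.frame(species = character(), class = character(),
                      carbons = integer(), double_bonds = integer(),
                      hydroxylation = character(), ion_mode = character(),
                      adduct = character(), formula = character(),
                      mz = numeric(), stringsAsFactors = FALSE))
  }
  required <- c("class", "carbons", "double_bonds", "hydroxylation", "ion_mode")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("panel config lacks columns: ", paste(missing, collapse = ", "))
  if (!"adduct" %in% names(config))
    config$adduct <- ifelse(config$ion_mode == "negative", "M-H", "M+H")
  key <- paste(config$class, config$carbons, config$double_bonds,
               config$hydroxylation, config$adduct)
  if (anyDuplicated(key))
    stop("duplicate (species, adduct) entries in panel config: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rows <- lapply(seq_len(nrow(config)), function(i) {
    r <- config[i, ]
    f <- lipidFormula(r$class, r$carbons, r$double_bonds, r$hydroxylation)
    data.frame(
      species = speciesShorthand(r$class, r$carbons, r$double_bonds,
                                 r$hydroxylation),
      class = r$class, carbons = as.integer(r$carbons),
      double_bonds = as.integer(r$double_bonds),
      hydroxylation = r$hydroxylation, ion_mode = r$ion_mode,
      adduct = r$adduct,
      formula = paste0(names(f)[f > 0], ifelse(f[f > 0] > 1, f[f > 0], ""),
                       collapse = ""),
      mz = theoreticalMz(r$class, r$carbons, r$double_bonds, r$hydroxylation,
                         adduct = r$adduct),
      stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$mz), ]
  rownames(panel) <- NULL
  panel
}

#' Read a panel configuration file
#'
#' @param path Path to a CSV or YAML panel configuration. CSV files carry the
#'   columns documented in [buildPanel()]; YAML files carry a list of records
#'   with the same fields.
#' @return A panel configuration data.frame.
#' @export
readPanelConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    config <- do.call(rbind, lapply(recs, function(r)
      data.frame(class = r$class, carbons = r$carbons,
                 double_bonds = r$double_bonds,
                 hydroxylation = if (is.null(r$hydroxylation)) "none" else r$hydroxylation,
                 ion_mode = r$ion_mode,
                 stringsAsFactors = FALSE)))
  } else {
    config <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  config
}

#' The default brain lipid panel
#'
#' The packaged panel holds 124 sum-composition species over 11 lipid classes
#' (negative mode: diacyl PE, PE plasmalogen, PI, PS, PG, sulfatide; positive
#' mode: PC, SM, hexosylceramide, ceramide, DG), covering every species
#' reported in MALDI-IMS analyses of human healthy and glioblastoma brain
#' tissue that this package's composition profiles are parameterized to.
#' Species were curated so that same-polarity theoretical masses are well
#' separated (> 70 ppm), keeping sum-composition annotation unambiguous at
#' the default 9 ppm tolerance.
#'
#' @param ion_mode Optionally restrict to `"negative"` or `"positive"` mode.
#' @return A panel data.frame as returned by [buildPanel()].
#' @export
#' @examples
#' nrow(defaultLipidPanel())       # 124
#' table(defaultLipidPanel()$class)
defaultLipidPanel <- function(ion_mode = c("both", "negative", "positive")) {
  ion_mode <- match.arg(ion_mode)
  path <- system.file("extdata", "default_panel.csv",
                      package = "glioLipidIMS", mustWork = TRUE)
  panel <- buildPanel(readPanelConfig(path))
  if (ion_mode != "both") panel <- panel[panel$ion_mode == ion_mode, ]
  rownames(panel) <- NULL
  panel
}
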