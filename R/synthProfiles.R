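#' Literature-parameterized lipid composition profiles
#'
#' Loads the packaged composition configuration: per study arm
#' (`healthy_vehicle`, `gbm_vehicle`, `healthy_tmz`, `gbm_tmz`) and for the
#' surrounding non-proliferative tissue (`bulk_parenchyma`), a class share per
#' ion mode (share of total ion current; sums to 1 per polarity) and within-
#' class species mole percentages. The arm profiles are parameterized to
#' reported MALDI-IMS measurements of the MKI67+ proliferative cluster of
#' human healthy/GBM brain: in particular the class shares encode, after TIC
#' normalization, a 1.5-fold PE, 3.6-fold PI and 1.8-fold SM increase plus a
#' 2.9-fold sulfatide decrease in GBM vs healthy, and a 2.2-fold PI increase
#' with 1.8-fold HexCer and 1.6-fold sulfatide decreases under TMZ treatment
#' of healthy tissue; the species tables carry the printed mole percentages
#' (e.g. PI 38:4 at 54.9% healthy / 75.7% GBM).
#'
#' @param path Optional path to an alternative YAML configuration with the
#'   same layout.
#' @return A named list with elements `arms` (per-profile class shares and
#'   species mole percentages) and `noise` (`sigma`, `mz_jitter_ppm`).
#' @seealso [resolveProfile()], [simulateSection()]
#' @export
#' @examples
#' prof <- lipidomeProfiles()
#' shares <- function(arm) prof$arms[[arm]]$class_shares$negative
#' shares("gbm_vehicle")$PI / shares("healthy_vehicle")$PI   # 3.6
lipidomeProfiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gbm_composition.yaml",
                        package = "glioLipidIMS", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (arm in names(cfg$arms)) {
    for (pol in names(cfg$arms[[arm]]$class_shares)) {
      s <- unlist(cfg$arms[[arm]]$class_shares[[pol]])
      if (abs(sum(s) - 1) > 1e-6)
        stop("class shares for ", arm, "/", pol, " sum to ", sum(s),
             ", expected 1")
      if (any(s <= 0)) stop("class shares must be positive (", arm, ")")
    }
  }
  cfg
}

#' Resolve a composition profile against a panel
#'
#' Expands one profile's class shares and named species mole percentages into
#' a per-species expected-intensity weight vector over the panel entries of
#' one ion mode. Panel species not named in the profile share the class
#' remainder equally; within-class fractions therefore sum to exactly 1 and
#' the weights to 1 per polarity.
#'
#' @param profiles Configuration from [lipidomeProfiles()].
#' @param arm Profile name (e.g. `"gbm_vehicle"`, `"bulk_parenchyma"`).
#' @param panel Panel data.frame; only rows of `polarity` are used.
#' @param polarity `"negative"` or `"positive"`.
#' @return A data.frame with the panel rows of the requested mode plus
#'   columns `fraction` (within-class mole fraction) and `weight`
#'   (class share x fraction; expected share of pixel TIC).
#' @export
resolveProfile <- function(profiles, arm, panel,
                           polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (!arm %in% names(profiles$arms))
    stop("unknown composition profile: ", arm)
  prof <- profiles$arms[[arm]]
  sub <- panel[panel$ion_mode == polarity, , drop = FALSE]
  if (nrow(sub) == 0L) stop("panel has no ", polarity, "-mode entries")
  shares <- unlist(prof$class_shares[[polarity]])
  missing <- setdiff(unique(sub$class), names(shares))
  if (length(missing))
    stop("profile ", arm, " lacks class shares for: ",
         paste(missing, collapse = ", "))
  frac <- numeric(nrow(sub))
  for (cl in unique(sub$class)) {
    idx <- which(sub$class == cl)
    named <- prof$species_molpct[[cl]]
    key <- sub("^[A-Za-z]+ (P-)?", "", sub$species[idx]) # "36:1", "d36:1"
    f <- rep(NA_real_, length(idx))
    if (!is.null(named)) {
      unknown <- setdiff(names(named), key)
      if (length(unknown))
        stop("profile ", arm, " names species absent from the panel for ",
             cl, ": ", paste(unknown, collapse = ", "))
      f[match(names(named), key)] <- unlist(named) / 100
    }
    rest <- which(is.na(f))
    total_named <- sum(f, na.rm = TRUE)
    if (total_named > 1 + 1e-9)
      stop("named mole percentages exceed 100% for ", arm, "/", cl)
    if (length(rest)) {
      f[rest] <- (1 - total_named) / length(rest)
    } else if (abs(total_named - 1) > 1e-9) {
      stop("all ", cl, " species named for ", arm,
           " but mole percentages do not sum to 100")
    }
    frac[idx] <- f
  }
  sub$fraction <- frac
  sub$weight <- frac * shares[sub$class]
  stopifnot(abs(sum(sub$weight) - 1) < 1e-9)
  rownames(sub) <- NULL
  sub
}
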