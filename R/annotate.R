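#' Annotate observed m/z values against a lipid panel
#'
#' For each observed m/z the candidate panel entry minimizing the absolute
#' ppm error is selected when it falls within the tolerance; when more than
#' one candidate lies within the tolerance the winner is still the nearest in
#' ppm but the annotation is flagged `ambiguous` (sum-composition assignment
#' cannot be disambiguated further without on-tissue fragmentation, which is
#' outside this package's scope).
#'
#' @param mz Numeric vector of observed m/z values (Da), all positive.
#' @param panel Panel data.frame from [buildPanel()]/[defaultLipidPanel()].
#'   Annotation is usually run per ion mode; pass a mode-restricted panel.
#' @param tolPpm Matching tolerance in ppm (default 9, the instrument mass
#'   accuracy bound this pipeline assumes; typical accuracy is better than
#'   3 ppm).
#' @return A data.frame with one row per observed value: `observed_mz`,
#'   `species`, `class`, `adduct`, `theoretical_mz`, `ppm_error` (signed,
#'   `1e6 * (observed - theoretical) / theoretical`), `ambiguous` and
#'   `n_candidates`. Unmatched values carry `NA` annotation fields.
#' @export
#' @examples
#' panel <- defaultLipidPanel("negative")
#' annotateMz(885.552, panel)             # PI 38:4 [M-H]-
annotateMz <- function(mz, panel, tolPpm = 9) {
  if (tolPpm <= 0) stop("tolPpm must be positive")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("observed m/z values must be positive and finite")
  out <- data.frame(
    observed_mz = mz,
    species = NA_character_, class = NA_character_, adduct = NA_character_,
    theoretical_mz = NA_real_, ppm_error = NA_real_,
    ambiguous = NA, n_candidates = 0L,
    stringsAsFactors = FALSE)
  if (nrow(panel) == 0L || length(mz) == 0L) return(out)
  pmz <- panel$mz
  o <- order(pmz)
  pmz_s <- pmz[o]
  ## candidate window around each observed value
  lo <- findInterval(mz / (1 + tolPpm * 1e-6) - 1e-9, pmz_s) + 1L
  hi <- findInterval(mz / (1 - tolPpm * 1e-6) + 1e-9, pmz_s)
  for (i in seq_along(mz)) {
    if (hi[i] < lo[i]) next
    cand <- o[lo[i]:hi[i]]
    ppm <- 1e6 * (mz[i] - pmz[cand]) / pmz[cand]
    keep <- abs(ppm) <= tolPpm
    cand <- cand[keep]; ppm <- ppm[keep]
    if (!length(cand)) next
    j <- which.min(abs(ppm))
    out$species[i] <- panel$species[cand[j]]
    out$class[i] <- panel$class[cand[j]]
    out$adduct[i] <- panel$adduct[cand[j]]
    out$theoretical_mz[i] <- pmz[cand[j]]
    out$ppm_error[i] <- ppm[j]
    out$ambiguous[i] <- length(cand) > 1L
    out$n_candidates[i] <- length(cand)
  }
  out
}
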