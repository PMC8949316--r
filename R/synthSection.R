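#' Specify a synthetic tissue section
#'
#' Defines the geometry and composition layout of one simulated section: an
#' elliptical tissue area surrounded by matrix-only background pixels, with
#' one or more planted contiguous regions inside the tissue. The first region
#' is the proliferative (MKI67+-like) region and defines the ROI mask; any
#' further regions are additional planted blobs; remaining tissue pixels take
#' the last listed composition.
#'
#' @param condition `"healthy"` or `"GBM"`.
#' @param treatment `"vehicle"` or `"TMZ"`.
#' @param grid Integer `(rows, cols)`, both at least 20.
#' @param backgroundFraction Proportion of matrix-only (background) pixels.
#' @param roiFraction Fraction of tissue pixels covered by each planted blob
#'   region (the compact MKI67+-like zone; default 0.2, within the 10-30%
#'   range typical of proliferation zones).
#' @param regionCompositions Character vector of composition profile names
#'   (see [lipidomeProfiles()]); the first is the ROI region, the last is the
#'   surrounding tissue. Defaults to the arm profile matching
#'   condition/treatment plus `"bulk_parenchyma"`.
#' @param seed Integer seed controlling region placement.
#' @return A `sectionSpec` list (class `"sectionSpec"`).
#' @export
#' @examples
#' spec <- sectionSpec("GBM", "vehicle", seed = 1)
sectionSpec <- function(condition = c("healthy", "GBM"),
                        treatment = c("vehicle", "TMZ"),
                        grid = c(60L, 60L),
                        backgroundFraction = 0.2,
                        roiFraction = 0.2,
                        regionCompositions = NULL,
                        seed = 1L) {
  condition <- match.arg(condition)
  treatment <- match.arg(treatment)
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 20L))
    stop("grid must be at least 20 x 20")
  if (backgroundFraction < 0 || backgroundFraction >= 1)
    stop("backgroundFraction must lie in [0, 1)")
  if (is.null(regionCompositions)) {
    arm <- paste(tolower(condition), tolower(treatment), sep = "_")
    regionCompositions <- c(arm, "bulk_parenchyma")
  }
  if (length(regionCompositions) < 1L)
    stop("at least one region composition is required")
  structure(list(condition = condition, treatment = treatment, grid = grid,
                 backgroundFraction = backgroundFraction,
                 roiFraction = roiFraction,
                 regionCompositions = regionCompositions,
                 seed = as.integer(seed)),
            class = "sectionSpec")
}

## Deterministic section geometry: per-pixel region label
## (0 = background, 1..k-1 = planted blobs, k = remaining tissue).
sectionGeometry <- function(spec) {
  nr <- spec$grid[1]; nc <- spec$grid[2]
  xy <- cbind(x = rep(seq_len(nc), each = nr), y = rep(seq_len(nr), nc))
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  ## ellipse with area (1 - backgroundFraction) * grid area
  target <- (1 - spec$backgroundFraction) * nr * nc
  scale <- sqrt(target / (pi * (nc / 2) * (nr / 2)))
  ax <- nc / 2 * scale; ay <- nr / 2 * scale
  d2 <- ((xy[, 1] - cx) / ax)^2 + ((xy[, 2] - cy) / ay)^2
  tissue <- d2 <= 1
  ## rank-based trim so the tissue pixel count is exact
  ord <- order(d2)
  tissue <- logical(nr * nc)
  tissue[ord[seq_len(round(target))]] <- TRUE

  labels <- integer(nr * nc)
  k <- length(spec$regionCompositions)
  labels[tissue] <- k
  if (k > 1L) {
    nBlob <- k - 1L
    tIdx <- which(tissue)
    blobArea <- spec$roiFraction * length(tIdx)
    centers <- withSeed(spec$seed, {
      ang <- stats::runif(nBlob, 0, 2 * pi) + seq_len(nBlob) * 2 * pi / nBlob
      r <- stats::runif(nBlob, 0.25, 0.55)
      cbind(cx + r * ax * cos(ang), cy + r * ay * sin(ang))
    })
    for (b in seq_len(nBlob)) {
      dd <- (xy[tIdx, 1] - centers[b, 1])^2 + (xy[tIdx, 2] - centers[b, 2])^2
      free <- labels[tIdx] == k
      take <- tIdx[free][order(dd[free])[seq_len(min(round(blobArea), sum(free)))]]
      labels[take] <- b
    }
  }
  list(coords = xy, labels = labels, tissue = tissue)
}

#' Simulate one imaging-MS section
#'
#' Generates a centroided peak list per pixel. Non-background pixels carry
#' one peak per panel species of the requested ion mode, with intensity
#' `weight * LogNormal(0, sigma)` (weight = class share x species fraction of
#' the pixel's region composition) and m/z jittered uniformly within
#' `+/- jitterPpm`. Background pixels carry 5-20 low-intensity chemical-noise
#' peaks at uniform random m/z (total ~1% of the expected tissue TIC). The
#' planted proliferative region is stored as `roi_mask` in the metadata,
#' generator region truth as `region_labels`. Fully reproducible from `seed`.
#'
#' @param spec A [sectionSpec()].
#' @param profiles Composition configuration from [lipidomeProfiles()].
#' @param panel Lipid panel from [defaultLipidPanel()]/[buildPanel()].
#' @param polarity Ion mode to simulate.
#' @param noiseSigma Log-normal sdlog of multiplicative intensity noise
#'   (`NULL` uses the configured default).
#' @param jitterPpm Uniform half-width of the m/z jitter in ppm (`NULL` uses
#'   the configured default).
#' @param seed Integer seed for all random draws.
#' @return An [IMSDataset-class].
#' @export
#' @examples
#' sec <- simulateSection(sectionSpec("GBM", "vehicle", grid = c(24, 24)),
#'                        noiseSigma = 0, jitterPpm = 0, seed = 1)
simulateSection <- function(spec,
                            profiles = lipidomeProfiles(),
                            panel = defaultLipidPanel(),
                            polarity = c("negative", "positive"),
                            noiseSigma = NULL, jitterPpm = NULL, seed = 1L) {
  polarity <- match.arg(polarity)
  if (is.null(noiseSigma)) noiseSigma <- profiles$noise$sigma
  if (is.null(jitterPpm)) jitterPpm <- profiles$noise$mz_jitter_ppm
  geom <- sectionGeometry(spec)
  k <- length(spec$regionCompositions)
  weights <- lapply(spec$regionCompositions, function(arm)
    resolveProfile(profiles, arm, panel, polarity))
  theo <- weights[[1]]$mz
  nsp <- length(theo)
  scanRange <- if (polarity == "negative") c(550, 1000) else c(480, 1000)

  n <- nrow(geom$coords)
  mzL <- vector("list", n); intL <- vector("list", n)
  withSeed(seed, {
    for (i in seq_len(n)) {
      lab <- geom$labels[i]
      if (lab == 0L) {
        npk <- sample(5:20, 1L)
        m <- sort(stats::runif(npk, scanRange[1], scanRange[2]))
        v <- (0.01 / npk) * stats::rlnorm(npk, 0, max(noiseSigma, 0.1))
        mzL[[i]] <- m; intL[[i]] <- v
      } else {
        w <- weights[[lab]]$weight
        v <- if (noiseSigma > 0) w * stats::rlnorm(nsp, 0, noiseSigma) else w
        m <- if (jitterPpm > 0)
          theo * (1 + stats::runif(nsp, -jitterPpm, jitterPpm) * 1e-6)
        else theo
        o <- order(m)
        mzL[[i]] <- m[o]; intL[[i]] <- v[o]
      }
    }
  })
  IMSDataset(
    coords = geom$coords, mz = mzL, intensity = intL,
    metadata = list(
      condition = spec$condition, treatment = spec$treatment,
      section_id = paste0(tolower(spec$condition), "_",
                          tolower(spec$treatment), "_s", seed),
      polarity = polarity, lateral_resolution_um = 50,
      noise_sigma = noiseSigma, mz_jitter_ppm = jitterPpm, seed = seed,
      roi_mask = geom$labels == 1L,
      region_labels = geom$labels))
}

#' Read/write IMS sections as plain-text tables
#'
#' Long-format TSV interchange for [IMSDataset-class] objects (columns `x`,
#' `y`, `mz`, `intensity`; one row per peak), with metadata serialized into a
#' YAML sidecar `<path>.meta.yaml`. The container carries the same semantics
#' as a centroided imzML file: pixel coordinates plus per-pixel m/z and
#' intensity arrays.
#'
#' @param x An [IMSDataset-class].
#' @param path Output/input TSV path.
#' @return `writeIMSDataset` returns `path` invisibly; `readIMSDataset`
#'   returns an [IMSDataset-class].
#' @export
writeIMSDataset <- function(x, path) {
  n <- lengths(x@mz)
  tab <- data.frame(
    x = rep(x@coords[, 1], n), y = rep(x@coords[, 2], n),
    mz = unlist(x@mz), intensity = unlist(x@intensity))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- x@metadata
  meta$roi_mask <- NULL; meta$region_labels <- NULL
  extra <- list(meta = meta,
                roi_mask = as.integer(x@metadata$roi_mask),
                region_labels = as.integer(x@metadata$region_labels),
                coords = list(x = as.integer(x@coords[, 1]),
                              y = as.integer(x@coords[, 2])))
  yaml::write_yaml(extra, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeIMSDataset
#' @export
readIMSDataset <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  extra <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  coords <- cbind(x = extra$coords$x, y = extra$coords$y)
  key <- paste(tab$x, tab$y)
  ckey <- paste(coords[, 1], coords[, 2])
  idx <- split(seq_len(nrow(tab)), factor(key, levels = ckey))
  mzL <- lapply(idx, function(i) tab$mz[i][order(tab$mz[i])])
  intL <- lapply(idx, function(i) tab$intensity[i][order(tab$mz[i])])
  meta <- extra$meta
  if (!is.null(extra$roi_mask)) meta$roi_mask <- as.logical(extra$roi_mask)
  if (!is.null(extra$region_labels))
    meta$region_labels <- as.integer(extra$region_labels)
  IMSDataset(coords = coords, mz = unname(mzL), intensity = unname(intL),
             metadata = meta)
}
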