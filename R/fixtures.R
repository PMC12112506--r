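## Summed-area helper: mean of M over every k x k window.
## Returns an (n_r - k + 1) x (n_c - k + 1) matrix of window means.
windowMean <- function(M, k) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum) |> t()
  i <- seq_len(nr - k + 1L); j <- seq_len(nc - k + 1L)
  (P[i + k, j + k] - P[i, j + k] - P[i + k, j] + P[i, j]) / (k * k)
}

## Gaussian-filtered standard-normal noise, rescaled to unit sd
smoothNoise <- function(n, sigma) {
  z <- EBImage::gblur(matrix(rnorm(n * n), n, n), sigma = sigma)
  z / sd(z)
}

#' Generate a synthetic H&E-like fixture
#'
#' Renders a desk-scale stand-in for a scanned slide: near-white glass, a
#' textured tissue region obtained by thresholding low-pass Gaussian noise at
#' the quantile matching the requested coverage, and smooth tumor blobs
#' (radial profile plus low-pass noise, thresholded) constrained to lie
#' within tissue. Colours follow the palette of the spec object, with the tumor colour
#' interpolated from the tissue colour by \code{separability}. PSA-style
#' rectangular regions are selected with a summed-area search: tumor regions
#' must overlap the tumor mask by at least 95 percent, non-tumor regions must
#' contain no tumor and at least half tissue.
#'
#' The output is bit-reproducible: the same spec (including seed) always
#' yields identical arrays.
#'
#' @param spec a [FixtureSpec-class].
#' @param nTumorRegions,nNonTumorRegions PSA regions to mark (defaults 4
#'   and 5, the 40:50 flavour of sparse annotation at desk scale). Fewer are
#'   returned, with a warning, when the geometry cannot host them.
#' @param regionSize PSA region edge in pixels (default 256 so a random
#'   224-pixel training crop fits inside with jitter).
#' @return A [FixtureBundle-class].
#' @examples
#' b <- generateFixture(fixtureSpec(seed = 3, imageSize = 1120))
#' b
#' @export
generateFixture <- function(spec, nTumorRegions = 4L, nNonTumorRegions = 5L,
                            regionSize = 256L) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  n <- spec@imageSize
  regionSize <- as.integer(min(regionSize, n))
  withLocalSeed(spec@seed, {
    ## tissue support from thresholded low-pass noise
    z <- smoothNoise(n, sigma = n / 16)
    tissue <- z > quantile(z, 1 - spec@tissueCoverage)

    ## tumor blobs: radial bump + low-pass noise, thresholded at 0
    tumor <- matrix(FALSE, n, n)
    if (spec@nTumorBlobs > 0L) {
      ys <- rep.int(seq_len(n), n); xs <- rep(seq_len(n), each = n)
      inner <- which(tissue)
      centers <- inner[ceiling(runif(spec@nTumorBlobs) * length(inner))]
      bnoise <- 0.25 * smoothNoise(n, sigma = n / 24)
      for (cc in centers) {
        cy <- (cc - 1L) %% n + 1L; cx <- (cc - 1L) %/% n + 1L
        rad <- spec@blobScale * runif(1, 0.65, 1)
        rr <- sqrt((ys - cy)^2 + (xs - cx)^2)
        blob <- matrix(1 - rr / rad, n, n) + bnoise
        tumor <- tumor | (blob > 0)
      }
      tissue <- tissue | tumor  # blobs may spill past tissue; keep tumor subset of tissue
    }

    ## render RGB
    pal <- spec@palette
    sep <- min(spec@separability, 1)
    tumorCol <- pal$tissue + sep * (pal$tumor - pal$tissue)
    img <- array(0, c(n, n, 3L))
    texTissue <- smoothNoise(n, sigma = 2)
    texFine <- matrix(rnorm(n * n, sd = 1), n, n)
    for (ch in 1:3) {
      base <- matrix(pal$background[ch], n, n)
      base[tissue] <- pal$tissue[ch]
      base[tumor] <- tumorCol[ch]
      tex <- 0.035 * texTissue + 0.02 * texFine
      tex[!tissue] <- 0.004 * texFine[!tissue]
      img[, , ch] <- clampNum(base + tex, 0, 1)
    }

    regions <- selectPsaRegions(tumor, tissue, regionSize,
                                nTumorRegions, nNonTumorRegions)

    new("FixtureBundle", image = img,
        tumorMask = matrix(as.integer(tumor), n, n),
        tissueMask = matrix(as.integer(tissue), n, n),
        psaRegions = regions,
        manifest = list(seed = spec@seed, imageSize = n,
                        nTumorBlobs = spec@nTumorBlobs,
                        blobScale = spec@blobScale,
                        tissueCoverage = spec@tissueCoverage,
                        separability = spec@separability,
                        palette = pal, regionSize = regionSize,
                        generator = "wsiseg"))
  })
}

## Pick non-overlapping labelled rectangles using window means of the masks.
selectPsaRegions <- function(tumor, tissue, k, nTumor, nNonTumor) {
  tf <- windowMean(tumor + 0, k)
  sf <- windowMean(tissue + 0, k)
  pick <- function(cand, count) {
    chosen <- integer(0)
    if (!length(cand) || count == 0L) return(chosen)
    cy <- (cand - 1L) %% nrow(tf) + 1L
    cx <- (cand - 1L) %/% nrow(tf) + 1L
    ord <- sample.int(length(cand))
    for (o in ord) {
      if (length(chosen) >= count) break
      ok <- TRUE
      for (p in chosen) {
        py <- (p - 1L) %% nrow(tf) + 1L; px <- (p - 1L) %/% nrow(tf) + 1L
        if (abs(py - cy[o]) < k && abs(px - cx[o]) < k) { ok <- FALSE; break }
      }
      if (ok) chosen <- c(chosen, cand[o])
    }
    chosen
  }
  tumCand <- which(tf >= 0.97)
  nonCand <- which(tf == 0 & sf >= 0.5)
  tum <- pick(tumCand, nTumor)
  non <- pick(nonCand, nNonTumor)
  if (length(tum) < nTumor || length(non) < nNonTumor)
    warning(sprintf("placed %d/%d tumor and %d/%d non-tumor regions",
                    length(tum), nTumor, length(non), nNonTumor))
  asRow <- function(idx, label) {
    if (!length(idx))
      return(data.frame(y0 = integer(0), x0 = integer(0), y1 = integer(0),
                        x1 = integer(0), label = character(0)))
    y0 <- (idx - 1L) %% nrow(tf) + 1L
    x0 <- (idx - 1L) %/% nrow(tf) + 1L
    data.frame(y0 = y0, x0 = x0, y1 = y0 + k - 1L, x1 = x0 + k - 1L,
               label = label)
  }
  rbind(asRow(tum, "tumor"), asRow(non, "non_tumor"))
}

#' Generate a labelled patch-region set
#'
#' Emulates sparse region-of-interest annotation: fixtures are generated from
#' sub-seeds of \code{spec} until the requested number of tumor and non-tumor
#' regions has been collected. Each region is a \code{regionSize}-pixel RGB
#' square from which one random 224x224 crop is taken per training epoch.
#'
#' @param spec a [FixtureSpec-class]; its seed drives the whole set.
#' @param nPerClass balanced count per class; alternatively give
#'   \code{counts}.
#' @param counts integer vector \code{c(tumor, nonTumor)} for deliberately
#'   imbalanced sets (the study-style imbalance is \code{c(40, 50)}).
#' @param regionSize region edge (default 232).
#' @param maxFixtures cap on fixtures generated while collecting regions.
#' @return list with \code{regions} (list of H x W x 3 arrays),
#'   \code{labels} (integer vector, tumor = 1, non-tumor = 0) and
#'   \code{manifest} (data.frame with source fixture seed and bounds).
#' @examples
#' ps <- generatePatchSet(fixtureSpec(seed = 2, imageSize = 1120),
#'                        nPerClass = 2)
#' table(ps$labels)
#' @export
generatePatchSet <- function(spec, nPerClass = NULL, counts = NULL,
                             regionSize = 232L, maxFixtures = 60L) {
  if (is.null(counts)) {
    if (is.null(nPerClass)) stop("give nPerClass or counts")
    if (nPerClass < 1L) stop("nPerClass must be >= 1")
    counts <- c(nPerClass, nPerClass)
  }
  counts <- as.integer(counts)
  regions <- list(); labels <- integer(0)
  man <- list()
  need <- counts
  i <- 0L
  while (any(need > 0L) && i < maxFixtures) {
    i <- i + 1L
    sub <- spec
    sub@seed <- as.integer(deriveSeed(spec@seed, i))
    b <- suppressWarnings(
      generateFixture(sub, nTumorRegions = min(need[1], 6L),
                      nNonTumorRegions = min(need[2], 6L),
                      regionSize = regionSize))
    rg <- b@psaRegions
    for (r in seq_len(nrow(rg))) {
      lab <- if (rg$label[r] == "tumor") 1L else 0L
      if ((lab == 1L && need[1] <= 0L) || (lab == 0L && need[2] <= 0L)) next
      regions[[length(regions) + 1L]] <-
        b@image[rg$y0[r]:rg$y1[r], rg$x0[r]:rg$x1[r], , drop = FALSE]
      labels <- c(labels, lab)
      man[[length(man) + 1L]] <-
        data.frame(fixtureSeed = sub@seed, y0 = rg$y0[r], x0 = rg$x0[r],
                   y1 = rg$y1[r], x1 = rg$x1[r], label = lab)
      if (lab == 1L) need[1] <- need[1] - 1L else need[2] <- need[2] - 1L
    }
  }
  if (any(need > 0L))
    warning(sprintf("collected %d tumor / %d non-tumor regions (wanted %d/%d)",
                    sum(labels == 1L), sum(labels == 0L), counts[1], counts[2]))
  list(regions = regions, labels = labels,
       manifest = do.call(rbind, man))
}

#' Simple colour/texture features of an image patch
#'
#' Channel means plus grey-level standard deviation; enough for a tiny
#' reference classifier on high-separability fixtures.
#'
#' @param patch H x W x 3 array.
#' @return named numeric vector (meanR, meanG, meanB, sdGray).
#' @export
patchFeatures <- function(patch) {
  g <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  c(meanR = mean(patch[, , 1]), meanG = mean(patch[, , 2]),
    meanB = mean(patch[, , 3]), sdGray = sd(g))
}

## ---------------------------------------------------------------------------
## Fixture / annotation I/O
## ---------------------------------------------------------------------------

#' Write a fixture bundle to disk
#'
#' Writes \code{image.png} (or \code{.tif}), \code{tumor_mask.png} and
#' \code{tissue_mask.png} (single channel, 0/255), \code{regions.geojson}
#' (QuPath-dialect FeatureCollection) and \code{manifest.json}.
#'
#' @param bundle a [FixtureBundle-class].
#' @param dir output directory (created if needed).
#' @param format "png" or "tiff" for the RGB image.
#' @return \code{dir}, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  writeImageHWC(bundle@image, file.path(dir, paste0("image.", ext)))
  writeImageHWC(bundle@tumorMask, file.path(dir, "tumor_mask.png"))
  writeImageHWC(bundle@tissueMask, file.path(dir, "tissue_mask.png"))
  writeRegionsGeoJSON(bundle@psaRegions, file.path(dir, "regions.geojson"))
  jsonlite::write_json(bundle@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write labelled regions as GeoJSON
#'
#' QuPath-style FeatureCollection: each region is a closed rectangular
#' Polygon in 0-based pixel coordinates (x, y) with a
#' \code{classification$name} property of "Tumor" or "Non-tumor".
#'
#' @param regions data.frame with \code{y0, x0, y1, x1, label} (1-based
#'   inclusive bounds as in [FixtureBundle-class]).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRegionsGeoJSON <- function(regions, path) {
  feats <- lapply(seq_len(nrow(regions)), function(i) {
    x0 <- regions$x0[i] - 1; x1 <- regions$x1[i]  # half-open pixel bounds
    y0 <- regions$y0[i] - 1; y1 <- regions$y1[i]
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(objectType = "annotation",
                           classification = list(
                             name = if (regions$label[i] == "tumor")
                               "Tumor" else "Non-tumor")))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read labelled regions from GeoJSON
#'
#' Inverse of [writeRegionsGeoJSON()]; arbitrary polygons are reduced to
#' their axis-aligned bounding box.
#'
#' @param path GeoJSON file.
#' @return data.frame with \code{y0, x0, y1, x1, label}.
#' @export
readRegionsGeoJSON <- function(path) {
  js <- jsonlite::read_json(path)
  rows <- lapply(js$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    xs <- vapply(coords, function(p) as.numeric(p[[1]]), 0)
    ys <- vapply(coords, function(p) as.numeric(p[[2]]), 0)
    nm <- tolower(f$properties$classification$name %||% "non-tumor")
    data.frame(y0 = min(ys) + 1L, x0 = min(xs) + 1L,
               y1 = max(ys), x1 = max(xs),
               label = if (grepl("^tumor", nm)) "tumor" else "non_tumor")
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
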