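# Slide tiling, informative-tissue filtering, and patch feature extraction.

#' Patch extraction specification
#'
#' @param patch_size_px Patch side in pixels at the working resolution
#'   (default 512).
#' @param target_mpp Working resolution in microns per pixel (default 0.50).
#' @param min_informative_fraction Patches with a lower fraction of
#'   informative (tissue) pixels are discarded; a fraction exactly at the
#'   boundary is kept (default 0.40).
#' @param informative_intensity_threshold Grayscale cut separating tissue
#'   from background, 0-255 scale (default 200). A pixel is informative when
#'   its intensity is on the `informative_darker` side of the cut.
#' @param informative_darker If `TRUE` (default), informative = intensity
#'   below the threshold, i.e. tissue is darker than the near-white slide
#'   background. Configurable because the comparison direction is sometimes
#'   stated the other way around.
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(patch_size_px = 512L, target_mpp = 0.50,
                       min_informative_fraction = 0.40,
                       informative_intensity_threshold = 200,
                       informative_darker = TRUE) {
  stopifnot(patch_size_px > 0, target_mpp > 0,
            min_informative_fraction >= 0, min_informative_fraction <= 1,
            informative_intensity_threshold >= 0,
            informative_intensity_threshold <= 255)
  structure(list(
    patch_size_px = as.integer(patch_size_px), target_mpp = target_mpp,
    min_informative_fraction = min_informative_fraction,
    informative_intensity_threshold = informative_intensity_threshold,
    informative_darker = isTRUE(informative_darker)
  ), class = "patch_spec")
}

# normalize an image array to H x W x 3 in [0, 255]
as_rgb255 <- function(image) {
  if (length(dim(image)) == 2) {
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  if (dim(image)[3] > 3) image <- image[, , 1:3, drop = FALSE]
  if (max(image, na.rm = TRUE) <= 1) image <- image * 255
  image
}

# nearest-neighbour resampling to a scale factor (used to bring a slide from
# its native resolution to the working microns-per-pixel)
resample_image <- function(image, factor) {
  if (abs(factor - 1) < 1e-9) return(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  nh <- max(1L, floor(h * factor))
  nw <- max(1L, floor(w * factor))
  ri <- pmin(h, pmax(1L, round((seq_len(nh) - 0.5) / factor + 0.5)))
  ci <- pmin(w, pmax(1L, round((seq_len(nw) - 0.5) / factor + 0.5)))
  image[ri, ci, , drop = FALSE]
}

#' Tile a slide raster into non-overlapping patches
#'
#' Resamples the image from its native resolution to `spec$target_mpp`, then
#' tiles it on a non-overlapping lattice of `patch_size_px` squares in
#' row-major order. Partial tiles at the right/bottom border are dropped.
#'
#' @param image RGB array (H x W x 3, values in `[0,1]` or `[0,255]`), a
#'   grayscale matrix, or a PNG/TIFF file path.
#' @param spec A [patch_spec()].
#' @param native_mpp Native resolution of `image`; defaults to
#'   `spec$target_mpp` (no resampling).
#' @param slide_id Identifier attached to every patch.
#' @return Tibble of patches: `slide_id`, origin `x`, `y` (0-based, lattice
#'   multiples of the patch size), centroid `cx`, `cy`, and a `pixels`
#'   list-column of RGB blocks.
#' @export
tile_slide <- function(image, spec = patch_spec(), native_mpp = NULL,
                       slide_id = "slide") {
  if (is.character(image)) image <- read_slide_image(image)
  image <- as_rgb255(image)
  if (is.null(native_mpp)) native_mpp <- spec$target_mpp
  image <- resample_image(image, native_mpp / spec$target_mpp)
  p <- spec$patch_size_px
  h <- dim(image)[1]
  w <- dim(image)[2]
  nr <- h %/% p
  nc <- w %/% p
  if (nr == 0 || nc == 0) {
    warning("image smaller than one patch; no tiles produced", call. = FALSE)
    return(tibble::tibble(slide_id = character(), x = integer(),
                          y = integer(), cx = numeric(), cy = numeric(),
                          pixels = list()))
  }
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr)) # row-major
  pixels <- purrr::map2(grid$row, grid$col, function(r, cc) {
    image[((r - 1) * p + 1):(r * p), ((cc - 1) * p + 1):(cc * p), , drop = FALSE]
  })
  tibble::tibble(
    slide_id = slide_id,
    x = (grid$col - 1L) * p, y = (grid$row - 1L) * p,
    cx = (grid$col - 1L) * p + p / 2, cy = (grid$row - 1L) * p + p / 2,
    pixels = pixels
  )
}

#' Read a slide raster from PNG or TIFF
#'
#' Plain rasters only; pyramidal WSIs are supported through any reader that
#' yields an RGB array at a known resolution (see [tile_slide()]'s
#' `native_mpp`).
#'
#' @param path PNG or TIFF file.
#' @return RGB array.
#' @export
read_slide_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    return(png::readPNG(path))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format: ", path, call. = FALSE)
}

patch_informative_fraction <- function(pixels, spec) {
  gray <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  if (spec$informative_darker) mean(gray < spec$informative_intensity_threshold)
  else mean(gray > spec$informative_intensity_threshold)
}

#' Filter patches by informative-tissue fraction
#'
#' Keeps a patch iff the fraction of informative pixels is at least
#' `spec$min_informative_fraction` (a patch exactly at the boundary is
#' kept). Informative means grayscale intensity below
#' `spec$informative_intensity_threshold` by default: tissue is darker than
#' the near-white background.
#'
#' @param patches Patch tibble from [tile_slide()] (must carry `pixels`).
#' @param spec A [patch_spec()].
#' @return The retained rows, with an `informative_fraction` column added.
#' @export
filter_patches <- function(patches, spec = patch_spec()) {
  stopifnot("pixels" %in% names(patches))
  frac <- purrr::map_dbl(patches$pixels, patch_informative_fraction, spec = spec)
  out <- patches
  out$informative_fraction <- frac
  out[frac >= spec$min_informative_fraction, , drop = FALSE]
}

#' Default handcrafted patch feature extractor
#'
#' A deterministic colour/texture descriptor: per-channel means, standard
#' deviations and 8-bin histograms, grayscale gradient energy, and local
#' contrast, padded with zeros (or projected through a fixed seeded
#' orthogonal-ish map when `dim` is smaller than the base descriptor) to the
#' requested dimension.
#'
#' @param dim Output feature dimension D (default 1024).
#' @return A `patch_extractor` (list with `name`, `dim`, and `fn`).
#' @export
default_extractor <- function(dim = 1024L) {
  dim <- as.integer(dim)
  base_dim <- 3L * 10L + 4L # per-channel stats + hist, gradient, contrast
  proj <- NULL
  if (dim < base_dim) {
    proj <- withr::with_seed(20240101L, {
      M <- matrix(stats::rnorm(base_dim * dim), base_dim, dim)
      qr.Q(qr(M))[, seq_len(dim), drop = FALSE]
    })
  }
  fn <- function(pixels) {
    v <- numeric(0)
    for (ch in 1:3) {
      x <- pixels[, , ch] / 255
      v <- c(v, mean(x), stats::sd(x),
             as.vector(graphics::hist(x, breaks = seq(0, 1, length.out = 9),
                                      plot = FALSE)$counts) / length(x))
    }
    gray <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / (3 * 255)
    gx <- gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE]
    gy <- gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE]
    v <- c(v, mean(abs(gx)), mean(abs(gy)), stats::sd(gray),
           diff(range(gray)))
    if (!is.null(proj)) as.vector(v %*% proj)
    else c(v, numeric(dim - length(v)))
  }
  structure(list(name = "handcrafted-colour-texture", dim = dim, fn = fn),
            class = "patch_extractor")
}

#' Extract node features for a set of patches
#'
#' @param patches Patch tibble carrying a `pixels` list-column.
#' @param extractor A `patch_extractor` contract: a list with `name`, the
#'   declared output `dim`, and `fn(pixels) -> numeric(dim)`.
#' @return Numeric matrix, one row per patch, `extractor$dim` columns.
#' @export
extract_features <- function(patches, extractor = default_extractor()) {
  stopifnot(inherits(extractor, "patch_extractor") ||
              (is.list(extractor) && all(c("dim", "fn") %in% names(extractor))))
  rows <- purrr::map(patches$pixels, function(px) {
    v <- extractor$fn(as_rgb255(px))
    if (length(v) != extractor$dim) {
      stop(sprintf("extractor '%s' returned %d values but declares dim %d",
                   extractor$name %||% "?", length(v), extractor$dim),
           call. = FALSE)
    }
    v
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
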