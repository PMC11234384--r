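#' Scene specification for synthetic imaging data
#'
#' A `scene_spec` describes the imaging geometry and noise model shared by
#' all synthetic scenes: image size, pixel size, the width of the Gaussian
#' point-spread function used to render diffraction-limited puncta, and a
#' camera noise model (Poisson shot noise plus Gaussian read noise).
#'
#' The default pixel size of 77.7 nm makes 3 pixels equal 233 nm, so the
#' default object-colocalization threshold corresponds to exactly three
#' pixels, close to the lateral resolution of a confocal microscope.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_nm Pixel pitch in nanometres (default 77.7).
#' @param psf_sigma_nm Standard deviation of the Gaussian PSF in nm
#'   (default 100, roughly a 233 nm FWHM).
#' @param gaussian_sd Read-noise standard deviation in intensity units
#'   (0 disables).
#' @param poisson_scaling Photons per intensity unit for shot noise
#'   (0 disables).
#' @param seed Integer seed controlling all randomness derived from this
#'   scene.
#' @return A `scene_spec` object (a validated list).
#' @export
scene_spec <- function(width_px = 256L, height_px = 256L,
                       pixel_size_nm = 77.7, psf_sigma_nm = 100,
                       gaussian_sd = 0, poisson_scaling = 0,
                       seed = 1L) {
  spec <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_nm = as.numeric(pixel_size_nm),
    psf_sigma_nm = as.numeric(psf_sigma_nm),
    noise_model = list(gaussian_sd = as.numeric(gaussian_sd),
                       poisson_scaling = as.numeric(poisson_scaling)),
    seed = as.integer(seed)
  ), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$width_px <= 0L || spec$height_px <= 0L)
    stop("scene dimensions must be positive")
  if (spec$pixel_size_nm <= 0)
    stop("pixel_size_nm must be positive")
  if (spec$psf_sigma_nm < 0)
    stop("psf_sigma_nm must be non-negative")
  invisible(spec)
}

#' Construct an image object
#'
#' Images are stored as plain numeric matrices (rows = y, columns = x) or
#' 3-d arrays (y, x, plane) together with the physical pixel size, a channel
#' label, and a flag recording whether background subtraction has been
#' applied. Pixel (row r, column c), 1-based, has its centre at
#' x = (c - 1) * pixel_size_nm, y = (r - 1) * pixel_size_nm, i.e. 0-based
#' pixel indices map directly to nm coordinates. Downstream length-based
#' thresholds (233 nm) rely on this convention.
#'
#' @param data Numeric matrix (y, x) or array (y, x, plane).
#' @param pixel_size_nm Pixel pitch in nm.
#' @param channel Channel label (free text, e.g. "ip3r", "mito").
#' @param background_corrected Logical flag.
#' @return An `mcs_image` object.
#' @export
mcs_image <- function(data, pixel_size_nm, channel = "unknown",
                      background_corrected = FALSE) {
  stopifnot(is.numeric(data), length(dim(data)) %in% c(2L, 3L),
            pixel_size_nm > 0)
  structure(list(data = data, pixel_size_nm = as.numeric(pixel_size_nm),
                 channel = channel,
                 background_corrected = isTRUE(background_corrected)),
            class = "mcs_image")
}

#' Construct a binary mask
#'
#' @param data Logical matrix on the image grid.
#' @param pixel_size_nm Pixel pitch in nm.
#' @param kind One of "cell", "mitochondria", "nuclei", "background", "roi".
#' @return An `mcs_mask` object.
#' @export
mcs_mask <- function(data, pixel_size_nm,
                     kind = c("cell", "mitochondria", "nuclei",
                              "background", "roi")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(data), pixel_size_nm > 0)
  storage.mode(data) <- "logical"
  structure(list(data = data, pixel_size_nm = as.numeric(pixel_size_nm),
                 kind = kind),
            class = "mcs_mask")
}

#' Construct a puncta field
#'
#' A puncta field is the object-level representation of a spot channel:
#' punctum centroids in nm together with per-punctum summed intensity and
#' pixel area. Centroids use the same 0-based-pixel-to-nm convention as
#' [mcs_image()].
#'
#' @param x_nm,y_nm Centroid coordinates in nm.
#' @param intensity Per-punctum integrated intensity.
#' @param area_px Per-punctum area in pixels.
#' @param channel Source channel label.
#' @param pixel_size_nm Pixel pitch of the source image.
#' @return A `puncta_field` object.
#' @export
puncta_field <- function(x_nm, y_nm, intensity = rep(1, length(x_nm)),
                         area_px = rep(1L, length(x_nm)),
                         channel = "unknown", pixel_size_nm = 77.7) {
  stopifnot(length(x_nm) == length(y_nm),
            length(intensity) == length(x_nm),
            length(area_px) == length(x_nm))
  structure(list(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                 intensity = as.numeric(intensity),
                 area_px = as.numeric(area_px),
                 channel = channel,
                 pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "puncta_field")
}

#' Number of puncta in a field
#' @param x A `puncta_field`.
#' @return Integer count.
#' @export
n_puncta <- function(x) {
  stopifnot(inherits(x, "puncta_field"))
  length(x$x_nm)
}

#' @export
print.puncta_field <- function(x, ...) {
  cat(sprintf("<puncta_field> %d puncta, channel '%s', pixel %.3g nm\n",
              n_puncta(x), x$channel, x$pixel_size_nm))
  invisible(x)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %dx%d px, %.3g nm/px, PSF sigma %.3g nm, seed %d\n",
              x$width_px, x$height_px, x$pixel_size_nm, x$psf_sigma_nm,
              x$seed))
  invisible(x)
}

#' @export
print.mcs_mask <- function(x, ...) {
  cat(sprintf("<mcs_mask> kind '%s', %d/%d px set\n",
              x$kind, sum(x$data), length(x$data)))
  invisible(x)
}

#' @export
print.mcs_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mcs_image> %s, channel '%s', %s, bg-corrected: %s\n",
              paste(d, collapse = "x"), x$channel,
              sprintf("%.3g nm/px", x$pixel_size_nm),
              x$background_corrected))
  invisible(x)
}

# Deterministic seed fan-out: one global seed plus a stream counter gives an
# independent, reproducible seed per stochastic stage (Lehmer step keeps the
# value inside 32-bit signed range).
derive_seed <- function(global_seed, counter) {
  as.integer((as.numeric(global_seed) * 48271 + as.numeric(counter)) %%
               2147483647)
}

# Convert continuous nm coordinates to nearest 1-based pixel indices,
# clamped to the grid.
nm_to_px <- function(x_nm, y_nm, pixel_size_nm, width_px, height_px) {
  col <- pmin(pmax(round(x_nm / pixel_size_nm) + 1L, 1L), width_px)
  row <- pmin(pmax(round(y_nm / pixel_size_nm) + 1L, 1L), height_px)
  cbind(row = as.integer(row), col = as.integer(col))
}
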