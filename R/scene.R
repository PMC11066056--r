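#' Parametric description of a synthetic FISH microscopy field
#'
#' A `scene_spec` fixes everything that determines a rendered field: the
#' number of objects of each class, their sizes, per-class signal amplitudes
#' in the three channels (DNA / 16S rRNA / phage), optics (pixel size and
#' point-spread sigma), background and noise, and the RNG seed. The five
#' object classes mirror the populations distinguished by the gating rules:
#' uninfected SAR11 (DNA + rRNA), phage-infected SAR11 (DNA + rRNA + phage),
#' zombie cells (DNA + phage, no rRNA), other bacteria (DNA only by default;
#' rRNA-positive too when `eub_mode = TRUE`, emulating the general bacterial
#' EUB I-III probe), and free phage particles (phage only, sub-cellular
#' size).
#'
#' @param field_shape integer(2), image height and width in pixels.
#' @param pixel_size physical pixel size in micrometres.
#' @param n_uninfected_sar11,n_infected_sar11,n_zombie,n_other_bacteria,n_free_phage
#'   non-negative object counts per class.
#' @param dividing_fraction fraction in \[0,1\] of cells (all four cell
#'   classes) rendered with two DNA foci inside one elongated envelope,
#'   i.e. as dividing cells.
#' @param cell_diameter_range micrometres; ellipse axis diameters are drawn
#'   uniformly from this range (SAR11 are small cells, default 0.4-0.8 um).
#' @param free_phage_diameter micrometres; must be below the smallest cell
#'   diameter.
#' @param channel_amplitudes named list `class -> c(dna, rrna, phage)` of
#'   mean plateau amplitudes (8-bit intensity units) before blur; see
#'   [default_amplitudes()].
#' @param background_level,noise_sd per-channel constant background and
#'   additive Gaussian noise sd (intensity units; scalars are recycled to
#'   the three channels).
#' @param psf_sigma isotropic Gaussian point-spread sigma in micrometres.
#' @param ribosome_continuum_fraction fraction in \[0,1\] of infected cells
#'   drawn with a partially depleted rRNA amplitude, uniform between 0 and
#'   `continuum_max`, emulating the observed continuum of decreasing
#'   ribosomal content during infection.
#' @param continuum_max upper rRNA amplitude for depleted infected cells;
#'   defaults to the detection-threshold-equivalent (40 units).
#' @param dividing_elongation factor by which the major axis of a dividing
#'   cell is stretched (pre-division cells elongate).
#' @param eub_mode logical; when TRUE the rRNA channel represents the
#'   general bacterial probe, so `other_bacteria` are rRNA-positive.
#' @param overlap_budget micrometres by which padded object bounding disks
#'   may overlap during placement; 0 (default) enforces disjoint objects.
#' @param seed integer RNG seed; `NULL` uses the current RNG stream.
#'
#' @return an object of class `scene_spec` (a validated list).
#' @seealso [render_field()], [render_negative_control()]
#' @export
scene_spec <- function(field_shape = c(768L, 768L),
                       pixel_size = 0.065,
                       n_uninfected_sar11 = 120L,
                       n_infected_sar11 = 15L,
                       n_zombie = 8L,
                       n_other_bacteria = 60L,
                       n_free_phage = 40L,
                       dividing_fraction = 0.05,
                       cell_diameter_range = c(0.4, 0.8),
                       free_phage_diameter = 0.15,
                       channel_amplitudes = default_amplitudes(),
                       background_level = 10,
                       noise_sd = 3,
                       psf_sigma = 0.1,
                       ribosome_continuum_fraction = 0,
                       continuum_max = 40,
                       dividing_elongation = 1.7,
                       eub_mode = FALSE,
                       overlap_budget = 0,
                       seed = NULL) {
  counts <- c(uninfected_sar11 = as.integer(n_uninfected_sar11),
              infected_sar11 = as.integer(n_infected_sar11),
              zombie = as.integer(n_zombie),
              other_bacteria = as.integer(n_other_bacteria),
              free_phage = as.integer(n_free_phage))
  if (any(counts < 0)) stop("class counts must be non-negative")
  if (dividing_fraction < 0 || dividing_fraction > 1)
    stop("dividing_fraction must be in [0,1]")
  if (ribosome_continuum_fraction < 0 || ribosome_continuum_fraction > 1)
    stop("ribosome_continuum_fraction must be in [0,1]")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (length(cell_diameter_range) != 2 ||
      cell_diameter_range[1] <= 0 ||
      diff(cell_diameter_range) < 0)
    stop("cell_diameter_range must be an increasing positive pair")
  if (free_phage_diameter >= cell_diameter_range[1])
    stop("free_phage_diameter must be below the minimum cell diameter")
  background_level <- as.numeric(rep_len(background_level, 3))
  noise_sd <- as.numeric(rep_len(noise_sd, 3))
  if (any(background_level < 0) || any(noise_sd < 0))
    stop("background and noise must be non-negative")
  amps <- validate_amplitudes(channel_amplitudes)
  spec <- list(field_shape = as.integer(rep_len(field_shape, 2)),
               pixel_size = as.numeric(pixel_size),
               counts = counts,
               dividing_fraction = as.numeric(dividing_fraction),
               cell_diameter_range = as.numeric(cell_diameter_range),
               free_phage_diameter = as.numeric(free_phage_diameter),
               channel_amplitudes = amps,
               background_level = background_level,
               noise_sd = noise_sd,
               psf_sigma = as.numeric(psf_sigma),
               ribosome_continuum_fraction =
                 as.numeric(ribosome_continuum_fraction),
               continuum_max = as.numeric(continuum_max),
               dividing_elongation = as.numeric(dividing_elongation),
               eub_mode = isTRUE(eub_mode),
               overlap_budget = as.numeric(overlap_budget),
               seed = if (is.null(seed)) NULL else as.integer(seed))
  class(spec) <- "scene_spec"
  spec
}

scene_classes <- c("uninfected_sar11", "infected_sar11", "zombie",
                   "other_bacteria", "free_phage")
channel_names <- c("dna", "rrna", "phage")

#' Default per-class channel amplitudes
#'
#' Mean plateau intensity (8-bit units, before blur) per object class in the
#' dna / rrna / phage channels. Free phage carry a high nominal amplitude
#' because their sub-resolution size spreads the signal under the PSF.
#'
#' @return named list of length-3 numeric vectors.
#' @export
default_amplitudes <- function() {
  list(uninfected_sar11 = c(dna = 200, rrna = 180, phage = 0),
       infected_sar11   = c(dna = 200, rrna = 180, phage = 170),
       zombie           = c(dna = 200, rrna = 0,   phage = 170),
       other_bacteria   = c(dna = 200, rrna = 0,   phage = 0),
       free_phage       = c(dna = 0,   rrna = 0,   phage = 240))
}

validate_amplitudes <- function(amps) {
  if (!all(scene_classes %in% names(amps)))
    stop("channel_amplitudes must name all five classes")
  amps <- amps[scene_classes]
  amps <- lapply(amps, function(a) {
    a <- as.numeric(rep_len(a, 3))
    names(a) <- channel_names
    if (any(a < 0)) stop("amplitudes must be non-negative")
    a
  })
  amps
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("scene_spec:", paste(x$field_shape, collapse = " x "), "px @",
      x$pixel_size, "um/px\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "), "\n")
  cat("  dividing_fraction:", x$dividing_fraction,
      " psf_sigma:", x$psf_sigma, "um  noise_sd:",
      paste(x$noise_sd, collapse = "/"), "\n")
  invisible(x)
}

#' Serialize / restore a scene specification
#'
#' Scene specifications round-trip through a flat JSON file so that a
#' rendered dataset can be regenerated exactly.
#'
#' @param spec a `scene_spec`.
#' @param path file path.
#' @return `read_scene_spec` returns a `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  x$counts <- as.list(x$counts)
  x$channel_amplitudes <- lapply(x$channel_amplitudes, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  amps <- lapply(x$channel_amplitudes, unlist)
  scene_spec(field_shape = x$field_shape,
             pixel_size = x$pixel_size,
             n_uninfected_sar11 = x$counts[["uninfected_sar11"]],
             n_infected_sar11 = x$counts[["infected_sar11"]],
             n_zombie = x$counts[["zombie"]],
             n_other_bacteria = x$counts[["other_bacteria"]],
             n_free_phage = x$counts[["free_phage"]],
             dividing_fraction = x$dividing_fraction,
             cell_diameter_range = x$cell_diameter_range,
             free_phage_diameter = x$free_phage_diameter,
             channel_amplitudes = amps,
             background_level = x$background_level,
             noise_sd = x$noise_sd,
             psf_sigma = x$psf_sigma,
             ribosome_continuum_fraction = x$ribosome_continuum_fraction,
             continuum_max = x$continuum_max,
             dividing_elongation = x$dividing_elongation,
             eub_mode = x$eub_mode,
             overlap_budget = x$overlap_budget,
             seed = x$seed)
}
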