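#' Render a synthetic multi-channel FISH field
#'
#' Draws object geometry and placement from the scene specification, paints
#' each object as an axis-aligned ellipse plateau at its per-class channel
#' amplitude, convolves every channel with an isotropic Gaussian
#' point-spread function, and adds constant background plus additive
#' Gaussian noise (clipped at zero). Dividing cells are painted in the DNA
#' channel as a faint nucleoid envelope carrying two bright foci whose
#' centres are separated by 0.6-0.9 of the cell length, so they present two
#' local DNA maxima to the cytometry stage while remaining one connected
#' object.
#'
#' Placement is rejection sampling of padded bounding disks (padding covers
#' the PSF support), so objects are disjoint after blur unless an
#' `overlap_budget` is configured. Rendering is deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `field` (a `field_image`: matrices `dna`,
#'   `rrna`, `phage` plus `pixel_size`) and `truth` (the ground-truth
#'   data.frame, one row per rendered object: id, class, centroid in
#'   0-based pixel coordinates, nominal equivalent diameter, per-channel
#'   presence flags, dividing flag).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_field_impl(spec, phage_signal = TRUE))
}

#' Render a negative-control field
#'
#' Identical to [render_field()] except that no object carries phage-channel
#' amplitude: the phage plane contains background and noise only, emulating
#' control samples not exposed to the phage-probe mix (or exposed to probes
#' that do not target the phage present). Ground truth still records the
#' nominal class of every object.
#'
#' @inheritParams render_field
#' @return as [render_field()].
#' @export
render_negative_control <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_field_impl(spec, phage_signal = FALSE))
}

render_field_impl <- function(spec, phage_signal = TRUE) {
  h <- spec$field_shape[1]; w <- spec$field_shape[2]
  px <- spec$pixel_size
  psf_px <- spec$psf_sigma / px
  counts <- spec$counts
  n <- sum(counts)

  truth <- data.frame(id = integer(0), class = character(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      diameter_um = numeric(0), dna = logical(0),
                      rrna = logical(0), phage = logical(0),
                      dividing = logical(0))
  planes <- lapply(1:3, function(i) matrix(0, h, w))
  names(planes) <- channel_names

  if (n > 0) {
    cls <- rep(scene_classes, counts)
    is_cell <- cls != "free_phage"
    # geometry: ellipse semi-axes in pixels
    dr <- spec$cell_diameter_range / px
    a <- b <- numeric(n)
    a[is_cell] <- runif(sum(is_cell), dr[1], dr[2]) / 2
    b[is_cell] <- runif(sum(is_cell), dr[1], dr[2]) / 2
    fp_r <- spec$free_phage_diameter / px / 2
    a[!is_cell] <- b[!is_cell] <- fp_r
    dividing <- is_cell & runif(n) < spec$dividing_fraction
    # dividing cells elongate along their major axis
    elong <- spec$dividing_elongation
    maj_is_row <- a >= b
    a[dividing & maj_is_row] <- a[dividing & maj_is_row] * elong
    b[dividing & !maj_is_row] <- b[dividing & !maj_is_row] * elong
    sep_frac <- runif(n, 0.6, 0.9)   # foci separation / cell length

    # per-object channel amplitudes
    amp <- t(vapply(cls, function(cl) spec$channel_amplitudes[[cl]],
                    numeric(3)))
    colnames(amp) <- channel_names
    if (spec$eub_mode) {
      oth <- cls == "other_bacteria"
      amp[oth, "rrna"] <- spec$channel_amplitudes$uninfected_sar11[["rrna"]]
    }
    # ribosome continuum: some infected cells have depleted rRNA amplitude
    inf <- which(cls == "infected_sar11")
    depleted <- inf[runif(length(inf)) < spec$ribosome_continuum_fraction]
    if (length(depleted))
      amp[depleted, "rrna"] <- runif(length(depleted), 0, spec$continuum_max)
    if (!phage_signal) amp[, "phage"] <- 0

    # placement: rejection sampling of padded bounding disks
    pad <- ceiling(4 * psf_px) + 1
    rad <- pmax(a, b) + pad
    budget_px <- spec$overlap_budget / px
    ord <- order(rad, decreasing = TRUE)   # large objects first
    cy <- cx <- numeric(n)
    placed <- integer(0)
    for (i in ord) {
      r <- rad[i]
      if (2 * r + 2 > min(h, w))
        stop("infeasible packing: object larger than field")
      ok <- FALSE
      for (att in seq_len(2000L)) {
        yy <- runif(1, r + 1, h - r)
        xx <- runif(1, r + 1, w - r)
        if (length(placed)) {
          d2 <- (cy[placed] - yy)^2 + (cx[placed] - xx)^2
          lim <- (rad[placed] + r - budget_px)
          if (any(d2 < lim^2)) next
        }
        cy[i] <- yy; cx[i] <- xx; ok <- TRUE; break
      }
      if (!ok)
        stop("infeasible packing: could not place all objects within the ",
             "overlap budget; reduce counts or enlarge the field")
      placed <- c(placed, i)
    }

    # paint amplitude canvases; sub-resolution objects (free phage) are
    # painted coverage-weighted so their flux is placement-independent
    for (i in seq_len(n)) {
      small <- min(a[i], b[i]) < 2
      if (small) {
        cv <- ellipse_coverage(cy[i], cx[i], a[i], b[i], h, w)
        for (ch in channel_names) {
          A <- amp[i, ch]
          if (A > 0)
            planes[[ch]] <- paint(planes[[ch]], cv$idx, A * cv$wt)
        }
        next
      }
      env <- ellipse_pixels(cy[i], cx[i], a[i], b[i], h, w)
      for (ch in channel_names) {
        A <- amp[i, ch]
        if (A <= 0) next
        if (ch == "dna" && dividing[i]) {
          planes[[ch]] <- paint(planes[[ch]], env, 0.3 * A)
          L <- 2 * max(a[i], b[i])
          off <- sep_frac[i] * L / 2
          fr <- 0.2 * L                      # focus radius
          d_row <- if (maj_is_row[i]) off else 0
          d_col <- if (maj_is_row[i]) 0 else off
          f1 <- ellipse_pixels(cy[i] - d_row, cx[i] - d_col, fr, fr, h, w)
          f2 <- ellipse_pixels(cy[i] + d_row, cx[i] + d_col, fr, fr, h, w)
          planes[[ch]] <- paint(planes[[ch]], intersect(f1, env), A)
          planes[[ch]] <- paint(planes[[ch]], intersect(f2, env), A)
        } else {
          planes[[ch]] <- paint(planes[[ch]], env, A)
        }
      }
    }

    truth <- data.frame(id = seq_len(n), class = cls,
                        centroid_row = cy - 1, centroid_col = cx - 1,
                        diameter_um = 2 * sqrt(a * b) * px,
                        dna = amp[, "dna"] > 0,
                        rrna = amp[, "rrna"] > 0,
                        phage = amp[, "phage"] > 0,
                        dividing = dividing)
  }

  # optics + noise
  for (ch in seq_along(planes)) {
    pl <- gaussian_blur(planes[[ch]], psf_px)
    pl <- pl + spec$background_level[ch]
    if (spec$noise_sd[ch] > 0)
      pl <- pl + matrix(rnorm(h * w, 0, spec$noise_sd[ch]), h, w)
    planes[[ch]] <- pmax(pl, 0)
  }

  field <- structure(c(planes, list(pixel_size = px)),
                     class = "field_image")
  list(field = field, truth = truth)
}

# coverage-weighted pixels of a small ellipse (supersampled): for
# sub-resolution objects the painted flux must not depend on the subpixel
# position of the centre, so amplitude is scaled by fractional pixel
# coverage estimated on an ss x ss subgrid
ellipse_coverage <- function(cy, cx, a, b, h, w, ss = 4L) {
  r0 <- max(1L, floor(cy - a - 1)); r1 <- min(h, ceiling(cy + a + 1))
  c0 <- max(1L, floor(cx - b - 1)); c1 <- min(w, ceiling(cx + b + 1))
  if (r0 > r1 || c0 > c1) return(list(idx = integer(0), wt = numeric(0)))
  rows <- r0:r1; cols <- c0:c1
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  cov <- matrix(0, length(rows), length(cols))
  for (dy in sub) for (dx in sub) {
    dr2 <- ((rows + dy - cy) / a)^2
    dc2 <- ((cols + dx - cx) / b)^2
    cov <- cov + (outer(dr2, dc2, `+`) <= 1)
  }
  cov <- cov / ss^2
  keep <- which(cov > 0)
  rr <- rows[(keep - 1) %% length(rows) + 1]
  cc <- cols[(keep - 1) %/% length(rows) + 1]
  list(idx = (cc - 1L) * h + rr, wt = cov[keep])
}

# linear indices of the pixels inside an axis-aligned ellipse
ellipse_pixels <- function(cy, cx, a, b, h, w) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
  c0 <- max(1L, floor(cx - b)); c1 <- min(w, ceiling(cx + b))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dr2 <- ((rows - cy) / a)^2
  dc2 <- ((cols - cx) / b)^2
  inside <- outer(dr2, dc2, `+`) <= 1
  idx <- which(inside)
  rr <- rows[(idx - 1) %% length(rows) + 1]
  cc <- cols[(idx - 1) %/% length(rows) + 1]
  (cc - 1L) * h + rr
}

# max-composite amplitude into a channel plane
paint <- function(plane, idx, A) {
  if (length(idx)) plane[idx] <- pmax(plane[idx], A)
  plane
}

#' Render a day-indexed series of synthetic fields
#'
#' @param day_specs a list of `list(day = <number>, spec = <scene_spec>)`
#'   entries with strictly increasing, unique days.
#' @return list with `fields` (named list of [render_field()] results, one
#'   per day) and `truth` (data.frame of per-day true fractions: infected
#'   fraction of SAR11, zombie fraction of all cells, SAR11 fraction of all
#'   cells, dividing fraction of all cells).
#' @export
render_timeseries <- function(day_specs) {
  if (!length(day_specs)) stop("day_specs must be non-empty")
  days <- vapply(day_specs, function(d) as.numeric(d$day), numeric(1))
  if (anyDuplicated(days)) stop("duplicate days in day_specs")
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing")
  fields <- lapply(day_specs, function(d) render_field(d$spec))
  names(fields) <- paste0("day_", days)
  truth <- do.call(rbind, lapply(seq_along(day_specs), function(i) {
    tr <- fields[[i]]$truth
    # SAR11 here means rRNA-detectable SAR11 (uninfected + infected), the
    # denominator the cytometry stage can actually observe; zombies lack
    # the 16S signal and are referenced to total cells instead.
    n_sar11 <- sum(tr$class %in% c("uninfected_sar11", "infected_sar11"))
    n_cells <- sum(tr$class != "free_phage")
    data.frame(day = days[i],
               true_infected_fraction =
                 if (n_sar11 > 0)
                   sum(tr$class == "infected_sar11") / n_sar11 else NA_real_,
               true_zombie_fraction =
                 if (n_cells > 0)
                   sum(tr$class == "zombie") / n_cells else NA_real_,
               true_sar11_fraction =
                 if (n_cells > 0) n_sar11 / n_cells else NA_real_,
               true_dividing_fraction =
                 if (n_cells > 0) sum(tr$dividing) / n_cells else NA_real_)
  }))
  list(fields = fields, truth = truth)
}
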