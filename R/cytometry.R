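#' Gating configuration for image cytometry
#'
#' Holds the per-channel detection thresholds, connectivity, size gates and
#' dividing-cell (DNA maxima) settings used by [segment_objects()],
#' [classify_objects()] and [count_dna_maxima()].
#'
#' The default threshold rule is `background + max(k * sigma, floor)` per
#' channel, where background is the channel median (the modal value in
#' sparse fields), sigma is the MAD-based robust standard deviation, `k = 5`,
#' and `floor` is an absolute guard (40 intensity units on the 8-bit scale).
#' The floor keeps the rule meaningful in the noise-free limit (sigma = 0)
#' and keeps the point-spread halo of bright sub-resolution particles from
#' inflating their apparent area past the free-phage size gate.
#'
#' @param threshold_rule `"bg_ksigma"` (default) or `"absolute"`.
#' @param k multiplier on the robust sigma (> 0).
#' @param threshold_floor minimum threshold elevation above background,
#'   intensity units.
#' @param abs_thresholds named numeric `c(dna=, rrna=, phage=)`, used when
#'   `threshold_rule = "absolute"`.
#' @param connectivity 4 or 8 (default) for connected components.
#' @param min_cell_area,max_cell_area plausible cell area bounds, um^2.
#' @param free_phage_max_area objects with area at or below this (um^2) are
#'   sub-cellular: free phage particles or vesicles, never cells. Phage
#'   capsids are < 100 nm, far below the default 0.05 um^2 (equivalent
#'   diameter ~0.25 um).
#' @param maxima_smooth_sigma Gaussian smoothing (um) applied to the DNA
#'   plane before local-maxima counting.
#' @param maxima_min_prominence minimum topographic prominence (intensity
#'   units) for a DNA intensity peak to count as a separate maximum.
#' @param positivity `"mean"` (default) or `"max"`: whether an object is
#'   channel-positive when its mean or its max intensity over the mask
#'   exceeds the channel threshold.
#' @return a `gate_config`.
#' @export
gate_config <- function(threshold_rule = c("bg_ksigma", "absolute"),
                        k = 5,
                        threshold_floor = 40,
                        abs_thresholds = c(dna = 50, rrna = 50, phage = 50),
                        connectivity = 8,
                        min_cell_area = 0.1,
                        max_cell_area = 3,
                        free_phage_max_area = 0.05,
                        maxima_smooth_sigma = 0.03,
                        maxima_min_prominence = 20,
                        positivity = c("mean", "max")) {
  threshold_rule <- match.arg(threshold_rule)
  positivity <- match.arg(positivity)
  if (k <= 0) stop("k must be > 0")
  if (!(connectivity %in% c(4, 8))) stop("connectivity must be 4 or 8")
  if (!(free_phage_max_area > 0 && free_phage_max_area < min_cell_area &&
        min_cell_area < max_cell_area))
    stop("need 0 < free_phage_max_area < min_cell_area < max_cell_area")
  structure(list(threshold_rule = threshold_rule, k = k,
                 threshold_floor = threshold_floor,
                 abs_thresholds = abs_thresholds,
                 connectivity = as.integer(connectivity),
                 min_cell_area = min_cell_area,
                 max_cell_area = max_cell_area,
                 free_phage_max_area = free_phage_max_area,
                 maxima_smooth_sigma = maxima_smooth_sigma,
                 maxima_min_prominence = maxima_min_prominence,
                 positivity = positivity),
            class = "gate_config")
}

# per-channel detection thresholds for a field
channel_thresholds <- function(field, cfg) {
  if (cfg$threshold_rule == "absolute")
    return(cfg$abs_thresholds[channel_names])
  th <- vapply(channel_names, function(ch) {
    v <- field[[ch]]
    bg <- median(v)
    sig <- mad(v)   # robust sigma, 0 in the noise-free limit
    bg + max(cfg$k * sig, cfg$threshold_floor)
  }, numeric(1))
  th
}

#' Segment objects from a multi-channel field
#'
#' Objects are connected components (4- or 8-connectivity per the gate
#' configuration) of the union of the per-channel threshold masks. Each
#' object carries its pixel mask, area, centroid, per-channel mean and max
#' intensities, channel-positivity flags and a sub-cellular marker (area at
#' or below the free-phage size gate). Sub-cellular objects are retained;
#' classification and tabulation decide their fate.
#'
#' @param field a `field_image`.
#' @param cfg a [gate_config()].
#' @return a `cyto_seg`: list with `table` (one row per object), `masks`
#'   (list of linear pixel indices into the planes), `thresholds` (the
#'   per-channel thresholds used) and `dim`.
#' @export
segment_objects <- function(field, cfg = gate_config()) {
  stopifnot(inherits(field, "field_image"), inherits(cfg, "gate_config"))
  th <- channel_thresholds(field, cfg)
  h <- nrow(field$dna); w <- ncol(field$dna)
  mask <- (field$dna > th[["dna"]]) | (field$rrna > th[["rrna"]]) |
    (field$phage > th[["phage"]])
  idx <- which(mask)
  empty <- data.frame(id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), eq_diameter = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mean_dna = numeric(0), max_dna = numeric(0),
                      mean_rrna = numeric(0), max_rrna = numeric(0),
                      mean_phage = numeric(0), max_phage = numeric(0),
                      pos_dna = logical(0), pos_rrna = logical(0),
                      pos_phage = logical(0), subcellular = logical(0))
  if (!length(idx))
    return(structure(list(table = empty, masks = list(), thresholds = th,
                          dim = c(h, w), pixel_size = field$pixel_size),
                     class = "cyto_seg"))

  membership <- label_components(mask, idx, cfg$connectivity)
  masks <- split(idx, membership)
  names(masks) <- NULL

  px2 <- field$pixel_size^2
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  area_px <- lengths(masks)
  stat <- function(plane, f) vapply(masks, function(m) f(plane[m]),
                                    numeric(1))
  tab <- data.frame(
    id = seq_along(masks),
    area_px = as.integer(area_px),
    area_um2 = area_px * px2,
    eq_diameter = 2 * sqrt(area_px * px2 / pi),
    centroid_row = vapply(split(rows, membership), mean, numeric(1)) - 1,
    centroid_col = vapply(split(cols, membership), mean, numeric(1)) - 1,
    mean_dna = stat(field$dna, mean), max_dna = stat(field$dna, max),
    mean_rrna = stat(field$rrna, mean), max_rrna = stat(field$rrna, max),
    mean_phage = stat(field$phage, mean), max_phage = stat(field$phage, max)
  )
  pos_stat <- if (cfg$positivity == "mean") "mean_" else "max_"
  for (ch in channel_names)
    tab[[paste0("pos_", ch)]] <- tab[[paste0(pos_stat, ch)]] > th[[ch]]
  tab$subcellular <- tab$area_um2 <= cfg$free_phage_max_area
  rownames(tab) <- NULL
  structure(list(table = tab, masks = masks, thresholds = th,
                 dim = c(h, w), pixel_size = field$pixel_size),
            class = "cyto_seg")
}

# connected-component labelling of foreground pixels via a pixel-adjacency
# graph (igraph); returns membership aligned with `idx`
label_components <- function(mask, idx, connectivity) {
  h <- nrow(mask); w <- ncol(mask)
  vmap <- integer(h * w)
  vmap[idx] <- seq_along(idx)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  e_from <- integer(0); e_to <- integer(0)
  for (off in offs) {
    ok <- rows + off[1] >= 1L & rows + off[1] <= h & cols + off[2] <= w
    nidx <- idx[ok] + off[1] + off[2] * h
    hit <- mask[nidx]
    e_from <- c(e_from, vmap[idx[ok]][hit])
    e_to <- c(e_to, vmap[nidx[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(e_from))
    g <- igraph::add_edges(g, rbind(e_from, e_to))
  igraph::components(g)$membership
}

#' Classify a segmented object by its channel flags and size
#'
#' Implements the gating partition: DNA+ rRNA+ phage- cells are SAR11;
#' DNA+ rRNA+ phage+ cells are phage-infected SAR11; phage+ rRNA- objects
#' above the free-phage size gate that contain DNA are zombie cells
#' (phage-infected but ribosome-deprived; zombies always contain DNA);
#' phage+ objects at or below the size gate are free phage particles or
#' vesicles (too small to be cells); DNA-only objects count toward total
#' cells only; anything else (including objects above `max_cell_area`,
#' treated as aggregates) is rejected.
#'
#' @param pos_dna,pos_rrna,pos_phage logical channel-positivity flags
#'   (vectorized).
#' @param area_um2 object area(s), um^2.
#' @param cfg a [gate_config()].
#' @return character vector of labels in `total_only`, `sar11`,
#'   `infected_sar11`, `zombie`, `free_phage_or_vesicle`, `rejected`.
#' @export
classify_object <- function(pos_dna, pos_rrna, pos_phage, area_um2,
                            cfg = gate_config()) {
  n <- length(pos_dna)
  stopifnot(length(pos_rrna) == n, length(pos_phage) == n,
            length(area_um2) == n)
  big <- area_um2 > cfg$free_phage_max_area
  lab <- rep("rejected", n)
  lab[pos_phage & !big] <- "free_phage_or_vesicle"
  lab[pos_dna & !pos_rrna & !pos_phage & big] <- "total_only"
  lab[pos_dna & pos_rrna & !pos_phage & big] <- "sar11"
  lab[pos_dna & pos_rrna & pos_phage & big] <- "infected_sar11"
  lab[pos_dna & !pos_rrna & pos_phage & big] <- "zombie"
  lab[area_um2 > cfg$max_cell_area] <- "rejected"
  lab
}

#' Attach class labels to a segmentation
#'
#' @param seg a `cyto_seg` from [segment_objects()].
#' @param cfg a [gate_config()].
#' @return the `cyto_seg` with a `label` column added to `seg$table`.
#' @export
classify_objects <- function(seg, cfg = gate_config()) {
  stopifnot(inherits(seg, "cyto_seg"))
  tab <- seg$table
  seg$table$label <- classify_object(tab$pos_dna, tab$pos_rrna,
                                     tab$pos_phage, tab$area_um2, cfg)
  seg
}

#' Count local DNA maxima within one object mask
#'
#' The DNA plane is Gaussian-smoothed (`maxima_smooth_sigma`), restricted to
#' the object mask, and its topographic peaks are counted by descending
#' water-level accretion: pixels are visited from brightest to dimmest; a
#' pixel with no brighter neighbour seeds a peak, and when two peaks meet at
#' a saddle the lower one is kept only if its prominence (peak height minus
#' saddle height) reaches `maxima_min_prominence`. Equal-intensity plateaus
#' merge into a single maximum. A cell with exactly two local DNA maxima is
#' a dividing cell.
#'
#' @param mask_idx integer vector of linear pixel indices of the object (as
#'   stored in `seg$masks`).
#' @param dna_plane the DNA intensity matrix the mask indexes into.
#' @param cfg a [gate_config()].
#' @param pixel_size um per pixel, to convert the smoothing sigma.
#' @param presmoothed set TRUE when `dna_plane` is already smoothed (used
#'   by [annotate_dna_maxima()] to smooth once per field).
#' @return integer number of prominent local maxima (>= 1).
#' @export
count_dna_maxima <- function(mask_idx, dna_plane, cfg = gate_config(),
                             pixel_size = 0.065, presmoothed = FALSE) {
  if (!length(mask_idx)) stop("empty object mask")
  sm <- if (presmoothed) dna_plane else
    gaussian_blur(dna_plane, cfg$maxima_smooth_sigma / pixel_size)
  h <- nrow(sm); w <- ncol(sm)
  v <- sm[mask_idx]
  ord <- order(v, decreasing = TRUE)
  # neighbour lookup restricted to the mask, border-safe: an n x 8 matrix
  # of mask positions (0 = not in mask / outside image)
  inmask <- integer(length(sm))
  inmask[mask_idx] <- seq_along(mask_idx)
  rr <- (mask_idx - 1L) %% h + 1L
  cc <- (mask_idx - 1L) %/% h + 1L
  nb_d <- cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  nb_mat <- matrix(0L, length(mask_idx), 8L)
  for (j in 1:8) {
    r2 <- rr + nb_d[j, 1]; c2 <- cc + nb_d[j, 2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb_mat[ok, j] <- inmask[(c2[ok] - 1L) * h + r2[ok]]
  }
  peak_of <- integer(length(mask_idx))   # 0 = unvisited
  peak_height <- numeric(0)
  peak_alive <- logical(0)
  n_prominent <- 0L
  find_root <- function(p, parent) {
    while (parent[p] != p) p <- parent[p]
    p
  }
  parent <- integer(0)
  for (o in ord) {
    nb <- nb_mat[o, ]
    nb <- nb[nb > 0L]
    nb_peaks <- unique(peak_of[nb][peak_of[nb] > 0L])
    if (length(nb_peaks))
      nb_peaks <- unique(vapply(nb_peaks, find_root, integer(1),
                                parent = parent))
    if (!length(nb_peaks)) {
      # new peak seed
      peak_height <- c(peak_height, v[o])
      parent <- c(parent, length(peak_height))
      peak_of[o] <- length(peak_height)
    } else if (length(nb_peaks) == 1L) {
      peak_of[o] <- nb_peaks
    } else {
      # saddle: merge all meeting peaks into the tallest
      tallest <- nb_peaks[which.max(peak_height[nb_peaks])]
      for (p in setdiff(nb_peaks, tallest)) {
        if (peak_height[p] - v[o] >= cfg$maxima_min_prominence)
          n_prominent <- n_prominent + 1L
        parent[p] <- tallest
      }
      peak_of[o] <- tallest
    }
  }
  # the global maximum always counts
  n_prominent + 1L
}

#' Count DNA maxima for every DNA-positive object
#'
#' Smooths the DNA plane once and applies [count_dna_maxima()] to each
#' DNA-positive, non-sub-cellular object; adds `dna_maxima` (NA for objects
#' not assessed) and `dividing` (exactly two maxima) columns.
#'
#' @param seg a classified `cyto_seg`.
#' @param field the `field_image` the segmentation came from.
#' @param cfg a [gate_config()].
#' @return the `cyto_seg` with `dna_maxima` and `dividing` columns.
#' @export
annotate_dna_maxima <- function(seg, field, cfg = gate_config()) {
  stopifnot(inherits(seg, "cyto_seg"), inherits(field, "field_image"))
  tab <- seg$table
  sm <- gaussian_blur(field$dna, cfg$maxima_smooth_sigma / field$pixel_size)
  nmax <- rep(NA_integer_, nrow(tab))
  assess <- which(tab$pos_dna & !tab$subcellular)
  for (i in assess)
    nmax[i] <- count_dna_maxima(seg$masks[[i]], sm, cfg,
                                pixel_size = field$pixel_size,
                                presmoothed = TRUE)
  seg$table$dna_maxima <- nmax
  seg$table$dividing <- !is.na(nmax) & nmax == 2L
  seg
}

#' Tabulate classified objects into cytometry counts and ratios
#'
#' Total cells are DNA-positive objects above the free-phage size gate
#' (total-only + SAR11 + infected + zombie). SAR11 cell counts include
#' infected cells (infected cells are SAR11 cells). Derived ratios use the
#' denominators of the survey: infected relative to SAR11 cells, zombies
#' and SAR11 relative to total cells, and the frequency of dividing cells
#' (FDC) relative to total cells. Ratios with a zero denominator are NA and
#' flagged, never silently zero.
#'
#' @param seg a classified (and optionally maxima-annotated) `cyto_seg`, or
#'   its `table`.
#' @return a `cytometry_result`: one-row data.frame with counts
#'   (`total_cells`, `sar11_cells`, `infected_cells`, `zombie_cells`,
#'   `dividing_cells`, `free_phage_objects`, `excluded_small_objects`,
#'   `rejected_objects`), derived ratios (`rel_infected`, `rel_zombie`,
#'   `rel_sar11`, `fdc`) and `undefined` flags.
#' @export
tabulate_counts <- function(seg) {
  tab <- if (inherits(seg, "cyto_seg")) seg$table else seg
  if (is.null(tab$label)) stop("objects are not classified yet")
  if (is.null(tab$dividing)) tab$dividing <- logical(nrow(tab))
  n_inf <- sum(tab$label == "infected_sar11")
  n_sar <- sum(tab$label == "sar11") + n_inf
  n_zom <- sum(tab$label == "zombie")
  n_tot <- sum(tab$label == "total_only") + n_sar + n_zom
  n_div <- sum(tab$dividing & tab$label %in%
                 c("total_only", "sar11", "infected_sar11", "zombie"))
  res <- data.frame(
    total_cells = n_tot, sar11_cells = n_sar, infected_cells = n_inf,
    zombie_cells = n_zom, dividing_cells = n_div,
    free_phage_objects = sum(tab$label == "free_phage_or_vesicle"),
    excluded_small_objects = sum(tab$subcellular %||% FALSE),
    rejected_objects = sum(tab$label == "rejected"),
    rel_infected = if (n_sar > 0) n_inf / n_sar else NA_real_,
    rel_zombie = if (n_tot > 0) n_zom / n_tot else NA_real_,
    rel_sar11 = if (n_tot > 0) n_sar / n_tot else NA_real_,
    fdc = if (n_tot > 0) n_div / n_tot else NA_real_,
    undefined_rel_infected = n_sar == 0,
    undefined_totals = n_tot == 0)
  class(res) <- c("cytometry_result", "data.frame")
  res
}

#' Run the full cytometry chain over one or more fields
#'
#' Segments, classifies and maxima-annotates each field, pools the object
#' counts across fields (a sample is typically many fields of view), and
#' computes the pooled ratios. Per-field results are attached for audit.
#'
#' @param fields a `field_image`, a list of them, or a list of
#'   [render_field()] results.
#' @param cfg a [gate_config()].
#' @param count_maxima logical; skip DNA-maxima annotation (the slowest
#'   step) when FDC is not needed.
#' @return a `cytometry_result` with attribute `per_field` (data.frame of
#'   per-field counts).
#' @export
run_cytometry <- function(fields, cfg = gate_config(), count_maxima = TRUE) {
  if (inherits(fields, "field_image")) fields <- list(fields)
  fields <- lapply(fields, function(f) {
    if (is.list(f) && !inherits(f, "field_image") && !is.null(f$field))
      f$field else f
  })
  if (!length(fields)) stop("need at least one field")
  stopifnot(all(vapply(fields, inherits, logical(1), "field_image")))
  tabs <- lapply(fields, function(f) {
    seg <- classify_objects(segment_objects(f, cfg), cfg)
    if (count_maxima) seg <- annotate_dna_maxima(seg, f, cfg)
    seg$table
  })
  per_field <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    r <- tabulate_counts(tabs[[i]])
    cbind(field = i, as.data.frame(r))
  }))
  pooled <- tabulate_counts(do.call(rbind, tabs))
  attr(pooled, "per_field") <- per_field
  pooled
}

#' @export
print.cytometry_result <- function(x, ...) {
  cat("cytometry_result: ", x$total_cells, " cells (",
      x$sar11_cells, " SAR11, ", x$infected_cells, " infected, ",
      x$zombie_cells, " zombie, ", x$dividing_cells, " dividing); ",
      x$free_phage_objects, " free phage/vesicle objects\n", sep = "")
  cat(sprintf("  rel_infected=%.4f rel_zombie=%.4f rel_sar11=%.4f fdc=%.4f\n",
              x$rel_infected, x$rel_zombie, x$rel_sar11, x$fdc))
  invisible(x)
}
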