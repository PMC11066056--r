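test_that("empty scene renders background plus noise only", {
  sp <- scene_spec(field_shape = c(64L, 64L), n_uninfected_sar11 = 0,
                   n_infected_sar11 = 0, n_zombie = 0,
                   n_other_bacteria = 0, n_free_phage = 0,
                   noise_sd = 0, seed = 1)
  rf <- render_field(sp)
  expect_equal(nrow(rf$truth), 0)
  for (ch in c("dna", "rrna", "phage"))
    expect_true(all(rf$field[[ch]] == sp$background_level[1]))
})

test_that("object count is conserved and rendering is deterministic", {
  sp <- scene_spec(field_shape = c(640L, 640L), n_uninfected_sar11 = 40,
                   n_infected_sar11 = 25, n_zombie = 15,
                   n_other_bacteria = 10, n_free_phage = 10, seed = 42)
  r1 <- render_field(sp)
  expect_equal(nrow(r1$truth), 100)
  expect_equal(as.vector(table(r1$truth$class)[c(
    "uninfected_sar11", "infected_sar11", "zombie", "other_bacteria",
    "free_phage")]), c(40, 25, 15, 10, 10))
  r2 <- render_field(sp)
  expect_identical(r1, r2)   # bit-identical images and truth
  r3 <- render_field(scene_spec(field_shape = c(640L, 640L),
                                n_uninfected_sar11 = 40,
                                n_infected_sar11 = 25, n_zombie = 15,
                                n_other_bacteria = 10, n_free_phage = 10,
                                seed = 43))
  expect_false(identical(r1$field$dna, r3$field$dna))
})

test_that("noise-free rendering matches a brute-force convolution oracle", {
  # circular cells (degenerate diameter range) so the painted support can
  # be reconstructed exactly from the ground-truth centroid and diameter
  sp <- scene_spec(field_shape = c(96L, 96L), n_uninfected_sar11 = 3,
                   n_infected_sar11 = 0, n_zombie = 0,
                   n_other_bacteria = 0, n_free_phage = 0,
                   dividing_fraction = 0, noise_sd = 0,
                   cell_diameter_range = c(0.6, 0.6), seed = 7)
  rf <- render_field(sp)
  px <- sp$pixel_size
  sig <- sp$psf_sigma / px
  half <- max(1L, as.integer(ceiling(4 * sig)))
  kern <- outer(dnorm(-half:half, sd = sig), dnorm(-half:half, sd = sig))
  kern <- kern / sum(kern)
  amp <- sp$channel_amplitudes$uninfected_sar11[["dna"]]
  h <- 96L; w <- 96L
  canvas <- matrix(0, h, w)
  r_px <- 0.3 / px
  for (i in seq_len(nrow(rf$truth))) {
    cy <- rf$truth$centroid_row[i] + 1
    cx <- rf$truth$centroid_col[i] + 1
    for (rr in 1:h) for (cc in 1:w)
      if (((rr - cy) / r_px)^2 + ((cc - cx) / r_px)^2 <= 1)
        canvas[rr, cc] <- amp
  }
  # direct convolution: explicit sum of kernel-weighted shifts, zero pad
  oracle <- matrix(0, h, w)
  for (a in -half:half) for (b in -half:half) {
    kv <- kern[a + half + 1, b + half + 1]
    src_r <- max(1, 1 + a):min(h, h + a)
    src_c <- max(1, 1 + b):min(w, w + b)
    oracle[src_r - a, src_c - b] <- oracle[src_r - a, src_c - b] +
      kv * canvas[src_r, src_c]
  }
  oracle <- oracle + sp$background_level[1]
  expect_equal(rf$field$dna, oracle, tolerance = 1e-10)
  # per-object mean equals amplitude + background up to PSF attenuation
  seg <- segment_objects(rf$field)
  expect_true(all(abs(seg$table$mean_dna - (amp + sp$background_level[1]))
                  < 0.45 * amp))
})

test_that("negative control carries no object signal in the phage plane", {
  sp <- scene_spec(field_shape = c(448L, 448L), n_uninfected_sar11 = 20,
                   n_infected_sar11 = 50, n_zombie = 10,
                   n_other_bacteria = 10, n_free_phage = 10, seed = 3)
  nc <- render_negative_control(sp)
  # ground truth still labels nominal classes
  expect_equal(sum(nc$truth$class == "infected_sar11"), 50)
  # phage plane is background + noise only: bounded by bg + k sigma
  expect_lt(max(nc$field$phage),
            sp$background_level[3] + 6 * sp$noise_sd[3])
  expect_identical(nc, render_negative_control(sp))   # reproducible
  # dna / rrna planes still carry objects
  expect_gt(max(nc$field$dna), 100)
})

test_that("infeasible packing raises an explicit error", {
  sp <- scene_spec(field_shape = c(64L, 64L), n_uninfected_sar11 = 400,
                   n_infected_sar11 = 0, n_zombie = 0,
                   n_other_bacteria = 0, n_free_phage = 0, seed = 1)
  expect_error(render_field(sp), "infeasible packing")
})

test_that("render_timeseries echoes per-day fractions and validates days", {
  mk <- function(n_inf, n_uninf, seed)
    scene_spec(field_shape = c(448L, 448L), n_uninfected_sar11 = n_uninf,
               n_infected_sar11 = n_inf, n_zombie = 2,
               n_other_bacteria = 10, n_free_phage = 5, seed = seed)
  fr <- c(0.01, 0.05, 0.19, 0.05, 0.01)
  n_sar <- 100
  specs <- lapply(seq_along(fr), function(i)
    list(day = i, spec = mk(round(fr[i] * n_sar),
                            n_sar - round(fr[i] * n_sar), 10 + i)))
  ts <- render_timeseries(specs)
  expect_equal(ts$truth$true_infected_fraction,
               round(fr * n_sar) / n_sar, tolerance = 1e-12)
  expect_error(render_timeseries(list()), "non-empty")
  expect_error(render_timeseries(specs[c(1, 1)]), "duplicate")
  expect_identical(render_timeseries(specs)$fields[[3]], ts$fields[[3]])
})

test_that("noise-free signal contract holds per class", {
  rf <- render_field(small_scene(21))
  tr <- rf$truth
  # free phage diameter below the configured cell minimum
  expect_true(all(tr$diameter_um[tr$class == "free_phage"] < 0.4))
  # channel-presence flags follow the class definitions
  expect_true(all(!tr$rrna[tr$class == "zombie"]))
  expect_true(all(tr$phage[tr$class == "zombie"]))
  expect_true(all(!tr$phage[tr$class == "uninfected_sar11"]))
  expect_true(all(!tr$dna[tr$class == "free_phage"]))
})

test_that("ribosome continuum depletes rRNA below the detection gate", {
  sp <- scene_spec(field_shape = c(448L, 448L), n_uninfected_sar11 = 0,
                   n_infected_sar11 = 40, n_zombie = 0,
                   n_other_bacteria = 0, n_free_phage = 0, noise_sd = 0,
                   ribosome_continuum_fraction = 1, seed = 8)
  rf <- render_field(sp)
  res <- run_cytometry(list(rf), count_maxima = FALSE)
  # fully depleted infected cells present as zombies to the classifier
  expect_equal(res$infected_cells + res$zombie_cells, 40)
  expect_gt(res$zombie_cells, 20)
})
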