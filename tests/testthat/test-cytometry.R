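test_that("segmentation finds each disjoint object exactly once", {
  sp <- scene_spec(field_shape = c(448L, 448L), n_uninfected_sar11 = 12,
                   n_infected_sar11 = 4, n_zombie = 2,
                   n_other_bacteria = 2, n_free_phage = 0, noise_sd = 0,
                   seed = 31)
  rf <- render_field(sp)
  seg <- segment_objects(rf$field)
  expect_equal(nrow(seg$table), 20)
  # masks agree with an independent flood-fill oracle on the union mask
  th <- seg$thresholds
  mask <- (rf$field$dna > th[["dna"]]) | (rf$field$rrna > th[["rrna"]]) |
    (rf$field$phage > th[["phage"]])
  oracle_labels <- flood_fill_components(mask, connectivity = 8)
  expect_equal(max(oracle_labels), 20)
  for (m in seg$masks)
    expect_equal(length(unique(oracle_labels[m])), 1)
})

test_that("uniform background yields zero objects", {
  f <- field_image(matrix(10, 64, 64), matrix(10, 64, 64),
                   matrix(10, 64, 64), 0.065)
  seg <- segment_objects(f)
  expect_equal(nrow(seg$table), 0)
  # threshold above image max as well
  f2 <- field_image(matrix(30, 64, 64), matrix(30, 64, 64),
                    matrix(30, 64, 64), 0.065)
  cfg <- gate_config(threshold_rule = "absolute",
                     abs_thresholds = c(dna = 100, rrna = 100, phage = 100))
  expect_equal(nrow(segment_objects(f2, cfg)$table), 0)
})

test_that("connectivity setting separates corner-touching blobs", {
  dna <- matrix(0, 32, 32)
  dna[5:10, 5:10] <- 200       # blob A
  dna[11:16, 11:16] <- 200     # blob B touches A corner-to-corner
  f <- field_image(dna, matrix(0, 32, 32), matrix(0, 32, 32), 0.065)
  cfg4 <- gate_config(threshold_rule = "absolute", connectivity = 4,
                      abs_thresholds = c(dna = 50, rrna = 50, phage = 50))
  cfg8 <- gate_config(threshold_rule = "absolute", connectivity = 8,
                      abs_thresholds = c(dna = 50, rrna = 50, phage = 50))
  expect_equal(nrow(segment_objects(f, cfg4)$table), 2)
  expect_equal(nrow(segment_objects(f, cfg8)$table), 1)
})

test_that("classification implements the gating rules", {
  cfg <- gate_config()
  # infected: all three channels, cell-sized
  expect_equal(classify_object(TRUE, TRUE, TRUE, 0.3, cfg),
               "infected_sar11")
  # zombie: phage signal, no rRNA, above the free-phage gate, contains DNA
  expect_equal(classify_object(TRUE, FALSE, TRUE, 0.3, cfg), "zombie")
  # free phage / vesicle: phage signal at or below the size gate
  expect_equal(classify_object(FALSE, FALSE, TRUE, 0.04, cfg),
               "free_phage_or_vesicle")
  expect_equal(classify_object(TRUE, TRUE, FALSE, 0.3, cfg), "sar11")
  expect_equal(classify_object(TRUE, FALSE, FALSE, 0.3, cfg), "total_only")
  # phage-positive large object without DNA is rejected, not a zombie
  expect_equal(classify_object(FALSE, FALSE, TRUE, 0.3, cfg), "rejected")
  # aggregates above max_cell_area are rejected
  expect_equal(classify_object(TRUE, TRUE, FALSE, 5, cfg), "rejected")
})

test_that("every flag/size combination receives exactly one label", {
  cfg <- gate_config()
  combos <- expand.grid(dna = c(TRUE, FALSE), rrna = c(TRUE, FALSE),
                        phage = c(TRUE, FALSE),
                        area = c(0.02, 0.3, 5))
  lab <- classify_object(combos$dna, combos$rrna, combos$phage,
                         combos$area, cfg)
  expect_equal(length(lab), nrow(combos))
  expect_true(all(lab %in% c("total_only", "sar11", "infected_sar11",
                             "zombie", "free_phage_or_vesicle",
                             "rejected")))
})

test_that("tabulation uses the survey's denominators", {
  tab <- data.frame(
    label = c(rep("sar11", 10), rep("infected_sar11", 2), "zombie",
              rep("total_only", 3)),
    subcellular = FALSE, dividing = FALSE)
  res <- tabulate_counts(tab)
  expect_equal(res$total_cells, 16)
  expect_equal(res$sar11_cells, 12)       # infected cells are SAR11 cells
  expect_equal(res$rel_infected, 2 / 12)
  expect_equal(res$rel_zombie, 1 / 16)
  # zero denominators flagged, not silently zero
  res0 <- tabulate_counts(data.frame(label = "zombie", subcellular = FALSE,
                                     dividing = FALSE))
  expect_true(is.na(res0$rel_infected))
  expect_true(res0$undefined_rel_infected)
  # all SAR11: upper bound
  res1 <- tabulate_counts(data.frame(label = rep("sar11", 5),
                                     subcellular = FALSE,
                                     dividing = FALSE))
  expect_equal(res1$rel_sar11, 1)
})

test_that("pooling across fields is linear and reduces to tabulate", {
  rf <- render_field(small_scene(17))
  r1 <- run_cytometry(list(rf), count_maxima = FALSE)
  r2 <- run_cytometry(list(rf, rf), count_maxima = FALSE)
  expect_equal(r2$total_cells, 2 * r1$total_cells)
  expect_equal(r2$infected_cells, 2 * r1$infected_cells)
  expect_equal(r2$rel_infected, r1$rel_infected)
  expect_equal(r2$rel_zombie, r1$rel_zombie)
  # single field equals direct tabulation
  seg <- classify_objects(segment_objects(rf$field))
  expect_equal(r1$total_cells, tabulate_counts(seg)$total_cells)
  expect_error(run_cytometry(list()), "at least one")
})

test_that("cytometry recovers ground truth exactly on noise-free scenes", {
  for (s in 1:25) {
    rf <- render_field(small_scene(400 + s))
    res <- run_cytometry(list(rf))
    expect_equal(result_counts(res), truth_counts(rf$truth),
                 info = paste("seed", 400 + s))
  }
})

test_that("raising thresholds or the size gate is monotone", {
  rf <- render_field(small_scene(55, noise_sd = 3))
  base <- gate_config(threshold_rule = "absolute",
                      abs_thresholds = c(dna = 50, rrna = 50, phage = 50))
  n_pos <- function(cfg) {
    r <- tabulate_counts(classify_objects(segment_objects(rf$field, cfg),
                                          cfg))
    r$infected_cells + r$zombie_cells
  }
  counts <- vapply(c(50, 80, 120, 160, 220), function(tp)
    n_pos(gate_config(threshold_rule = "absolute",
                      abs_thresholds = c(dna = 50, rrna = 50,
                                         phage = tp))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  # raising free_phage_max_area never increases zombie count
  zcount <- vapply(c(0.02, 0.05, 0.08), function(fp) {
    cfg <- gate_config(free_phage_max_area = fp, min_cell_area = 0.09)
    tabulate_counts(classify_objects(segment_objects(rf$field, cfg),
                                     cfg))$zombie_cells
  }, numeric(1))
  expect_true(all(diff(zcount) <= 0))
})

test_that("frequency of dividing cells tracks the generating fraction", {
  d <- 0.15
  fields <- lapply(1:3, function(s)
    render_field(scene_spec(n_uninfected_sar11 = 150,
                            n_infected_sar11 = 10, n_zombie = 5,
                            n_other_bacteria = 40, n_free_phage = 10,
                            dividing_fraction = d, seed = 800 + s)))
  res <- run_cytometry(fields)
  n <- res$total_cells
  expect_gte(n, 500)
  expect_lte(abs(res$fdc - d), 3 * sqrt(d * (1 - d) / n))
})

test_that("EUB mode makes other bacteria rRNA-positive", {
  sp <- scene_spec(field_shape = c(448L, 448L), n_uninfected_sar11 = 10,
                   n_infected_sar11 = 0, n_zombie = 5,
                   n_other_bacteria = 20, n_free_phage = 0,
                   noise_sd = 0, eub_mode = TRUE, seed = 12)
  rf <- render_field(sp)
  res <- run_cytometry(list(rf), count_maxima = FALSE)
  # under the general bacterial probe all intact cells are rRNA-positive
  expect_equal(res$sar11_cells, 30)
  expect_equal(res$zombie_cells, 5)
})
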