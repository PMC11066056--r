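#' Run the simulate -> cytometry -> regression chain end to end
#'
#' Renders a day-indexed series of synthetic fields, runs the cytometry
#' pipeline per day, assembles a regression dataset from the recovered
#' fractions (infected fraction shifted off zero via [transform_zero()],
#' zombie fraction, SAR11 fraction, FDC as a percentage), and fits the
#' three beta regressions of the survey: infected ~ zombie,
#' zombie ~ SAR11, and infected ~ FDC(%). Mirrors the analysis chain
#' counts -> relative abundances -> regressions.
#'
#' @param day_specs as for [render_timeseries()]; needs >= 10 days for the
#'   regression stage (fewer days returns the cytometry table with the fits
#'   set to NULL).
#' @param cfg a [gate_config()].
#' @param mcmc list of sampler settings passed to [fit_beta_regression()]
#'   (`chains`, `iter`, `warmup`, `seed`).
#' @param out_dir optional directory; when given, writes `cytometry.tsv`,
#'   `regression_data.tsv`, per-model fit summaries and a text report.
#' @return list with `cytometry` (per-day results + truth), `dataset`
#'   (the regression table), and `fits` (list of three
#'   `beta_regression_fit` or NULL).
#' @export
run_end_to_end <- function(day_specs, cfg = gate_config(),
                           mcmc = list(chains = 4, iter = 2000,
                                       warmup = 2000, seed = 1),
                           out_dir = NULL) {
  ts <- render_timeseries(day_specs)
  res <- lapply(ts$fields, function(f) run_cytometry(list(f), cfg))
  cyto <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(day = ts$truth$day[i], as.data.frame(res[[i]]))))
  dataset <- data.frame(
    day = cyto$day,
    rel_infT = transform_zero(ifelse(is.na(cyto$rel_infected), 0,
                                     cyto$rel_infected)),
    Zombie_cells = ifelse(is.na(cyto$rel_zombie), 0, cyto$rel_zombie),
    rel_SAR11_abundance = ifelse(is.na(cyto$rel_sar11), 0, cyto$rel_sar11),
    FDC_percent = 100 * ifelse(is.na(cyto$fdc), 0, cyto$fdc))
  fits <- NULL
  if (nrow(dataset) >= 10) {
    fit1 <- fit_beta_regression(dataset, rel_infT ~ Zombie_cells,
                                chains = mcmc$chains, iter = mcmc$iter,
                                warmup = mcmc$warmup, seed = mcmc$seed)
    ds2 <- dataset
    ds2$Zombie_cellsT <- transform_zero(ds2$Zombie_cells)
    fit2 <- fit_beta_regression(ds2, Zombie_cellsT ~ rel_SAR11_abundance,
                                chains = mcmc$chains, iter = mcmc$iter,
                                warmup = mcmc$warmup, seed = mcmc$seed + 1)
    fit3 <- fit_beta_regression(dataset, rel_infT ~ FDC_percent,
                                chains = mcmc$chains, iter = mcmc$iter,
                                warmup = mcmc$warmup, seed = mcmc$seed + 2)
    fits <- list(infected_vs_zombie = fit1, zombie_vs_sar11 = fit2,
                 infected_vs_fdc = fit3)
  }
  out <- list(cytometry = list(per_day = cyto, truth = ts$truth),
              dataset = dataset, fits = fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cyto, file.path(out_dir, "cytometry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dataset, file.path(out_dir, "regression_data.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fits)) {
      for (nm in names(fits))
        write_beta_fit(fits[[nm]], file.path(out_dir, nm))
      rep <- file.path(out_dir, "report.txt")
      con <- file(rep, "w"); on.exit(close(con))
      writeLines(c("end-to-end synthetic run",
                   sprintf("days: %d, seed: %s", nrow(dataset),
                           deparse(mcmc$seed)),
                   vapply(names(fits), function(nm) {
                     s <- fits[[nm]]$summary
                     sprintf("%s: slope %.3f +/- %.3f, 95%% CI [%.3f, %.3f]",
                             nm, s$mean[s$parameter == "slope"],
                             s$sd[s$parameter == "slope"],
                             s$ci_lower[s$parameter == "slope"],
                             s$ci_upper[s$parameter == "slope"])
                   }, character(1))), con)
    }
  }
  out
}

#' Scene specifications for a bloom-like infection time series
#'
#' The emulated study conditions: a spring sampling season with two
#' infection peaks (a smaller one near day 25 reaching ~9% of SAR11
#' infected, a larger one near day 95 reaching ~19%), baseline infection
#' near the detection limit (~1%), zombies co-occurring at about half the
#' infected fraction, and division activity rising with infection
#' (faster-growing hosts are infected more).
#'
#' @param days sampling days (strictly increasing).
#' @param n_sar11 SAR11 cells per field.
#' @param seed base seed; day i uses `seed + i`.
#' @return a list of `list(day, spec)` entries for [render_timeseries()].
#' @export
bloom_series_specs <- function(days = seq(1, 133, by = 6),
                               n_sar11 = 130L, seed = 20200401L) {
  peak <- function(day, center, width, height)
    height * exp(-(day - center)^2 / (2 * width^2))
  inf_frac <- 0.01 + peak(days, 25, 8, 0.08) + peak(days, 95, 7, 0.18)
  lapply(seq_along(days), function(i) {
    n_inf <- round(n_sar11 * inf_frac[i])
    list(day = days[i],
         spec = scene_spec(
           n_uninfected_sar11 = n_sar11 - n_inf,
           n_infected_sar11 = n_inf,
           n_zombie = round(n_inf * 0.5),
           n_other_bacteria = 60L,
           n_free_phage = 40L,
           dividing_fraction = 0.03 + 0.4 * inf_frac[i],
           seed = seed + i))
  })
}

#' Write the canonical small test fixtures
#'
#' Generates the plain-text fixtures used by the examples and tests: a
#' noise-free field TIFF plus its ground truth, a negative-control TIFF, a
#' boundary probe-design genome FASTA, a hand-checkable mapping count
#' table, and a simulated regression dataset. Deterministic per seed.
#'
#' @param out_dir writable directory.
#' @param seed integer seed.
#' @return data.frame manifest (file, md5) of the written fixtures.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- scene_spec(field_shape = c(256L, 256L), n_uninfected_sar11 = 10,
                     n_infected_sar11 = 4, n_zombie = 2,
                     n_other_bacteria = 5, n_free_phage = 5,
                     dividing_fraction = 0.2, noise_sd = 0, seed = seed)
  rf <- render_field(spec)
  write_field_tiff(rf$field, file.path(out_dir, "field_noisefree.tif"))
  write_truth_tsv(rf$truth, file.path(out_dir, "field_noisefree_truth.tsv"))
  nc <- render_negative_control(scene_spec(field_shape = c(256L, 256L),
                                           n_uninfected_sar11 = 10,
                                           n_infected_sar11 = 5,
                                           n_zombie = 0,
                                           n_other_bacteria = 5,
                                           n_free_phage = 0,
                                           seed = seed + 1))
  write_field_tiff(nc$field, file.path(out_dir, "field_negative_control.tif"))
  genome <- synthetic_probe_genome(seed = seed)
  writeLines(c(">synthetic_phage_40kb", substring(
    genome, seq(1, nchar(genome), 80),
    pmin(seq(1, nchar(genome), 80) + 79, nchar(genome)))),
    file.path(out_dir, "probe_genome_synthetic.fasta"))
  counts <- data.frame(
    sample = c("s1", "s1", "s1"),
    reference = c("mag_a", "mag_b", "phage_1"),
    reference_class = c("sar11_mag", "sar11_mag", "phage"),
    mapped_reads = c(1000, 500, 100),
    length_kb = c(1300, 1100, 50),
    total_reads = c(1e6, 1e6, 1e6))
  write_abundance_tsv(counts, file.path(out_dir, "mapping_counts.tsv"))
  reg <- simulate_beta_data(-3.72, 6.92, 30, 148, seed = seed,
                            names = c("Zombie_cells", "rel_infT"))
  utils::write.table(reg, file.path(out_dir, "regression_data.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  data.frame(file = basename(files),
             md5 = vapply(files, function(f)
               as.character(tools::md5sum(f)), character(1)),
             row.names = NULL)
}

#' Construct a synthetic 40-kb phage-like genome for probe design
#'
#' Base composition is drawn at ~33% GC (matching the GC content of the
#' target pelagiphage genomes) so that in-band candidate windows are
#' plentiful; an accompanying annotation table marks terminase, polymerase
#' and structural gene regions.
#'
#' @param length_bp genome length (default 40000).
#' @param gc target GC fraction.
#' @param seed integer seed.
#' @return character genome string with attribute `annotations` (gene
#'   table, 0-based half-open).
#' @export
synthetic_probe_genome <- function(length_bp = 40000, gc = 0.33, seed = 1) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    g <- paste(sample(names(p), length_bp, replace = TRUE, prob = p),
               collapse = "")
    ann <- data.frame(
      id = c("terL", "dnap", "mcp", "tail_fiber", "hyp1"),
      start = c(1000L, 8000L, 16000L, 24000L, 32000L),
      end = c(3500L, 11000L, 19000L, 26500L, 34000L),
      class = c("terminase", "polymerase", "structural", "structural",
                "other"))
    attr(g, "annotations") <- ann
    g
  })
}
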