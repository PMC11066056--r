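#!/usr/bin/env Rscript
# Simulate the study conditions: a bloom-like time series of multi-channel
# FISH fields with two infection peaks, plus negative-control fields.
# Writes ground truth and example images under results/01_fields/.

suppressMessages(library(zombiefish))

out <- "results/01_fields"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- bloom_series_specs()
ts <- render_timeseries(specs)
write_truth_tsv(ts$truth, file.path(out, "truth_per_day.tsv"))

# example images: the peak-infection day and a matched negative control
peak_day <- which.max(ts$truth$true_infected_fraction)
write_field_tiff(ts$fields[[peak_day]]$field,
                 file.path(out, "example_peak_day.tif"))
nc <- render_negative_control(specs[[peak_day]]$spec)
write_field_tiff(nc$field, file.path(out, "example_negative_control.tif"))

message(sprintf("rendered %d days; infected fraction peaks at %.1f%% (day %d)",
                length(specs), 100 * max(ts$truth$true_infected_fraction),
                ts$truth$day[peak_day]))
message("ground truth written to ", out)
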