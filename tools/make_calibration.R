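## Regenerates the shipped adaptive-threshold calibration table.
## Run from the package root:  Rscript tools/make_calibration.R
pkg <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), ".."))
for (f in list.files(file.path(pkg, "R"), full.names = TRUE)) source(f)
tab <- calibrate_adaptive(diameters_mm = c(12, 16, 20, 24, 28, 36),
                          lb_levels = c(3, 5, 8, 12, 20, 30),
                          settings = acquisition_settings(noise_scale = 0),
                          seed = 1L)
write.csv(as.data.frame(tab), file.path(pkg, "inst", "extdata", "adaptive_calibration.csv"),
          row.names = FALSE)
cat("wrote", nrow(tab), "rows\n")
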