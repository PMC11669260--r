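# Builds inst/extdata/reference_bundle_synthetic.json: the packaged
# coefficient bundle calibrated to the published survival and prediction
# grids. Run from the repository root:
#   Rscript data-raw/make_reference_bundle.R
# Deterministic; takes a few minutes (the mortality calibration solves a
# 23-parameter nonlinear least-squares problem with quantile root-finding
# inside the objective).

devtools::load_all(".", quiet = TRUE)

sg <- read.csv("inst/extdata/reference_grid_survival.csv")
pg <- read.csv("inst/extdata/reference_grid_predictions.csv")

bundle <- calibrate_reference_bundle(sg, pg, verbose = TRUE)
print(bundle)
cat("count method:", bundle$lifetime_count_method, "\n")
print(bundle$metadata$calibration)

write_bundle(bundle, "inst/extdata/reference_bundle_synthetic.json")

## round-trip check + validation summary
b2 <- read_bundle("inst/extdata/reference_bundle_synthetic.json")
v <- validate_grid(b2)
print(v)
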