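# Frozen numerical conventions used across the package. Changing any of these
# changes the feature schema or the statistics, so they live in one place.

# quantile() type used everywhere (linear interpolation between order stats)
.QUANTILE_TYPE <- 7L

# pseudo-count used to smooth Weight-of-Evidence cells
.WOE_SMOOTHING <- 0.5

# interior-edge probabilities for decile binning fitted on controls
.BIN_PROBS <- seq(0.1, 0.9, by = 0.1)

# fraction thresholds and defaults mirrored by RunConfig
.DEFAULT_PREVALENCE_THRESHOLD <- 0.05
.DEFAULT_WINDOW_DAYS <- 730L
.DEFAULT_HOLDOUT_FRAC <- 0.1
.DEFAULT_SPY_FRAC <- 0.1
.DEFAULT_NOISE_TOL <- 0.2
.DEFAULT_DECISION_THRESHOLD <- 0.5

# ICD-10 roots whose presence would leak the diagnosis into the feature set:
# myeloproliferative/myelodysplastic roots and the hematologic-malignancy
# C81-C96 block plus D70-D77
.LEAKAGE_SINGLE_ROOTS <- c("D45", "D46", "D47")
.LEAKAGE_D_RANGE <- sprintf("D%02d", 70:77)
.LEAKAGE_C_RANGE <- sprintf("C%02d", 81:96)

# codes and text pattern that flag a putative case record
.PMF_FLAG_CODES <- c("C94", "C94.4", "D47", "D47.1", "D47.4")
.PMF_FLAG_REGEX <- "\\b[mM]ielofibroz"

# numeric floor for the Elkan-Noto label-frequency estimate
.C_HAT_EPS <- 1e-6

.MISSING <- NA_real_
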