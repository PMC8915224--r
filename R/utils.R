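# Internal helpers shared across modules.

# CT scanners store integer HU; R's round() is round-half-to-even, so noisy
# HU values are rounded half-away-from-zero explicitly before casting.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Report-layer rounding: half-away-from-zero at a fixed number of decimals,
# matching how measurement devices and the necropsy protocol print values.
round_report <- function(x, digits = 1) {
  round_half_away(x * 10^digits) / 10^digits
}

fc_levels <- function() {
  c("severe_underweight", "underweight", "normal", "overweight", "obese")
}

muscle_levels <- function() {
  c("atrophic", "normal", "hypertrophic")
}

ffr_class_levels <- function() {
  c("not_overweight", "overweight", "obese")
}

# Deterministic per-cat substream: cohorts are reproducible under subsetting
# because each cat's volume depends only on (base seed, cat index).
derive_seed <- function(seed, i) {
  (abs(as.integer(seed)) + 7919L * as.integer(i)) %% 2147483587L
}
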