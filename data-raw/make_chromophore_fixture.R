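# Generates inst/extdata/synthetic_whole_blood_mua.csv — a synthetic
# Gaussian-mixture approximation of oxy/deoxy whole-blood absorption (1/cm,
# 150 g/L hemoglobin): Soret tail below 480 nm, oxygenated double peak at
# 542/577 nm, deoxygenated single peak at 555 nm, deoxygenated-dominant red
# gap beyond 600 nm.
lambda <- seq(440, 730, by = 2)
mua_oxy <- 320 * exp(-((lambda - 446) / 45)^2) +
  65 * exp(-((lambda - 542) / 13)^2) +
  62 * exp(-((lambda - 577) / 11)^2) + 1.5
mua_deoxy <- 490 * exp(-((lambda - 432) / 42)^2) +
  91 * exp(-((lambda - 555) / 22)^2) +
  20 * exp(-((lambda - 670) / 60)^2) + 2
stopifnot(all(mua_oxy > 0), all(mua_deoxy > 0))
write.csv(
  data.frame(wavelength_nm = lambda,
             mua_oxy = round(mua_oxy, 4),
             mua_deoxy = round(mua_deoxy, 4)),
  "inst/extdata/synthetic_whole_blood_mua.csv",
  row.names = FALSE, quote = FALSE
)
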