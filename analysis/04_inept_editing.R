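#!/usr/bin/env Rscript
# Refocused-INEPT editing of NH vs NH2 and the linewidth penalty.
#
# Computes the NH/NH2 editing curves for J = 92 Hz (tau_H = 2 ms), the
# delays that suppress (2.7 ms) or maximize (1.4 ms) the NH2 signal,
# verifies the analytic curves against the density-matrix simulator, and
# quantifies how a given homogeneous linewidth attenuates the transfer:
# a 160 Hz line (T2' ~ 2 ms) loses ~87% of its INEPT signal at the
# standard delays, while a 41 Hz glutamine-like line survives.

library(ladderNMR)

dir.create("results", showWarnings = FALSE)
J <- 92

curve <- editing_curve(J = J, tau_H = 2e-3,
                       tau_N_grid = seq(0, 6e-3, length.out = 121))
curve$epsilon_NH2_numeric <- vapply(curve$tau_N_s, function(tn) {
  simulate_inept_numeric(inept_params(J = J, tau_H = 2e-3, tau_N = tn,
                                      n_protons = 2))
}, numeric(1))
stopifnot(max(abs(curve$epsilon_NH2 - curve$epsilon_NH2_numeric)) < 1e-6)
write.csv(curve, "results/inept_editing_curve.csv", row.names = FALSE)

supp <- suppression_delay(J)
mx <- nh2_max_delay(J)
cat(sprintf("NH2 suppression delay: %.4f ms (~1/(4J))\n", supp * 1e3))
cat(sprintf("NH2 maximum delay:     %.4f ms (~1/(8J))\n", mx * 1e3))

atten <- data.frame(
  delta_homo_hz = c(0, 22, 41, 82, 128, 157, 160, 543),
  t2prime_ms = NA, attenuation = NA, predicted_visible = NA
)
for (i in seq_len(nrow(atten))) {
  dh <- atten$delta_homo_hz[i]
  atten$t2prime_ms[i] <- if (dh > 0) t2prime_from_delta_homo(dh) * 1e3 else Inf
  vis <- predict_inept_visibility(dh)
  atten$attenuation[i] <- vis$attenuation
  atten$predicted_visible[i] <- vis$visible
}
print(atten, digits = 3)
write.csv(atten, "results/inept_attenuation.csv", row.names = FALSE)
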