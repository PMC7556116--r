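#!/usr/bin/env Rscript
# Relaxation fitting and rule-based ladder classification.
#
# Fits synthetic relaxation decays drawn at the measured per-residue
# rotating-frame rates (5% noise, wild-bootstrap 2-sigma errors, 500
# iterations), then applies the evidence pattern — small 15N R1rho plus
# hydrogen-bond shift evidence, with the ring-current exception — to the
# six measured side-chains. Finding: N226 and N262 are called rigid_ladder,
# N243/N279/Q259 flexible, and Q240 rigid but non_ladder (its large shift
# difference comes from a ring-current-shielded proton, not a hydrogen
# bond).

library(ladderNMR)

dir.create("results", showWarnings = FALSE)
tab <- make_observables_table("hets_table1",
                              path = "results/observables_table.csv")

fits <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
  rate <- tab$r1rho_15N[i]
  curve <- make_decay(rate, seq(0, 2.5 / max(rate, 5), length.out = 8),
                      noise_fraction = 0.05, seed = 100 + i,
                      site_label = tab$residue[i],
                      experiment_kind = "spinlock")
  fit <- bootstrap_ci(curve, n_iter = 500, seed = 100 + i)
  data.frame(residue = tab$residue[i], true_rate_s = rate,
             fitted_rate_s = round(fit$rate, 3),
             ci_2sigma = round(fit$ci_2sigma, 3))
}))
print(fits)
write.csv(fits, "results/r1rho_fits.csv", row.names = FALSE)
inside <- abs(fits$true_rate_s - fits$fitted_rate_s) <= fits$ci_2sigma
cat(sprintf("true rates within 2 sigma: %d/%d (2 sigma covers ~95%%)\n",
            sum(inside), length(inside)))

calls <- classify_table(tab)
print(calls[, c("residue", "call")])
write.csv(calls[, c("residue", "call")], "results/ladder_calls.csv",
          row.names = FALSE)

cat("\nfull criteria trace for Q240 (ring-current exception):\n")
q240 <- classify_sidechain(sidechain_observables(
  "Q240", cp_visible = TRUE, inept_visible = TRUE,
  shift_pair = c(7.8, 4.9), delta_homo = 41, r1rho_15N = 2.5
))
print(q240)
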