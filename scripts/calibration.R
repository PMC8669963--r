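#!/usr/bin/env Rscript
# Committed calibration run for the qualitative pattern suite.
#
# Run once, BEFORE the pattern thresholds were frozen, at the pre-registered
# master seed 1 and default parameters (n = 100, 2,000-iteration blocks,
# 20 replicates). The frozen values derived from it:
#   - condition-1 stability band: 10% relative (observed max deviation ~3%)
#   - de novo replicate-noise band: 5% relative (observed |ON-OFF|/OFF ~1%)
# The ON/OFF contrast tallies are reported for transparency: the identical
# common-mode drive cannot move pairwise phase differences, so these are
# noise contrasts (see the methods vignette).
#
# Usage: Rscript scripts/calibration.R

library(kuradbs)

chronic <- lapply(c(1, 2), function(cond) {
  run_experiment(withdrawal_renewal_protocol(2000), cond, n = 100,
                 n_replicates = 20, master_seed = 1)
})
p1 <- chronic[[1]]$per_replicate_block_plv
p2 <- chronic[[2]]$per_replicate_block_plv

m1 <- chronic[[1]]$summary$grand_plv_mean
cat(sprintf("condition 1 block means: %s\n",
            paste(sprintf("%.4f", m1), collapse = " ")))
cat(sprintf("condition 1 max relative deviation from DBS ON: %.4f\n",
            max(abs(m1 - m1[1]) / m1[1])))
cat(sprintf("condition 2 block means: %s\n",
            paste(sprintf("%.4f", chronic[[2]]$summary$grand_plv_mean),
                  collapse = " ")))

higher <- sum(vapply(1:20, function(r) all(p1[r, ] > p2[r, ]), logical(1)))
cat(sprintf("condition 1 > condition 2 in all blocks: %d/20 matched pairs\n",
            higher))

off_up <- sum(vapply(1:20, function(r) {
  mean(p2[r, c(2, 4)]) >= mean(p2[r, c(1, 3)])
}, logical(1)))
cat(sprintf("condition 2 OFF-mean >= preceding-ON-mean: %d/20 replicates\n",
            off_up))

dn <- run_experiment(de_novo_protocol(500), 1, n = 100,
                     n_replicates = 20, master_seed = 1)
mdn <- dn$summary$grand_plv_mean
cat(sprintf("de novo condition 1 OFF=%.4f ON=%.4f ratio=%.4f\n",
            mdn[1], mdn[2], mdn[2] / mdn[1]))
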