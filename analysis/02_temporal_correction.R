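#!/usr/bin/env Rscript
# Stage 2 -- classification noise and temporal-consistency correction.
#
# The true stack is corrupted with the published Machadinho-like confusion
# rows (SF is the hardest class: 9.5% labelled MF, 18.5% NF). Spurious
# SF/NF -> MF reversions are then corrected back to SF. The correction can
# only help: reversions to MF are ecologically implausible.

library(lcctraj)

sim <- simulate_stack(simulation_config(shape = c(100, 100), seed = 42))
spec <- confusion_spec(matrix(c(1, 0, 0,
                                0, 0.985, 0.015,
                                0.095, 0.185, 0.72), 3, 3, byrow = TRUE))
noisy <- corrupt_with_confusion(sim$stack, spec, seed = 43)

res <- correct_disallowed_transitions(noisy)
write.csv(res$corrections, "results/02_corrections.csv", row.names = FALSE)

agree <- function(stack) mean(stack$codes == sim$stack$codes)
cat(sprintf("label agreement with truth: %.3f noisy, %.3f corrected\n",
            agree(noisy), agree(res$stack)))
cat(sprintf("%d cells corrected across %d dates\n",
            sum(res$corrections$n_corrected), n_dates(noisy)))

write_stack(res$stack, "scratch/corrected_stack", prefix = "corr")
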