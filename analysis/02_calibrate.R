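#!/usr/bin/env Rscript
# Stage 2: calibrate raw luminescence into cytosolic Ca2+ traces.
#
# Each well's photon counts are converted through the aequorin rate-constant
# curve, using the terminal discharge to close the remaining-pool
# denominator; the calibrated traces are truncated at the discharge.

library(pawsig)

run <- "results/run"
traces <- read_plate(file.path(run, "plate.csv"))
cal <- lapply(traces, calibrate_trace)
write_ca_traces(cal, file.path(run, "calibrated.csv"))

peaks <- vapply(cal, function(tr) max(tr$ca), numeric(1))
bases <- vapply(cal, function(tr) mean(tr$ca[tr$times < 100]), numeric(1))
cat(sprintf("Calibrated %d wells.\n", length(cal)))
cat(sprintf("Resting [Ca2+]cyt: %.3g M (median); evoked peaks up to %.3g M.\n",
            median(bases), max(peaks)))
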