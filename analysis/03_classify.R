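#!/usr/bin/env Rscript
# Event-aligned responses and cell classification: stimulus responsiveness,
# prediction-error responsiveness, selectivity classes; compare the calls
# against the generator's ground truth.

library(oddball2p)

ses <- read_session("scratch/session_default")
dff <- readRDS("scratch/dff_default.rds")

rt <- build_response_table(dff, ses$events, ses$config)
cls <- classify_cells(rt, ses$config)

m <- match(cls$cell_id, ses$truth$cell_id)
planted <- ses$truth$pe_gain[m] > 0
cat(sprintf("prediction-error calls: sensitivity %.3f, FPR %.3f\n",
            mean(cls$pe_responsive[planted]),
            mean(cls$pe_responsive[!planted])))
print(table(truth = ses$truth$cell_class[m], class = cls$selectivity_class))

# decay of the amplified response over oddball exposures
amp <- rt[!is.na(rt$exposure_index) &
            rt$cell_id %in% ses$truth$cell_id[ses$truth$pe_gain > 0], ]
means <- tapply(amp$response, amp$exposure_index, mean)
fit <- estimate_exposure_decay(as.integer(names(means)), as.numeric(means))
cat(sprintf("exposure decay: planted %.2f, recovered %.2f\n",
            ses$truth$exposure_decay[1], fit$lambda))

write.table(cls, "results/03_cell_classification.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
decay <- data.frame(exposure = as.integer(names(means)),
                    mean_response = as.numeric(means))
write.table(decay, "results/03_exposure_decay.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
saveRDS(rt, "scratch/response_table_default.rds")
cat("classification written to results/03_cell_classification.tsv\n")
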