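#!/usr/bin/env Rscript

# Step 4: summary tables of group means and standard errors per task and
# effector (the quantities the study displays as bar charts), plus the
# marginal means over target fingers and phalanges.

suppressMessages(library(oppkin))

res <- read_results("results/session_results.tsv")
rep <- run_report(res)
data.table::fwrite(rep, "results/report_means.tsv", sep = "\t")

dth <- rep[rep$measure == "D" & rep$effector == "thumb", ]
cat("Mean thumb displacement ratio D_T by target phalanx:\n")
print(round(tapply(dth$mean, dth$phalanx, mean)[c("distal", "middle", "proximal")], 3))
cat("Mean D_T by target finger:\n")
print(round(tapply(dth$mean, dth$finger, mean)[c("index", "middle", "ring", "little")], 3))

sal <- rep[rep$measure == "SAL", ]
sal_t <- tapply(sal$mean[sal$effector == "thumb"], sal$task[sal$effector == "thumb"], mean)
sal_f <- tapply(sal$mean[sal$effector == "finger"], sal$task[sal$effector == "finger"], mean)
cat(sprintf("Thumb movements are smoother than finger movements in %d of 12 tasks\n",
            sum(sal_t[names(sal_f)] > sal_f)))
cat(sprintf("(mean SAL thumb %.2f vs finger %.2f; closer to zero = smoother).\n",
            mean(sal_t), mean(sal_f)))
cat("Report table written to results/report_means.tsv.\n")
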