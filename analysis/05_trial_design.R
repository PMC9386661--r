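#!/usr/bin/env Rscript
# Exact single-stage design for the trial's hypotheses and the response
# endpoints with binomial confidence intervals.

suppressPackageStartupMessages(library(duplexct))
dir.create("results", showWarnings = FALSE)

design <- ahern_design(p0 = 0.10, p1 = 0.30, alpha = 0.05, power = 0.85)
print(design)

design_tab <- data.frame(
  p0 = design$p0, p1 = design$p1, alpha_nominal = design$alpha_nominal,
  power_nominal = design$power_nominal, n = design$n, r = design$r,
  alpha_exact = design$alpha_exact, power_exact = design$power_exact)
write_log_tsv(design_tab, "results/design.tsv")

endpoints <- list(
  objective_response = endpoint_estimate(8, 27, "wald"),
  stable_disease = endpoint_estimate(11, 27, "wald"),
  disease_control = endpoint_estimate(17, 27, "wald"))
ep_tab <- do.call(rbind, lapply(names(endpoints), function(nm) {
  e <- endpoints[[nm]]
  data.frame(endpoint = nm, successes = e$successes, total = e$total,
             proportion_percent = e$proportion_percent, method = e$ci_method,
             ci_low_percent = e$ci_low_percent,
             ci_high_percent = e$ci_high_percent)
}))
write_log_tsv(ep_tab, "results/endpoints.tsv")
for (nm in names(endpoints)) { cat(nm, ": "); print(endpoints[[nm]]) }
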