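#!/usr/bin/env Rscript
# Stage 4: render the run report (markdown) from the stage-2 object.

library(lesionpls)

report <- readRDS("results/pipeline_report.rds")
report_markdown(report, "results/report.md")
cat("report written to results/report.md\n")
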