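#!/usr/bin/env Rscript
# Survey design: how many of the 227 households in the seven study villages
# must be interviewed at a 5% precision level?

suppressPackageStartupMessages(library(ethnoindices))
dir.create("results", showWarnings = FALSE)

frame <- sampling_frame(227, precision = 0.05)
n <- required_sample_size(frame$total_households, frame$precision)
cat(sprintf("Finite-population corrected sample size: %d of %d households (e_p = %.2f)\n",
            n, frame$total_households, frame$precision))

# sensitivity: the same frame at other precision levels
grid <- data.frame(precision = c(0.01, 0.03, 0.05, 0.10))
grid$sample_size <- vapply(grid$precision,
                           function(e) required_sample_size(227, e), integer(1))
print(grid, row.names = FALSE)
write.csv(cbind(total_households = 227, grid),
          "results/sample_size.csv", row.names = FALSE)
cat("wrote results/sample_size.csv\n")
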