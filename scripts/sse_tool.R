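#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline:
#   Rscript scripts/sse_tool.R simulate --model 0 --seed 1 --out spikes.txt
#   Rscript scripts/sse_tool.R run --input spikes.txt --t-stop 1 --out-dir res/
#   Rscript scripts/sse_tool.R benchmark --model 4 --runs 20 --csv out.csv
suppressPackageStartupMessages(library(sseDetect))
status <- sse_cli(commandArgs(trailingOnly = TRUE))
quit(status = if (is.numeric(status)) status else 0L)
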