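#!/usr/bin/env Rscript
# Per-cycle metrics for every simulated larva: segments each trace into
# black-frame-delimited cycles, applies the first/last and startle
# exclusions, and computes max tail angle of the difference signal,
# normalized integral and percentage of time above the 5-degree threshold.
# Writes results/cycles_standard.csv (+ _prolonged, _interval).

library(vsrquant)

files <- list.files("results/traces", full.names = TRUE)
stopifnot(length(files) > 0)

fps <- 30
kind <- function(f) {
  if (grepl("prolonged", f)) "prolonged" else if (grepl("interval", f)) "interval"
  else "standard"
}
tabs <- split(files, vapply(files, kind, character(1)))

for (k in names(tabs)) {
  rows <- lapply(tabs[[k]], function(f) {
    tr <- read_trace_csv(f, fps = fps)
    cycle_metrics_table(tr, larva_id = sub("\\.csv$", "", basename(f)))
  })
  m <- do.call(rbind, rows)
  out <- sprintf("results/cycles_%s.csv", k)
  write.csv(m, out, row.names = FALSE)
  ret <- m[!m$excluded, ]
  message(sprintf("%s: %d larvae, %d retained cycles (%.1f%% active), wrote %s",
                  k, length(tabs[[k]]), nrow(ret),
                  100 * mean(ret$active), out))
}
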