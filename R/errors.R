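# Classed conditions so the command-line wrapper can map failures to exit
# codes (2 usage, 3 data, 4 numerical).

stopUsage <- function(...) {
  stop(structure(class = c("csprs_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopData <- function(...) {
  stop(structure(class = c("csprs_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopNumeric <- function(...) {
  stop(structure(class = c("csprs_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
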