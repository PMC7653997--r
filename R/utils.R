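`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition constructors. The three classes map onto the CLI exit codes
# (config -> 2, data/format -> 3, numerical -> 4).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("awmfe_config_error", "awmfe_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("awmfe_data_error", "awmfe_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("awmfe_numeric_error", "awmfe_error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

# Order chromosomes numerically where labels are numeric, lexically otherwise.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  if (anyNA(num)) match(chrom, sort(unique(chrom))) else num
}
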