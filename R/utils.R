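# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) {
  stop(structure(class = c("multiprs_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("multiprs_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("multiprs_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Canonical variant id used for matching and file output: chrom:pos:other:effect
variant_id <- function(chrom, pos, other_allele, effect_allele) {
  paste(chrom, pos, other_allele, effect_allele, sep = ":")
}

# Position-level key (alleles matched separately, orientation-free).
pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

VALID_ALLELES <- c("A", "C", "G", "T")

# Derive a stage-specific RNG seed from a user seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
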