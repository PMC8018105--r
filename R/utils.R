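# internal helpers shared across modules

stop_format <- function(...) stop(errorCondition(sprintf(...),
                                                 class = c("epirelapse_format_error", "error")))
stop_validation <- function(...) stop(errorCondition(sprintf(...),
                                                     class = c("epirelapse_validation_error", "error")))
stop_domain <- function(...) stop(errorCondition(sprintf(...),
                                                 class = c("epirelapse_domain_error", "error")))

# chromosome sort key: chr1..chr22, chrX, chrY, then anything else
chrom_order <- function(chrom) {
  lev <- c(paste0("chr", 1:22), "chrX", "chrY")
  k <- match(chrom, lev)
  k[is.na(k)] <- length(lev) + 1L
  k
}

# FNV-1a 32-bit hash of a string, hex-encoded; used to fingerprint configs.
# The xor only touches the low byte, so it is done on the low byte alone and
# the state is kept as a double below 2^32 (R has no unsigned 32-bit type).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # modular multiply in two 16-bit halves to stay inside double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
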