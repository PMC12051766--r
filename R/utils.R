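`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a character scalar; used to stamp output files with
# a configuration fingerprint without adding a hashing dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)  # xor touches the low byte only
    # 32-bit overflow-safe multiply by the FNV prime 16777619 = 403 * 41617
    h <- (h * 403) %% 4294967296
    h <- (h * 41617) %% 4294967296
  }
  # h is kept as a double (can exceed .Machine$integer.max); format in halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_fingerprint <- function(cfg) {
  fnv1a32(paste(deparse(unclass(cfg)), collapse = ""))
}

package_version_string <- function() {
  as.character(utils::packageVersion("istpdose"))
}

# Write a data frame as CSV with a provenance comment header (package
# version, seed, optional config fingerprint). Content is deterministic:
# no timestamps.
write_with_provenance <- function(df, path, seed = NA, config_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# istpdose %s seed=%s%s",
                     package_version_string(),
                     as.character(seed),
                     if (is.null(config_hash)) "" else paste0(" config=", config_hash)),
             con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
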