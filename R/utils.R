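# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_refstab <- function(fmt, ..., class = "refstab_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "refstab_error")))
}

# Sample coefficient of variation (n-1 SD over arithmetic mean).
# Returns NA for zero mean: CV is undefined there.
cv_vec <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

# FNV-1a 32-bit hash of a character vector, for provenance headers.
# Arithmetic in doubles with a 16-bit split so products stay exact (< 2^53).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic rank: ascending by value, ties broken lexicographically by id.
rank_with_ties <- function(value, id) {
  ord <- order(value, id)
  r <- integer(length(value))
  r[ord] <- seq_along(value)
  r
}
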