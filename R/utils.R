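## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

check_flag01 <- function(x, what) {
  if (!all(x %in% c(0L, 1L, TRUE, FALSE), na.rm = TRUE))
    stop2("%s must be coded 0/1 or logical", what)
  as.integer(x)
}

## FNV-1a 32-bit hash of a character scalar; used to fingerprint run configs
## (no digest package in the dependency set, and 32 bits is plenty for
## distinguishing configs in a report header).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); keep h as double (> 2^31)
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    ## 32-bit overflow-safe multiply by 16777619 = 403 + 2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
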