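# misc internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a over a deparsed object; stable identifier for configs in outputs
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256                       # xor affects the low byte only
    h <- h - lo8 + bitwXor(lo8, b %% 256)
    # 32-bit multiply by 16777619 without overflow, via split arithmetic
    h <- ((h %% 65536) * 16777619 + (h %/% 65536 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
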