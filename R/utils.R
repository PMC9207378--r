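# Condition helpers: every recoverable failure mode carries a dedicated
# condition class so the batch pipeline can map it to a manifest status.
.fvlStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fvlError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 47.45 -> 47.5), the
#' convention used for the reported percentages. Base [round()] rounds ties
#' to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 32-bit FNV-1a over the UTF-8 bytes of a string; used to fingerprint the
# pipeline configuration in the run manifest without extra dependencies.
# Arithmetic is done in doubles, split so every product stays below 2^53.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\x1f")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Stable textual form of a (possibly nested) config list for hashing.
.configString <- function(config) {
  flat <- unlist(config)
  if (is.null(flat) || length(flat) == 0L) return("default")
  flat <- flat[order(names(flat))]
  paste(names(flat), vapply(flat, format, character(1)), sep = "=",
        collapse = ";")
}
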