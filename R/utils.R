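# Internal helpers shared across modules.

# half-open interval overlap width; vectors recycle
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# encode a set of junction spans as a canonical string "s-e;s-e" (sorted)
encode_spans <- function(starts, ends) {
  if (length(starts) == 0L) return("")
  ord <- order(starts, ends)
  paste(paste0(starts[ord], "-", ends[ord]), collapse = ";")
}

# decode "s-e;s-e" into a tibble with start/end columns (integer)
decode_spans <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  tibble::tibble(
    start = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    end   = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_spliceland <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}
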