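# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
logit <- function(p, eps = 1e-3) {
  # clamp keeps transformed values finite for betas at/near 0 or 1
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# round-half-up at `digits` decimals; base round() is half-to-even, which
# disagrees with how published percentage tables are typically formatted
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split semicolon-joined feature labels ("" -> character(0))
split_features <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_features <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}
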