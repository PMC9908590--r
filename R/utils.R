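#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats runif rpois quantile sd setNames
#' @importFrom utils head tail
NULL

# Structured error: every toolkit error carries a machine-readable `code`
# (e.g. "PARSE_ERROR") and condition classes wsianno_<lowercase code> /
# wsianno_error, so callers can branch without string-matching messages.
wsianno_abort <- function(code, message, ...) {
  abort(
    message,
    class = c(paste0("wsianno_", tolower(code)), "wsianno_error"),
    code = code,
    ...
  )
}

#' Extract the machine-readable code of a toolkit error
#'
#' @param cnd A condition object thrown by wsianno.
#' @return The error code string, or `NA_character_` for foreign conditions.
#' @export
error_code <- function(cnd) {
  if (!is.null(cnd$code)) cnd$code else NA_character_
}

# Deterministic named substreams: each pipeline stage draws from its own
# seed derived from the user seed, so regenerating one artifact never
# shifts the randomness of another. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(h %% 65521L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
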