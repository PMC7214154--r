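# Internal helpers shared across modules.

# Counter-based per-generator substream: one global seed plus a small stream
# index gives each generator its own reproducible RNG stream, so adding a
# generator never perturbs the output of an existing one. Result stays below
# 2^31 - 1 (R's integer range).
.substreamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 1103 + as.double(stream) * 100003) %% 2147483647)
}

.withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substreamSeed(seed, stream))
  expr
}

.assertScalarProb <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop("parameter '", name, "' must be a ",
                if (open) "proportion in (0, 1)" else "value in [0, 1]",
                call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x) && (if (positive) x > 0 else x >= 0)
  if (!ok) stop("parameter '", name, "' must be a ",
                if (positive) "positive" else "non-negative",
                " integer count", call. = FALSE)
  invisible(as.integer(x))
}

#' Percentage of a count relative to a total
#'
#' Small reporting helper used throughout the summary stage: the percentage
#' that \code{n} represents of \code{total}, rounded to \code{digits}
#' decimal places (one by default, matching the reporting convention of the
#' pipeline's summary tables).
#'
#' @param n numerator count.
#' @param total denominator count, must be positive.
#' @param digits decimal places to round to.
#' @return numeric scalar, \code{100 * n / total} rounded.
#' @examples
#' percentOf(82, 286)  # 28.7
#' percentOf(23, 82, digits = 0)  # 28
#' @export
percentOf <- function(n, total, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(total), length(total) == 1L)
  if (total <= 0) stop("'total' must be positive", call. = FALSE)
  round(100 * n / total, digits)
}

# write a table with a leading comment line (config hash provenance)
.writeTableWithComment <- function(df, path, comment = NULL, sep = "\t") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTable <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
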