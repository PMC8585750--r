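#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov TukeyHSD cor.test t.test rnbinom rbinom runif rexp
#'   setNames aggregate p.adjust pf
#' @importFrom utils read.delim write.table head tail
NULL

# Natural sort for chromosome names: chr2 before chr10, scaffolds after chr*.
natural_sort <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("\\D+", "", x)))
  pre <- gsub("[0-9]+.*$", "", x)
  x[order(pre, num, x)]
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_invalid(fmt, ...)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed below 2^31 from a parent seed and tag.
child_seed <- function(seed, tag) {
  (as.double(seed) * 1009 + sum(utf8ToInt(tag))) %% 2147483647
}

round1 <- function(x) round(x, 1)
round2 <- function(x) round(x, 2)
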