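#' @importFrom rlang %||% .data abort warn
#' @importFrom stats predict rnorm runif rbinom rlnorm quantile sd median
#'   setNames complete.cases
NULL

#' Derive a child seed from a global seed and a string key
#'
#' Every stochastic operation in the package draws its own seed
#' deterministically from the study-wide seed and a short label, so that
#' adding or reordering stochastic steps never perturbs the others.
#'
#' @param seed Integer global seed.
#' @param key Character label of the consuming operation.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in R's integer range
  h <- 0
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer((h + (abs(seed) %% m) * 7919) %% (m - 1) + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

`%theni%` <- function(x, y) if (is.null(x) || !length(x)) y else x
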