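#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a 32-bit
#' integer seed, so that each pipeline stage has its own reproducible
#' random stream regardless of the order in which stages run.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' z-score a numeric vector
#'
#' Centers and scales to unit standard deviation. A constant vector is
#' returned as all zeros rather than NaN.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and (unless constant) SD 1.
#' @export
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Convert surprisal from nats to bits
#'
#' @param nats numeric vector of surprisal values in natural-log units.
#' @return the same values in base-2 units.
#' @export
nats_to_bits <- function(nats) nats / log(2)

# internal: run an expression under a local RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# internal: stop unless all names are columns of df
check_columns <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
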