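# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Number of items to flag out of `total` for a target fraction: floor the
# expected count, then add the remainder as a single seeded Bernoulli unit.
# Guarantees the realized count is within 1 of round(frac * total).
frac_count <- function(frac, total) {
  expected <- frac * total
  n <- floor(expected)
  rem <- expected - n
  if (rem > 0 && stats::runif(1L) < rem) n <- n + 1L
  as.integer(n)
}

# Cheap stable FNV-1a style hash of a character scalar, for config fingerprints
# in output headers. Not cryptographic.
config_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# 1 - Pearson correlation distance between numeric vectors, with the
# convention that a constant (zero-variance) profile is at distance 1 from
# everything: it carries no shape information.
cor_dist <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    return(1)
  }
  1 - stats::cor(x, y)
}

# Reverse complement of a plain ACGTN character string.
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# Assert a scalar fraction in [0, 1]
check_frac <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
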