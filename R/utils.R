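# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' seeded operations do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite numeric `seed` is required", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 999983 * as.numeric(k)) %% 2147483647L)
}

# Numeric-aware chromosome ordering: 1..22 then X, Y, then anything else.
chromosome_order <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(ch))
  key <- ifelse(!is.na(num), num,
    ifelse(ch == "X", 100, ifelse(ch == "Y", 101, 102)))
  order(key, ch)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
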