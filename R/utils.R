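# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding used for rendered report tables, where ties go away from
#' zero (so 26.75 renders as 26.8) rather than to even as in [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-adic string/byte hash folded into [1, 2^31 - 2].
# Used to derive independent RNG streams per probe / meadow / stage from one
# root seed, so that adding a probe never perturbs the streams of others.
hash_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(root %% m)
  for (part in list(...)) {
    for (b in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 31 + b) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Week-of-year of a timestamp
#'
#' @param time a `POSIXct`/`Date` vector.
#' @param convention `"iso"` for ISO-8601 week numbering (default) or
#'   `"ordinal"` for `ceiling(day_of_year / 7)`.
#' @return integer vector of week numbers.
#' @export
week_of_year <- function(time, convention = c("iso", "ordinal")) {
  convention <- match.arg(convention)
  if (convention == "iso") {
    as.integer(strftime(time, "%V"))
  } else {
    lt <- as.POSIXlt(time)
    as.integer(ceiling((lt$yday + 1) / 7))
  }
}

# Calendar date (local clock, no DST adjustment) of a timestamp vector.
clock_date <- function(time) {
  as.Date(strftime(time, "%Y-%m-%d"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
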