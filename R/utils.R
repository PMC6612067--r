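# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_iso_date <- function(x, field = "date") {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  out[nonblank] <- parsed
  attr(out, "bad_rows") <- which(nonblank)[is.na(parsed)]
  out
}

# age in completed years at a reference date (calendar arithmetic, no 365.25)
#' @noRd
age_at <- function(birth_date, at_date) {
  by <- as.integer(format(birth_date, "%Y"))
  ay <- as.integer(format(at_date, "%Y"))
  pre <- format(at_date, "%m%d") < format(birth_date, "%m%d")
  ay - by - as.integer(pre)
}

# order-statistic percentile: linear interpolation at rank 1 + (n-1)q
# ("interpolate", stats::quantile type 7) or nearest-rank (type 1)
#' @noRd
interp_quantile <- function(x, q, method = c("interpolate", "nearest")) {
  method <- match.arg(method)
  type <- if (method == "interpolate") 7L else 1L
  unname(stats::quantile(x, probs = q, type = type, names = FALSE))
}

# run code with a private RNG stream, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
stop_husegment <- function(...) stop(..., call. = FALSE)
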