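# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

na_date <- function() as.Date(NA_integer_)

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
  if (any(is.na(d) & !is.na(x) & nzchar(as.character(x)))) {
    stop(sprintf("invalid %s: %s", what,
                 paste(x[is.na(d)], collapse = ", ")), call. = FALSE)
  }
  d
}

# min over non-missing dates; all missing -> NA ("any of" semantics)
date_min_any <- function(...) {
  d <- do.call(c, lapply(list(...), function(x) as.Date(x)))
  d <- d[!is.na(d)]
  if (!length(d)) na_date() else min(d)
}

# max requiring every component ("all of" semantics); any NA -> NA
date_max_all <- function(...) {
  d <- do.call(c, lapply(list(...), function(x) as.Date(x)))
  if (!length(d) || anyNA(d)) na_date() else max(d)
}

# calendar-year shift; Feb 29 normalizes forward to Mar 1 in non-leap years
add_years <- function(d, n) {
  if (is.na(d)) return(na_date())
  lt <- as.POSIXlt(d)
  lt$year <- lt$year + n
  as.Date(lt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# parse "TRUE"/"FALSE"/"1"/"0"/"yes"/"no" etc.
parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out)) {
    stop("cannot interpret as logical: ",
         paste(unique(v[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
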