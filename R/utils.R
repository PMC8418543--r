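`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a value from a scenario by dotted path
#'
#' @param s a `bmn_scenario` (or plain nested list)
#' @param path dotted key path, e.g. `"fermentation.magnetite_yield_mg_l"`
#' @return the value stored at `path`
#' @export
scenario_get <- function(s, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (k in keys) {
    if (!is.list(s) || is.null(s[[k]]))
      stop("no parameter at path '", path, "' (missing key '", k, "')",
           call. = FALSE)
    s <- s[[k]]
  }
  s
}

#' Set a value in a scenario by dotted path
#'
#' @inheritParams scenario_get
#' @param value replacement value
#' @return the modified scenario
#' @export
scenario_set <- function(s, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    if (!is.list(x) || is.null(x[[keys[1]]]))
      stop("no parameter at path '", path, "' (missing key '", keys[1], "')",
           call. = FALSE)
    if (length(keys) == 1L) x[[keys]] <- value
    else x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    x
  }
  out <- rec(unclass(s), keys)
  class(out) <- class(s)
  out
}

# convert a price entry to USD per native unit
price_usd <- function(entry, exchange_rate) {
  if (identical(entry$currency %||% "USD", "BRL"))
    entry$price / exchange_rate
  else entry$price
}
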