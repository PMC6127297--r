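#' Null-coalescing helper
#'
#' Returns `y` when `x` is NULL, otherwise `x`.
#'
#' @param x,y Values.
#' @return `x` unless it is NULL, else `y`.
#' @name op-null-default
#' @export
`%||%` <- function(x, y) if (is.null(x)) y else x
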