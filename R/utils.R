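#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

# convert (n x d) integer coordinate matrix to linear indices for array dims
coords_to_linear <- function(co, dims) {
  lin <- co[, 1L]
  mult <- 1L
  for (d in seq_along(dims)[-1L]) {
    mult <- mult * dims[d - 1L]
    lin <- lin + (co[, d] - 1L) * mult
  }
  lin
}

# derive a 32-bit-safe child seed from a base seed and a stream label
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2011 + as.numeric(stream) * 7919) %% 2147483629)
}
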