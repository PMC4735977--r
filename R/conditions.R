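#' @keywords internal
#' @noRd
coexmi_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "coexmi_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# log2 with the 0*log2(0) = 0 convention applied by callers; here just guard
#' @noRd
xlog2x <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}
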