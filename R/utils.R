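# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_handkin <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "handkin_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || (positive && x <= 0)) {
    stop_handkin(sprintf("`%s` must be a single %sfinite number", name,
                         if (positive) "positive " else ""),
                 "handkin_parameter_error")
  }
  invisible(x)
}

# map angles (degrees) into (-180, 180]; also clears negative zero
wrap_half_open <- function(theta) {
  theta[!is.na(theta) & theta <= -180] <- 180
  theta[!is.na(theta) & theta == 0] <- 0
  theta
}

# median absolute deviation without the 1.4826 consistency factor
mad_raw <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(abs(x - stats::median(x)))
}
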