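#' @importFrom methods as is
#' @importFrom stats kmeans rnbinom rbinom rnorm runif rmultinom dist
#' @importFrom utils read.table write.table modifyList
NULL

# Typed conditions so callers (and the CLI wrapper) can map failures to
# exit codes: config -> 2, format/input -> 3, numerical -> 4.
stop_scanchor <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "scanchor_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config    <- function(msg, ...) stop_scanchor("scanchor_config_error", msg, ...)
stop_format    <- function(msg, ...) stop_scanchor("scanchor_format_error", msg, ...)
stop_input     <- function(msg, ...) stop_scanchor("scanchor_input_error", msg, ...)
stop_numerical <- function(msg, ...) stop_scanchor("scanchor_numerical_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else x
}

# Frobenius norm squared
fnorm2 <- function(x) sum(x * x)

# Deterministic child seeds derived from one run seed; kept < 2^31.
child_seed <- function(seed, salt) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(salt) * 7L + 1L
}

check_finite <- function(x, what, phase = NULL) {
  if (!all(is.finite(x))) {
    if (is.null(phase)) {
      stop_numerical("non-finite values encountered in %s", what)
    }
    stop_numerical("non-finite values encountered in %s (phase: %s)", what, phase)
  }
  invisible(x)
}
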