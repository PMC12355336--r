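# Shared helpers: classed conditions and small validators.

cf_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "farmcf_error"), ...)
}

cf_warn <- function(msg, class = "farmcf_warning") {
  rlang::warn(msg, class = class)
}

# Non-negative finite numeric check with a contextual name.
check_nonneg <- function(x, what) {
  if (length(x) == 0) return(invisible(TRUE))
  if (any(!is.finite(x))) {
    cf_abort(paste0(what, " must be finite."), "farmcf_validation_error")
  }
  if (any(x < 0)) {
    cf_abort(paste0(what, " must be >= 0 (got ", min(x), ")."),
             "farmcf_validation_error")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
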