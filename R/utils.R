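# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a temporary RNG seed, restoring .Random.seed afterwards so
# seeded helpers never perturb the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

abort_ntcp <- function(message, class) {
  rlang::abort(message, class = c(class, "ntcpxero_error"))
}

check_prob_vector <- function(p, arg = "predicted", open = TRUE) {
  if (!is.numeric(p) || anyNA(p)) {
    abort_ntcp(sprintf("`%s` must be a numeric vector without missing values.", arg),
               "ntcpxero_input_error")
  }
  if (open && (any(p <= 0) || any(p >= 1))) {
    abort_ntcp(sprintf("`%s` must lie strictly in (0, 1).", arg),
               "ntcpxero_input_error")
  }
  invisible(p)
}

check_binary_vector <- function(y, arg = "observed") {
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    abort_ntcp(sprintf("`%s` must be a 0/1 (or logical) vector without missing values.", arg),
               "ntcpxero_input_error")
  }
  as.integer(y)
}
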