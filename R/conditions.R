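# Classed conditions so callers can distinguish failure modes programmatically.
# All inherit from "hygrosorb_error".

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hygrosorb_error"), call = call))
}

abort_domain <- function(msg) abort(msg, "hygrosorb_domain_error")
abort_range <- function(msg) abort(msg, "hygrosorb_range_error")
abort_validation <- function(msg) abort(msg, "hygrosorb_validation_error")
abort_size <- function(msg) abort(msg, "hygrosorb_size_error")
abort_lookup <- function(msg) abort(msg, "hygrosorb_lookup_error")
abort_convergence <- function(msg) abort(msg, "hygrosorb_convergence_error")
abort_degenerate <- function(msg) abort(msg, "hygrosorb_degenerate_error")
abort_unsupported <- function(msg) abort(msg, "hygrosorb_unsupported_model_error")
abort_parse <- function(msg) abort(msg, "hygrosorb_parse_error")
abort_config <- function(msg) abort(msg, "hygrosorb_config_error")

# Evaluate `code` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_validation("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
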