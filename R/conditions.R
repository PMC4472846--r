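# Classed conditions so the CLI can map failures to exit codes
# (2 config, 3 input, 4 runtime).

mq_error <- function(msg, class, call = sys.call(-1)) {
  structure(
    class = c(class, "mq_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

stop_config <- function(...) stop(mq_error(paste0(...), "mq_config_error"))
stop_input <- function(...) stop(mq_error(paste0(...), "mq_input_error"))
stop_io <- function(...) stop(mq_error(paste0(...), "mq_io_error"))

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, then restores the caller's RNG state so that
#' deterministic simulation never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
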