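#' Derive a reproducible stage seed from a master seed
#'
#' Hashes the master seed together with a stage label (and optionally a trait
#' or replicate identifier) into a 31-bit integer seed. Adding a new stage or
#' trait never reshuffles the seeds of existing ones.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels identifying the stage (e.g. stage
#'   name, trait id, replicate number).
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  key <- paste(c(format(master, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "\x1f")
  h <- 0
  mod <- 2147483647          # 2^31 - 1, keeps every derived seed a valid R integer
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% mod
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fatal <- function(...) stop(..., call. = FALSE)
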