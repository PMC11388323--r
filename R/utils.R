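`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one user-visible seed; each stage
#' draws from its own substream derived with a fixed offset so stages can be
#' replayed independently.
#'
#' @param seed Integer master seed.
#' @param offset Integer offset naming the substream.
#' @return An integer seed below `.Machine$integer.max`.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% (.Machine$integer.max - 1L))
}

stop_config <- function(...) {
  stop(structure(class = c("eventseg_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

# midranks per column of a matrix
col_ranks <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  apply(M, 2L, rank)
}
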