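# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (genotypes, OTU counts, random effects, CV splits) use sub-streams
#' derived from it so that adding a stage never perturbs another stage's
#' draws.
#'
#' @param seed master seed (integer).
#' @param offset stream index (small non-negative integer).
#' @return an integer seed, always in [0, 2^31 - 1).
#' @keywords internal
sub_seed <- function(seed, offset) {
  # linear congruential scramble; modulus keeps the result a valid R integer
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + 7919 * (offset + 1)) %%
               2147483647)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_config("`%s` must be a single integer >= %d (got %s)",
                name, min, deparse(substitute(x)))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("`%s` must be a probability in [0, 1]", name)
  as.numeric(x)
}

# Shared check that a matrix-like object has unique row ids.
check_ids <- function(ids, what) {
  if (anyDuplicated(ids))
    stop_config("duplicate %s ids: %s", what,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(ids)
}

# zero-padded sequential identifiers, e.g. animal_007
make_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "_%0", nchar(as.character(n)), "d"), seq_len(n))
}
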