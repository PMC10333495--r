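# internal validation helpers --------------------------------------------

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# Counter-based per-run seed derivation: run i of a multi-restart protocol
# uses seed (master_seed + i) mod (2^31 - 1), so any single run can be
# replayed in isolation from its recorded seed.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + as.numeric(counter)) %% 2147483647)
}

# evaluate an expression under a private RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

abbreviate_list <- function(x, max = 5L) {
  if (length(x) <= max) return(paste(x, collapse = ", "))
  paste0(paste(x[seq_len(max)], collapse = ", "),
         ", ... and ", length(x) - max, " more")
}
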