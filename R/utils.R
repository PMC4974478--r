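# Small sequence helpers shared across modules. Strings are plain uppercase
# character vectors; Biostrings does the actual biology.

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a nucleotide string; trailing partial codon is dropped.
# Stops are "*"; never silently removed.
translate_nt <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n == 0L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")
  ))
}

# Truncate a protein string at the first stop (exclusive).
before_stop <- function(aa) sub("\\*.*$", "", aa)

#' Evaluate code with a fixed, restorable RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random
#' stream afterwards, so simulation helpers are deterministic per seed
#' without leaking global RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
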