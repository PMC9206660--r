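# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Convert a PHRED quality string to integer scores (offset 33)
#' @noRd
phred_to_int <- function(q) {
  if (!nzchar(q)) return(integer(0))
  utf8ToInt(q) - 33L
}

#' Convert integer PHRED scores to an offset-33 quality string
#' @noRd
int_to_phred <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(q + 33L)
}

#' Random DNA string(s)
#' @noRd
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of plain character sequences
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
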