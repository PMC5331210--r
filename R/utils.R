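# Internal helpers shared across modules.

# Derive a child seed from a caller-supplied seed and a component tag, so
# that each generator component consumes an independent, reproducible RNG
# stream. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 69069 + h * 1013 + 7) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Phred+33 (Sanger) quality encoding
#'
#' @param q Integer vector of Phred scores.
#' @return `phred_to_char`: the encoded quality string.
#' @export
phred_to_char <- function(q) {
  intToUtf8(as.integer(q) + 33L, multiple = FALSE)
}

#' @param s Quality string.
#' @return `char_to_phred`: integer vector of Phred scores.
#' @rdname phred_to_char
#' @export
char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Biostrings emits a benign "metadata columns ... dropped" warning when
# (de)constructing quality-scaled string sets from named vectors; muffle
# only that.
quiet_biostrings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
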