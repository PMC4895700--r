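#' @useDynLib mirnome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-stage / per-library seed from a global one (kept < 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the DNA alphabet (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Deterministic (locale-independent) ordering helpers.
radix_order <- function(...) order(..., method = "radix")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
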