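# Read filtration cascade: discard ambiguous, 5'-adapter-bearing, adapterless
# and poly-A reads, require 6-18 nt of 3' adapter, trim it, and collapse
# identical inserts into unique tags.

#' QC parameter set
#'
#' @param min_tail,max_tail accepted 3' adapter match length (nt).
#' @param min_len,max_len accepted insert length after trimming.
#' @param polya_run minimum trailing-A run that marks a poly-A insert.
#' @param polya_frac overall A fraction above which an insert is poly-A.
#' @param adapter5_k minimum exact 5'-adapter substring marking a dimer.
#' @return named list of QC parameters.
#' @export
qc_params <- function(min_tail = 6L, max_tail = 18L, min_len = 16L,
                      max_len = 27L, polya_run = 6L, polya_frac = 0.8,
                      adapter5_k = 10L) {
  list(min_tail = min_tail, max_tail = max_tail, min_len = min_len,
       max_len = max_len, polya_run = polya_run, polya_frac = polya_frac,
       adapter5_k = adapter5_k)
}

qc_decisions <- c("keep", "drop_polyA", "drop_ambiguous", "drop_5adapter",
                  "drop_no3adapter", "drop_length")

#' Trim the 3' adapter from read sequences
#'
#' Finds the longest prefix of `adapter_3p` occurring as an exact suffix of
#' each sequence and removes it. A matched length of 0 means no adapter
#' prefix was found.
#'
#' @param seq character vector of read sequences.
#' @param adapter_3p 3' adapter sequence.
#' @param min_match shortest adapter prefix accepted as a match; shorter
#'   coincidental suffixes report `matched_len = 0`.
#' @return list with `insert` (trimmed sequences) and `matched_len`.
#' @export
trim_3adapter <- function(seq, adapter_3p, min_match = 6L) {
  if (any(!nzchar(seq))) stop("malformed read: empty sequence")
  n <- nchar(seq)
  matched <- integer(length(seq))
  hi <- min(nchar(adapter_3p), max(n))
  if (hi >= min_match) {
    for (L in seq(hi, min_match)) {
      todo <- matched == 0L & n >= L
      if (!any(todo)) next
      hit <- substr(seq[todo], n[todo] - L + 1L, n[todo]) ==
        substr(adapter_3p, 1L, L)
      matched[todo][hit] <- L
    }
  }
  list(insert = substr(seq, 1L, n - matched), matched_len = matched)
}

# Vectorised decision for a batch of reads; applied in fixed order so each
# read has a unique primary drop reason:
# ambiguous -> 5' adapter -> 3'-adapter match -> poly-A (on the trimmed
# insert) -> length bounds.
classify_read_batch <- function(seq, adapter_3p, adapter_5p,
                                params = qc_params()) {
  if (length(seq) == 0) {
    return(list(decision = character(), insert = character()))
  }
  if (any(is.na(seq)) || any(!nzchar(seq)))
    stop("malformed read: empty sequence")
  decision <- rep(NA_character_, length(seq))

  decision[grepl("N", seq, fixed = TRUE)] <- "drop_ambiguous"

  k <- params$adapter5_k
  if (nchar(adapter_5p) >= k) {
    subs <- unique(substring(adapter_5p, seq_len(nchar(adapter_5p) - k + 1L),
                             k:nchar(adapter_5p)))
    has5 <- Reduce(`|`, lapply(subs, function(s) grepl(s, seq, fixed = TRUE)))
    decision[is.na(decision) & has5] <- "drop_5adapter"
  }

  tr <- trim_3adapter(seq, adapter_3p, min_match = min(params$min_tail, 6L))
  bad3 <- tr$matched_len < params$min_tail | tr$matched_len > params$max_tail
  decision[is.na(decision) & bad3] <- "drop_no3adapter"

  ins <- tr$insert
  n_a <- nchar(ins) - nchar(gsub("A", "", ins, fixed = TRUE))
  tail_a <- grepl(paste0("A{", params$polya_run, ",}$"), ins)
  polya <- tail_a | (nchar(ins) > 0 & n_a / pmax(nchar(ins), 1L) >=
                       params$polya_frac)
  decision[is.na(decision) & polya] <- "drop_polyA"

  badlen <- nchar(ins) < params$min_len | nchar(ins) > params$max_len
  decision[is.na(decision) & badlen] <- "drop_length"

  decision[is.na(decision)] <- "keep"
  list(decision = decision, insert = ins)
}

#' Classify a single read through the filtration cascade
#'
#' Checks are applied in fixed order (ambiguous nucleotides, 5' adapter,
#' 3'-adapter match length in \[min_tail, max_tail\], poly-A insert, insert
#' length bounds) so that exactly one decision is returned.
#'
#' @param seq read sequence (A/C/G/T/N).
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param params [qc_params()].
#' @return one of `keep`, `drop_polyA`, `drop_ambiguous`, `drop_5adapter`,
#'   `drop_no3adapter`, `drop_length`.
#' @export
classify_read <- function(seq, adapter_3p, adapter_5p, params = qc_params()) {
  classify_read_batch(seq, adapter_3p, adapter_5p, params)$decision
}

#' Collapse identical inserts into unique tags
#'
#' @param inserts character vector of QC-passed insert sequences.
#' @return data.frame of `seq` and `count`, sorted by descending count then
#'   lexicographic sequence; counts sum to `length(inserts)`.
#' @export
collapse_tags <- function(inserts) {
  if (length(inserts) == 0) {
    return(data.frame(seq = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[radix_order(-out$count, out$seq), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Run the full QC stage on a read set
#'
#' @param reads data.frame with `seq` (and optionally `id`, `qual`).
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param params [qc_params()].
#' @return list with `tags` (collapsed unique inserts with counts) and
#'   `report` (named counters per decision; they sum to the input read
#'   count).
#' @export
qc_reads <- function(reads, adapter_3p = default_adapters()$adapter_3p,
                     adapter_5p = default_adapters()$adapter_5p,
                     params = qc_params()) {
  res <- classify_read_batch(reads$seq, adapter_3p, adapter_5p, params)
  report <- vapply(qc_decisions, function(d) sum(res$decision == d),
                   integer(1))
  tags <- collapse_tags(res$insert[res$decision == "keep"])
  list(tags = tags, report = report)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the collapsed-read dialect used by common small-RNA tools:
#' `tag{serial}_x{count}`.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$seq)
  names(x) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
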