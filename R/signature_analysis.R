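# Signature comparison across conditions: set overlaps with percentages and
# a GSEA-style running-sum enrichment statistic with a seeded permutation
# null. The statistic is the classic unweighted Kolmogorov-Smirnov running
# sum with gene-set permutation — the only variant computable without
# replicate phenotypes.

#' Overlap between two identifier sets
#'
#' @param set_a,set_b character vectors of identifiers (duplicates ignored);
#'   `set_a` must be non-empty (its size is the percentage denominator).
#' @return list: `size_a`, `size_b`, `intersection`, `percent_of_a`
#'   (100 * |A n B| / |A|).
#' @export
overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0)
    stop("undefined percentage: set_a is empty")
  i <- length(intersect(set_a, set_b))
  list(size_a = length(set_a), size_b = length(set_b), intersection = i,
       percent_of_a = 100 * i / length(set_a))
}

# Running-sum enrichment score for hit positions in a ranking of n items.
running_es <- function(n, hit_pos) {
  nh <- length(hit_pos)
  step <- rep(-1 / (n - nh), n)
  step[hit_pos] <- 1 / nh
  cs <- cumsum(step)
  cs[which.max(abs(cs))]
}

#' GSEA-style enrichment of a gene set in a ranked list
#'
#' The enrichment score is the maximum deviation of (cumulative hit fraction
#' minus cumulative miss fraction) along the ranking, signed by the deviation
#' direction. The p-value is `(1 + #{|ES*| >= |ES|}) / (n_perm + 1)` over
#' uniform random gene sets of equal size, so it can never fall below its
#' permutation floor.
#'
#' @param ranked_ids identifiers ordered by the ranking metric (descending,
#'   e.g. log fold change).
#' @param gene_set non-empty proper subset of `ranked_ids`.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed; fixed seed gives identical results.
#' @return list of class `enrichment_result`: `es` in \[-1, 1\], `p_value`,
#'   `n_permutations`, `seed`.
#' @export
gsea_enrichment <- function(ranked_ids, gene_set, n_perm = 1000L, seed = 1L) {
  n <- length(ranked_ids)
  if (anyDuplicated(ranked_ids)) stop("ranked_ids must be unique")
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0 || !all(gene_set %in% ranked_ids))
    stop("input error: gene_set must be a non-empty subset of ranked_ids")
  if (length(gene_set) >= n)
    stop("input error: gene_set must be a proper subset of the ranking")
  hit_pos <- which(ranked_ids %in% gene_set)
  es <- running_es(n, hit_pos)
  k <- length(hit_pos)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    running_es(n, sample.int(n, k))
  }, numeric(1)))
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  structure(list(es = es, p_value = p, n_permutations = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' Build a signature from a differential call
#'
#' @param call a `differential_call` from [call_differential()].
#' @return list of class `signature`: `label`, `up`, `down`, `fold_by_id`.
#' @export
as_signature <- function(call) {
  stopifnot(inherits(call, "differential_call"))
  structure(list(label = call$label, up = call$up, down = call$down,
                 fold_by_id = stats::setNames(call$folds$fold,
                                              call$folds$mirna_id)),
            class = "signature")
}

#' Assemble the signature comparison report
#'
#' Collects per-comparison differential counts, overlap percentages
#' (rounded to one decimal for display; raw values retained), enrichment
#' results and novel-candidate tallies into one report structure that can be
#' written as JSON and TSV.
#'
#' @param signatures named list of `signature` objects.
#' @param overlaps named list of [overlap()] results.
#' @param enrichments named list of `enrichment_result` objects.
#' @param novel_summary optional list with `n_candidates`, `n_consensus`,
#'   `n_ago_verified` (zeros when absent).
#' @return list of class `signature_report`.
#' @export
signature_report <- function(signatures = list(), overlaps = list(),
                             enrichments = list(), novel_summary = NULL) {
  if (is.null(novel_summary)) {
    novel_summary <- list(n_candidates = 0L, n_consensus = 0L,
                          n_ago_verified = 0L)
  }
  report <- list(
    signatures = lapply(signatures, function(s) {
      list(label = s$label, n_up = length(s$up), n_down = length(s$down))
    }),
    overlaps = lapply(overlaps, function(o) {
      list(size_a = o$size_a, size_b = o$size_b,
           intersection = o$intersection,
           percent_of_a = o$percent_of_a,
           percent_display = round(o$percent_of_a, 1))
    }),
    enrichments = lapply(enrichments, function(e) {
      list(es = e$es, p_value = e$p_value,
           n_permutations = e$n_permutations)
    }),
    novel = novel_summary)
  class(report) <- "signature_report"
  report
}

#' Write a signature report as JSON and TSV
#'
#' @param report a `signature_report`.
#' @param json_path,tsv_path output paths (either may be NULL to skip).
#' @return the report, invisibly.
#' @export
write_signature_report <- function(report, json_path = NULL,
                                   tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    rows <- list()
    for (nm in names(report$signatures)) {
      s <- report$signatures[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        section = "signature", name = nm,
        value = sprintf("up=%d;down=%d", s$n_up, s$n_down))
    }
    for (nm in names(report$overlaps)) {
      o <- report$overlaps[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        section = "overlap", name = nm,
        value = sprintf("%d/%d=%.1f%%", o$intersection, o$size_a,
                        o$percent_display))
    }
    for (nm in names(report$enrichments)) {
      e <- report$enrichments[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        section = "enrichment", name = nm,
        value = sprintf("ES=%.4f;p=%.4g", e$es, e$p_value))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      section = "novel", name = "tallies",
      value = sprintf("candidates=%d;consensus=%d;ago_verified=%d",
                      report$novel$n_candidates, report$novel$n_consensus,
                      report$novel$n_ago_verified))
    write_tsv(do.call(rbind, rows), tsv_path)
  }
  invisible(report)
}
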