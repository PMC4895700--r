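# Novel-miRNA discovery: cluster unannotated read placements into stacks,
# excise candidate precursors around the dominant tag, fold them by
# pair-maximisation (Nussinov with GU wobble), classify hairpins under three
# stringency presets emulating a three-detector intersection, and verify
# candidates against Ago1/2 RIP-seq read support.

#' Fold a sequence by Nussinov base-pair maximisation
#'
#' Maximises Watson-Crick + GU-wobble pair count over nested structures with
#' a hairpin-loop minimum (`j - i > min_loop`). T is treated as U. The
#' traceback is deterministic (pairing preferred over bifurcation on ties;
#' smallest split point wins).
#'
#' @param seq DNA/RNA sequence, 2-500 nt (U accepted and mapped to T).
#' @param min_loop minimum unpaired loop span (default 3).
#' @return object of class `fold_result`: `seq`, `pairs` (two-column matrix
#'   of 1-based indices, i < j), `n_pairs`, `structure` (dot-bracket).
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  seq <- toupper(chartr("u", "t", seq))
  seq <- chartr("U", "T", seq)
  n <- nchar(seq)
  if (n < 2 || n > 500)
    stop("input error: sequence length must be in [2, 500]")
  pairs <- nussinov_pairs(seq, as.integer(min_loop))
  if (nrow(pairs) > 1) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(seq = seq, pairs = pairs, n_pairs = nrow(pairs),
                 structure = dot_bracket(n, pairs)),
            class = "fold_result")
}

#' Dot-bracket notation helpers
#'
#' `dot_bracket` renders a pair list as a dot-bracket string;
#' `parse_dotbracket` inverts it.
#'
#' @param n sequence length.
#' @param pairs two-column matrix of 1-based pair indices (i < j).
#' @return `dot_bracket`: a string; `parse_dotbracket`: a pair matrix.
#' @export
dot_bracket <- function(n, pairs) {
  x <- rep(".", n)
  if (nrow(pairs)) {
    x[pairs[, 1]] <- "("
    x[pairs[, 2]] <- ")"
  }
  paste(x, collapse = "")
}

#' @rdname dot_bracket
#' @param structure dot-bracket string.
#' @export
parse_dotbracket <- function(structure) {
  x <- strsplit(structure, "")[[1]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(x)) {
    if (x[i] == "(") open <- c(open, i)
    else if (x[i] == ")") {
      j <- open[length(open)]
      open <- open[-length(open)]
      out <- rbind(out, c(j, i))
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  out[order(out[, 1]), , drop = FALSE]
}

#' Hairpin-classification stringency presets
#'
#' Three presets of one detector emulate the published practice of
#' intersecting three independent discovery algorithms: they share the
#' topology rules and differ in how many mature bases must pair and how
#' much of the precursor must be in the stem.
#'
#' @return named list of presets (`lenient`, `default`, `strict`), each with
#'   `min_mature_paired` (of a 22-mer) and `min_stem_fraction`.
#' @export
hairpin_presets <- function() {
  list(lenient = list(name = "lenient", min_mature_paired = 14L,
                      min_stem_fraction = 0.50),
       default = list(name = "default", min_mature_paired = 15L,
                      min_stem_fraction = 0.55),
       strict = list(name = "strict", min_mature_paired = 16L,
                     min_stem_fraction = 0.60))
}

# Pairs with no other pair nested strictly inside (the hairpin loops).
terminal_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  keep <- vapply(seq_len(nrow(pairs)), function(r) {
    !any(pairs[, 1] > pairs[r, 1] & pairs[, 2] < pairs[r, 2])
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

#' Classify a folded precursor as a miRNA-like hairpin
#'
#' Pass requires: (a) exactly one terminal loop (a single stem-loop);
#' (b) the mature interval lies on one arm, not overlapping the terminal
#' loop; (c) at least `preset$min_mature_paired` mature bases are paired;
#' (d) the paired fraction of the whole precursor is at least
#' `preset$min_stem_fraction`.
#'
#' @param fold a `fold_result`.
#' @param mature_interval integer pair: 1-based mature start/end within the
#'   precursor.
#' @param preset one element of [hairpin_presets()].
#' @return list: `pass` flag, `reasons` (character vector of failed
#'   criteria), `mature_paired`, `stem_fraction`, `n_terminal_loops`.
#' @export
classify_hairpin <- function(fold, mature_interval,
                             preset = hairpin_presets()$default) {
  stopifnot(inherits(fold, "fold_result"), length(mature_interval) == 2)
  n <- nchar(fold$seq)
  ms <- mature_interval[1]; me <- mature_interval[2]
  if (ms < 1 || me > n || ms > me)
    stop("mature interval must lie within the precursor")
  reasons <- character(0)
  term <- terminal_pairs(fold$pairs)
  if (nrow(term) != 1L) reasons <- c(reasons, "not_single_stem_loop")
  if (nrow(term) >= 1L) {
    # loop of the terminal pair nearest the mature arm
    t <- term[which.min(pmax(term[, 1] - me, ms - term[, 2], 0L)), ]
    if (!(me <= t[1] || ms >= t[2]))
      reasons <- c(reasons, "mature_overlaps_terminal_loop")
  } else {
    reasons <- c(reasons, "mature_overlaps_terminal_loop")
  }
  paired_idx <- unique(as.vector(fold$pairs))
  mature_paired <- sum(paired_idx >= ms & paired_idx <= me)
  if (mature_paired < preset$min_mature_paired)
    reasons <- c(reasons, "too_few_mature_bases_paired")
  stem_fraction <- 2 * fold$n_pairs / n
  if (stem_fraction < preset$min_stem_fraction)
    reasons <- c(reasons, "stem_fraction_too_low")
  list(pass = length(reasons) == 0L, reasons = reasons,
       mature_paired = mature_paired, stem_fraction = stem_fraction,
       n_terminal_loops = nrow(term))
}

#' Trim a folded excision window to the single stem-loop around the mature
#'
#' Pair-maximising folds of windows wider than the true precursor decorate
#' the flanks with small spurious hairpins; this helper selects the terminal
#' loop nearest the mature tag, walks outward through its nested ancestors
#' while they enclose no second terminal loop, and returns the re-indexed
#' fold of that maximal single-stem region.
#'
#' @param fold `fold_result` of the excised window.
#' @param mature_interval mature start/end within the window.
#' @return list with `fold` (trimmed `fold_result`), `region` (start/end of
#'   the trimmed precursor within the window) and `mature` (re-indexed
#'   interval), or NULL when the window has no stem containing the mature.
#' @export
trim_to_hairpin <- function(fold, mature_interval) {
  if (!nrow(fold$pairs)) return(NULL)
  ms <- mature_interval[1]; me <- mature_interval[2]
  term <- terminal_pairs(fold$pairs)
  d <- pmax(term[, 1] - me, ms - term[, 2], 0L)
  t <- term[which.min(d), ]
  anc <- fold$pairs[fold$pairs[, 1] <= t[1] & fold$pairs[, 2] >= t[2], ,
                    drop = FALSE]
  anc <- anc[order(-anc[, 1]), , drop = FALSE] # innermost first
  a0 <- t[1]; b0 <- t[2]
  for (r in seq_len(nrow(anc))) {
    second <- any(term[, 1] > anc[r, 1] & term[, 2] < anc[r, 2] &
                    !(term[, 1] == t[1] & term[, 2] == t[2]))
    if (second) break
    a0 <- anc[r, 1]; b0 <- anc[r, 2]
  }
  # extend the region to cover mature bases just outside the stem; pairs
  # reaching outside the region are dropped (those bases count as unpaired)
  a0 <- min(a0, ms); b0 <- max(b0, me)
  sub <- fold$pairs[fold$pairs[, 1] >= a0 & fold$pairs[, 2] <= b0, ,
                    drop = FALSE]
  sub <- sub - (a0 - 1L)
  seq <- substr(fold$seq, a0, b0)
  trimmed <- structure(list(seq = seq, pairs = sub, n_pairs = nrow(sub),
                            structure = dot_bracket(nchar(seq), sub)),
                       class = "fold_result")
  list(fold = trimmed, region = c(a0, b0), mature = c(ms, me) - (a0 - 1L))
}

#' Cluster unannotated placements into read stacks
#'
#' Single-linkage clustering along each chromosome and strand: placements
#' whose intervals lie within `max_gap` of each other join one stack; stacks
#' below `min_reads` total counts are discarded.
#'
#' @param placements data.frame with `tag_seq`, `chrom`, `start`, `end`,
#'   `strand`, `count`.
#' @param max_gap maximum gap (nt) joining two placements (default 10).
#' @param min_reads minimum total read count per stack (default 5).
#' @return list of stacks; each has `chrom`, `strand`, `start`, `end`,
#'   `tags` (the member placements) and `total_count`.
#' @export
build_stacks <- function(placements, max_gap = 10L, min_reads = 5L) {
  if (is.null(placements) || nrow(placements) == 0) return(list())
  out <- list()
  for (key in split(seq_len(nrow(placements)),
                    paste(placements$chrom, placements$strand))) {
    d <- placements[key, , drop = FALSE]
    d <- d[radix_order(d$start, d$end, d$tag_seq), , drop = FALSE]
    grp <- integer(nrow(d))
    g <- 1L; grp[1] <- 1L
    reach <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] > reach + max_gap) g <- g + 1L
      grp[i] <- g
      reach <- max(reach, d$end[i])
    }
    for (s in split(d, grp)) {
      if (sum(s$count) < min_reads) next
      out[[length(out) + 1L]] <-
        list(chrom = s$chrom[1], strand = s$strand[1],
             start = min(s$start), end = max(s$end), tags = s,
             total_count = sum(s$count))
    }
  }
  ord <- radix_order(vapply(out, function(s) s$chrom, character(1)),
                     vapply(out, function(s) s$start, numeric(1)),
                     vapply(out, function(s) s$strand, character(1)))
  out[ord]
}

# Evaluate one excised window: the mature tag is anchored at one end, so
# candidate precursor extents grow from that end; each extent is folded,
# trimmed to the stem-loop around the mature and classified under every
# preset. Pair maximisation over-pairs wide windows, so the best-scoring
# extent delimits the precursor. Returns the best result.
evaluate_window <- function(wseq, m_int, presets) {
  wlen <- nchar(wseq)
  mat_len <- m_int[2] - m_int[1] + 1L
  at_start <- m_int[1] == 1L
  extents <- unique(pmin(c(seq(mat_len + 28L, wlen, by = 7L), wlen), wlen))
  extents <- extents[extents >= mat_len + 10L]
  best <- list(passes = stats::setNames(rep(FALSE, length(presets)),
                                        names(presets)),
               region = NULL, fold = NULL, score = -1L)
  for (e in extents) {
    if (at_start) {
      sub <- substr(wseq, 1L, e)
      m <- m_int
      off <- 0L
    } else {
      sub <- substr(wseq, wlen - e + 1L, wlen)
      off <- wlen - e
      m <- m_int - off
    }
    fr <- fold_nussinov(sub)
    tr <- trim_to_hairpin(fr, m)
    if (is.null(tr)) next
    passes <- vapply(presets, function(p) {
      classify_hairpin(tr$fold, tr$mature, p)$pass
    }, logical(1))
    score <- sum(passes)
    if (score > best$score) {
      best <- list(passes = passes, region = tr$region + off,
                   fold = tr$fold, score = score)
    }
    if (score == length(presets)) break
  }
  best
}

#' Detect consensus novel-miRNA candidates from read stacks
#'
#' For each stack the modal (highest-count) tag defines the putative mature
#' species (ties broken by 5'-most genomic start). Two precursor windows are
#' excised — mature plus `flank` nt downstream, and upstream, in transcript
#' orientation — folded, trimmed to the single stem-loop around the mature
#' ([trim_to_hairpin()]) and classified under every preset. A candidate is a
#' consensus call when at least `quorum` presets pass on the same window.
#'
#' @param stacks list from [build_stacks()].
#' @param genome named `DNAStringSet`.
#' @param presets list of presets (default [hairpin_presets()]).
#' @param quorum presets that must agree (default all three).
#' @param flank excision flank in nt (default 70).
#' @return data.frame of candidates sorted by descending total count:
#'   locus, mature interval and sequence, per-preset pass flags, `consensus`,
#'   dot-bracket `structure` of the trimmed precursor.
#' @export
consensus_detect <- function(stacks, genome, presets = hairpin_presets(),
                             quorum = 3L, flank = 70L) {
  if (quorum > length(presets))
    stop("config error: quorum exceeds the number of presets")
  if (length(unique(vapply(presets, function(p) {
    paste(p$min_mature_paired, p$min_stem_fraction)
  }, character(1))) ) != length(presets))
    stop("config error: presets must be distinct")
  rows <- list()
  for (st in stacks) {
    tg <- st$tags
    best <- which(tg$count == max(tg$count))
    best <- best[which.min(tg$start[best])]
    mat_start <- tg$start[best]; mat_end <- tg$end[best]
    mat_len <- mat_end - mat_start + 1L
    chrom_len <- Biostrings::width(genome)[match(st$chrom, names(genome))]
    windows <- if (st$strand == "+") {
      list(downstream = c(mat_start, min(mat_end + flank, chrom_len)),
           upstream = c(max(mat_start - flank, 1L), mat_end))
    } else {
      list(downstream = c(max(mat_start - flank, 1L), mat_end),
           upstream = c(mat_start, min(mat_end + flank, chrom_len)))
    }
    cand <- NULL
    for (wname in names(windows)) {
      w <- windows[[wname]]
      wseq <- as.character(Biostrings::subseq(genome[[st$chrom]], w[1], w[2]))
      if (st$strand == "-") wseq <- revcomp(wseq)
      # mature position in transcript coordinates within the window
      moff <- if (st$strand == "+") mat_start - w[1] else w[2] - mat_end
      m_int <- c(moff + 1L, moff + mat_len)
      ev <- evaluate_window(wseq, m_int, presets)
      passes <- ev$passes
      tr_region <- ev$region # window coordinates, or NULL
      pre <- if (is.null(tr_region)) w else {
        if (st$strand == "+") w[1] - 1L + tr_region
        else c(w[2] + 1L - tr_region[2], w[2] + 1L - tr_region[1])
      }
      row <- data.frame(
        chrom = st$chrom, strand = st$strand,
        pre_start = pre[1], pre_end = pre[2],
        mat_start = mat_start, mat_end = mat_end,
        mature_seq = tg$tag_seq[best], total_count = st$total_count,
        window = wname, t(as.matrix(passes)),
        n_presets_pass = sum(passes),
        consensus = sum(passes) >= quorum,
        structure = if (is.null(ev$fold)) "" else ev$fold$structure,
        stringsAsFactors = FALSE)
      if (is.null(cand) || row$n_presets_pass > cand$n_presets_pass)
        cand <- row
    }
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) {
    d <- data.frame(candidate_id = character(), chrom = character(),
                    strand = character(), pre_start = integer(),
                    pre_end = integer(), mat_start = integer(),
                    mat_end = integer(), mature_seq = character(),
                    total_count = integer(), window = character(),
                    n_presets_pass = integer(), consensus = logical(),
                    structure = character(), stringsAsFactors = FALSE)
    for (p in names(presets)) d[[p]] <- logical(0)
    return(d)
  }
  d <- do.call(rbind, rows)
  d <- d[radix_order(-d$total_count, d$chrom, d$mat_start), , drop = FALSE]
  d <- cbind(candidate_id = sprintf("cand-%03d", seq_len(nrow(d))), d,
             stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

#' Verify candidates against Ago1/2 RIP-seq read support
#'
#' A candidate is Ago-verified when at least `min_reads` reads overlap its
#' mature interval (>= 50% of the read inside, same strand) in at least
#' `min_datasets` RIP libraries.
#'
#' @param candidates data.frame from [consensus_detect()].
#' @param ago_placements list of per-library placement data.frames (with
#'   `count`), e.g. from QC + [place_tags()] on RIP reads.
#' @param min_reads,min_datasets verification thresholds.
#' @return `candidates` with added per-library `ago_reads` columns,
#'   `ago_datasets_supporting` and `ago_verified`.
#' @export
verify_agoip <- function(candidates, ago_placements, min_reads = 5L,
                         min_datasets = 1L) {
  if (length(ago_placements) == 0) {
    warning("no Ago libraries supplied; all candidates unverified")
    candidates$ago_datasets_supporting <- 0L
    candidates$ago_verified <- FALSE
    return(candidates)
  }
  counts <- matrix(0L, nrow(candidates), length(ago_placements))
  for (l in seq_along(ago_placements)) {
    pl <- ago_placements[[l]]
    if (is.null(pl) || nrow(pl) == 0) next
    for (i in seq_len(nrow(candidates))) {
      need <- ceiling(0.5 * (pl$end - pl$start + 1L))
      ov <- pl$chrom == candidates$chrom[i] &
        pl$strand == candidates$strand[i] &
        pmin(pl$end, candidates$mat_end[i]) -
          pmax(pl$start, candidates$mat_start[i]) + 1L >= need
      counts[i, l] <- sum(pl$count[ov])
    }
  }
  colnames(counts) <- sprintf("ago_reads_%02d", seq_along(ago_placements))
  candidates <- cbind(candidates, counts, stringsAsFactors = FALSE)
  candidates$ago_datasets_supporting <-
    as.integer(rowSums(counts >= min_reads))
  candidates$ago_verified <-
    candidates$ago_datasets_supporting >= min_datasets
  candidates
}
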