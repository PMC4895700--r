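# Independent oracles and shared fixtures for the test suite.

.fixture_cache <- new.env()

# One small planted study reused across tests (built once per run).
small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- build_simulation(genome_length = 2e4, n_known = 5,
                                           n_novel = 4, n_mrna = 2,
                                           seed = 42)
  }
  .fixture_cache$sim
}

small_refset <- function() {
  if (is.null(.fixture_cache$refset)) {
    sim <- small_sim()
    .fixture_cache$refset <-
      reference_set(sim$genome, sim$mrna,
                    sim$mirnas[sim$mirnas$is_known, , drop = FALSE])
  }
  .fixture_cache$refset
}

# Exhaustive enumeration of nested structures (max pair count); independent
# of the DP implementation. Feasible for sequences <= ~14 nt.
enum_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(seq), "")[[1]]
  ok <- c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (paste0(s[k], s[j]) %in% ok) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, 1L + left + rec(k + 1L, j - 1L))
      }
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}

# Naive O(n*m) substring scan over both strands; the placement oracle.
scan_placements <- function(tag, genome) {
  out <- list()
  L <- nchar(tag)
  for (chrom in names(genome)) {
    g <- as.character(genome[[chrom]])
    n <- nchar(g)
    if (n < L) next
    windows <- substring(g, 1:(n - L + 1L), L:n)
    for (str in c("+", "-")) {
      pat <- if (str == "+") tag else revcomp(tag)
      hit <- which(windows == pat)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          tag_seq = tag, chrom = chrom, start = hit, end = hit + L - 1L,
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag_seq = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand, method = "radix"), ]
  rownames(res) <- NULL
  res
}

# Brute-force single-linkage clustering by transitive closure on the
# "within max_gap" relation; the read-stack oracle.
cluster_oracle <- function(placements, max_gap = 10L) {
  n <- nrow(placements)
  grp <- seq_len(n)
  near <- function(i, j) {
    placements$chrom[i] == placements$chrom[j] &&
      placements$strand[i] == placements$strand[j] &&
      placements$start[j] <= placements$end[i] + max_gap &&
      placements$start[i] <= placements$end[j] + max_gap
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] && near(i, j)) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}

# Non-overlapping dinucleotide block shuffle (preserves block content).
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  blocks <- split(s, ceiling(seq_len(n) / 2))
  paste(unlist(blocks[sample.int(length(blocks))]), collapse = "")
}
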