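# Exact-match placement of clean tags on the genome, mRNA exclusion,
# known-miRNA annotation with multi-mapping multiplicities, and E-box motif
# scanning. Exact matching is appropriate here because simulated reads are
# error-free; mismatch policy is out of scope.

#' Bundle genome, mRNA set and miRNA annotation into a reference set
#'
#' @param genome named `DNAStringSet` (one entry per chromosome) or a FASTA
#'   path.
#' @param mrna `DNAStringSet` of mRNA sequences (the mRNA screen), a FASTA
#'   path, or NULL.
#' @param mirnas known-miRNA annotation data.frame (mirna_id, chrom, strand,
#'   pre_start, pre_end, mat_start, mat_end), or a miRBase-style GFF3 path.
#'   Mature sequences are filled in from the genome when absent.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(genome, mrna = NULL, mirnas = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome)) || anyNA(names(genome)))
    stop("genome chromosomes must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(mrna)) mrna <- Biostrings::readDNAStringSet(mrna)
  if (is.null(mrna)) mrna <- Biostrings::DNAStringSet()
  if (is.character(mirnas)) mirnas <- import_mirna_gff(mirnas)
  if (is.null(mirnas)) mirnas <- empty_mirna_table()
  if (nrow(mirnas) > 0) {
    if (anyDuplicated(mirnas$mirna_id)) stop("mirna_ids must be unique")
    glen <- stats::setNames(Biostrings::width(genome), names(genome))
    if (any(mirnas$pre_end > glen[mirnas$chrom]) || any(mirnas$pre_start < 1))
      stop("annotation intervals outside chromosome bounds")
    if (is.null(mirnas$mature_seq)) {
      mirnas$mature_seq <- vapply(seq_len(nrow(mirnas)), function(i) {
        s <- as.character(Biostrings::subseq(genome[[mirnas$chrom[i]]],
                                             mirnas$mat_start[i],
                                             mirnas$mat_end[i]))
        if (mirnas$strand[i] == "-") revcomp(s) else s
      }, character(1))
    }
  }
  structure(list(genome = genome, mrna = mrna, mirnas = mirnas),
            class = "reference_set")
}

#' Place a tag on the genome by exact match
#'
#' Returns every exact occurrence of the tag on both strands, sorted by
#' (chrom, start, strand). A minus-strand placement means the tag equals the
#' reverse complement of the genomic window starting at `start`.
#'
#' @param tag_seq tag sequence (no N; length >= 12).
#' @param refset [reference_set()] (or a bare `DNAStringSet` genome).
#' @return data.frame: `tag_seq`, `chrom`, `start`, `end`, `strand`; empty
#'   when unmapped.
#' @export
place_tag <- function(tag_seq, refset) {
  genome <- if (inherits(refset, "reference_set")) refset$genome else refset
  if (grepl("N", tag_seq, fixed = TRUE)) stop("tag contains N")
  if (nchar(tag_seq) < 12) stop("input error: tag shorter than 12 nt")
  rc <- revcomp(tag_seq)
  out <- list()
  for (chrom in names(genome)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") tag_seq else rc
      m <- Biostrings::matchPattern(pat, genome[[chrom]])
      if (length(m)) {
        out[[length(out) + 1L]] <- data.frame(
          tag_seq = tag_seq, chrom = chrom,
          start = Biostrings::start(m), end = Biostrings::end(m),
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
  res <- res[radix_order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Batch exact placement of many tags via a PDict (Aho-Corasick) scan over
# each chromosome and strand; equivalent to place_tag() per tag but one
# genome pass per strand.
place_tag_batch <- function(seqs, genome) {
  empty <- data.frame(tag_seq = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(seqs)) return(empty)
  if (any(grepl("N", seqs, fixed = TRUE))) stop("tag contains N")
  if (any(nchar(seqs) < 12)) stop("input error: tag shorter than 12 nt")
  u <- unique(seqs)
  fwd <- Biostrings::DNAStringSet(u)
  dicts <- list("+" = Biostrings::PDict(fwd, tb.start = 1, tb.end = 12),
                "-" = Biostrings::PDict(Biostrings::reverseComplement(fwd),
                                        tb.start = 1, tb.end = 12))
  out <- list()
  for (chrom in names(genome)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPDict(dicts[[str]], genome[[chrom]])
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0) next
      r <- unlist(m)
      out[[length(out) + 1L]] <- data.frame(
        tag_seq = rep(u, cnt), chrom = chrom,
        start = Biostrings::start(r), end = Biostrings::end(r),
        strand = str, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[radix_order(res$tag_seq, res$chrom, res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Place a batch of tags, keeping their read counts
#'
#' @param tags data.frame with `seq` and `count`.
#' @param refset [reference_set()] or genome `DNAStringSet`.
#' @return placement data.frame with a `count` column.
#' @export
place_tags <- function(tags, refset) {
  genome <- if (inherits(refset, "reference_set")) refset$genome else refset
  res <- place_tag_batch(tags$seq, genome)
  res$count <- tags$count[match(res$tag_seq, tags$seq)]
  res
}

#' Annotate placed tags against the mRNA screen and known-miRNA catalogue
#'
#' A tag is `mRNA` if it is an exact substring of any mRNA sequence (these
#' are excluded from miRNA quantification but still count toward the mapped
#' total when genome-placed); otherwise `known_miRNA` if at least one
#' placement overlaps a mature interval on the matching strand with >= 90%
#' of the tag inside it; otherwise `unannotated` if genome-placed; otherwise
#' `unmapped`. The multi-mapping multiplicity is the number of placements
#' satisfying the mature-overlap rule across all annotated miRNA regions.
#'
#' @param tags data.frame with `seq` and `count` (from [qc_reads()]).
#' @param refset [reference_set()].
#' @param min_overlap_frac fraction of the tag that must lie inside a mature
#'   interval (default 0.9).
#' @return data.frame: `tag_seq`, `count`, `category`, `matched_mirna_ids`
#'   (comma-separated), `multiplicity`, `n_placements`, plus the placement
#'   table as attribute `"placements"`.
#' @export
annotate_tags <- function(tags, refset, min_overlap_frac = 0.9) {
  stopifnot(inherits(refset, "reference_set"))
  n <- nrow(tags)
  ann <- refset$mirnas
  pl <- place_tag_batch(tags$seq, refset$genome)
  tag_idx <- match(pl$tag_seq, tags$seq)
  nplace <- tabulate(tag_idx, nbins = n)

  # mature-overlap rule per placement, against every annotated miRNA region
  placement_hit <- rep(FALSE, nrow(pl))
  pair_tag <- integer(0); pair_id <- character(0)
  if (nrow(pl) > 0 && nrow(ann) > 0) {
    need <- ceiling(min_overlap_frac * nchar(pl$tag_seq))
    for (k in seq_len(nrow(ann))) {
      ok <- pl$chrom == ann$chrom[k] & pl$strand == ann$strand[k] &
        pmin(pl$end, ann$mat_end[k]) - pmax(pl$start, ann$mat_start[k]) +
        1L >= need
      if (any(ok)) {
        placement_hit <- placement_hit | ok
        pair_tag <- c(pair_tag, tag_idx[ok])
        pair_id <- c(pair_id, rep(ann$mirna_id[k], sum(ok)))
      }
    }
  }
  mult <- integer(n)
  if (nrow(pl) > 0) {
    agg <- tapply(placement_hit, factor(tag_idx, levels = seq_len(n)), sum)
    mult <- as.integer(ifelse(is.na(agg), 0L, agg))
  }
  matched <- character(n)
  if (length(pair_tag)) {
    by_tag <- split(pair_id, pair_tag)
    for (nm in names(by_tag)) {
      matched[as.integer(nm)] <-
        paste(sort(unique(by_tag[[nm]])), collapse = ",")
    }
  }

  is_mrna <- rep(FALSE, n)
  if (length(refset$mrna) > 0 && n > 0) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$seq),
                            tb.start = 1, tb.end = 12)
    for (k in seq_along(refset$mrna)) {
      cnt <- Biostrings::countPDict(pd, refset$mrna[[k]])
      is_mrna <- is_mrna | cnt > 0
    }
  }
  cat_ <- ifelse(is_mrna, "mRNA",
                 ifelse(nzchar(matched), "known_miRNA",
                        ifelse(nplace > 0, "unannotated", "unmapped")))
  out <- data.frame(tag_seq = tags$seq, count = tags$count, category = cat_,
                    matched_mirna_ids = matched, multiplicity = mult,
                    n_placements = nplace, stringsAsFactors = FALSE)
  attr(out, "placements") <- pl
  out
}

#' Scan a sequence for E-box motifs (CANNTG)
#'
#' Forward-strand scan for the canonical c-Myc binding motif CANNTG; the
#' motif's fixed positions are reverse-complement symmetric, so a forward
#' scan covers both strands. Overlapping matches are all reported.
#'
#' @param seq DNA sequence over A/C/G/T/N.
#' @return integer vector of 1-based match start positions.
#' @export
scan_ebox <- function(seq) {
  n <- nchar(seq)
  if (n < 6) return(integer(0))
  x <- strsplit(seq, "")[[1]]
  i <- seq_len(n - 5L)
  i[x[i] == "C" & x[i + 1L] == "A" & x[i + 4L] == "T" & x[i + 5L] == "G"]
}

#' Export placements as BED6
#'
#' Converts 1-based closed placements to BED's 0-based half-open intervals;
#' the name column carries the tag sequence and the score its read count.
#'
#' @param placements placement data.frame (with a `count` column or counts
#'   joined from tags).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_placements_bed <- function(placements, path) {
  score <- if ("count" %in% names(placements)) placements$count else 0L
  bed <- data.frame(placements$chrom, placements$start - 1L, placements$end,
                    placements$tag_seq, score, placements$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
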