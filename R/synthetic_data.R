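# Synthetic smRNA-Seq data generation: toy genomes, planted miRNA hairpins,
# adapter-ligated libraries for the three study conditions (empty vector,
# Kaposin B, Kaposin B + c-Myc) and Ago1/2-RIP libraries, with a
# machine-readable ground truth for parameter-recovery testing.

#' Default small-RNA adapter sequences
#'
#' Standard Illumina small-RNA chemistry: the 3' adapter ligated downstream of
#' the insert and the 5' adapter whose presence marks adapter dimers.
#'
#' @return named list with elements `adapter_3p` and `adapter_5p`.
#' @export
default_adapters <- function() {
  list(adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC")
}

#' Library simulation configuration
#'
#' @param n_reads number of reads to emit (exactly).
#' @param adapter_3p 3' adapter sequence (>= 18 nt).
#' @param adapter_5p 5' adapter sequence.
#' @param adapter_tail_range integer pair: range of 3' adapter lengths
#'   appended to each insert (default 6..18 nt).
#' @param seed RNG seed for this library.
#' @return object of class `library_config`.
#' @export
library_config <- function(n_reads,
                           adapter_3p = default_adapters()$adapter_3p,
                           adapter_5p = default_adapters()$adapter_5p,
                           adapter_tail_range = c(6L, 18L),
                           seed = 1L) {
  stopifnot(n_reads >= 1, nchar(adapter_3p) >= 18,
            length(adapter_tail_range) == 2,
            adapter_tail_range[1] >= 1,
            adapter_tail_range[2] <= nchar(adapter_3p),
            adapter_tail_range[1] <= adapter_tail_range[2])
  structure(list(n_reads = as.integer(n_reads), adapter_3p = adapter_3p,
                 adapter_5p = adapter_5p,
                 adapter_tail_range = as.integer(adapter_tail_range),
                 seed = as.integer(seed)),
            class = "library_config")
}

#' Generate a random toy genome
#'
#' @param length genome length in bases (>= 1000).
#' @param gc_fraction target GC content in (0, 1).
#' @param seed RNG seed; fixed seed gives an identical genome.
#' @param chrom_name chromosome name.
#' @return a named [Biostrings::DNAStringSet] with one chromosome.
#' @export
generate_genome <- function(length, gc_fraction = 0.45, seed = 1L,
                            chrom_name = "chrSim") {
  if (length < 1000) stop("genome length must be >= 1000")
  stopifnot(gc_fraction > 0, gc_fraction < 1)
  seq <- with_seed(seed, random_dna(length, gc_fraction))
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom_name
  g
}

empty_mirna_table <- function() {
  data.frame(mirna_id = character(), chrom = character(), strand = character(),
             pre_start = integer(), pre_end = integer(),
             mat_start = integer(), mat_end = integer(),
             mature_seq = character(), is_known = logical(),
             stringsAsFactors = FALSE)
}

#' Plant a miRNA hairpin into a genome
#'
#' Writes a synthetic precursor (mature arm + low-complexity loop +
#' near-reverse-complement star arm) into the genome at `position` and returns
#' the edited genome together with the annotation record. The construction is
#' checked at generation time: the precursor must fold into a hairpin accepted
#' by [classify_hairpin()] under the default preset, and the star arm carries
#' at least one mismatch so that the mature sequence occurs exactly once as an
#' exact match.
#'
#' @param genome a one-or-more chromosome `DNAStringSet`.
#' @param position 1-based genomic start of the precursor.
#' @param chrom chromosome to edit (default: first).
#' @param mature_len mature miRNA length, 18-24 nt.
#' @param strand "+" or "-": orientation of the transcribed hairpin.
#' @param is_known flag: planted as a known (annotated) miRNA or a novel one.
#' @param mirna_id identifier for the planted miRNA.
#' @param loop_len terminal loop length (>= 8 nt).
#' @param star_mismatches substitutions in the star arm (1-3).
#' @param seed RNG seed.
#' @param existing previously planted records (for the overlap check).
#' @return list with elements `genome` (edited) and `mirna` (one-row
#'   data.frame: id, chrom, strand, precursor and mature intervals, mature
#'   sequence, is_known flag).
#' @export
plant_hairpin <- function(genome, position, chrom = names(genome)[1],
                          mature_len = 22L, strand = "+", is_known = TRUE,
                          mirna_id = "mir-1", loop_len = 10L,
                          star_mismatches = 2L, seed = 1L,
                          existing = NULL) {
  stopifnot(mature_len >= 18, mature_len <= 24, loop_len >= 8,
            star_mismatches >= 1, star_mismatches <= 3,
            strand %in% c("+", "-"))
  glen <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (is.na(glen)) stop("unknown chromosome: ", chrom)
  pre_len <- mature_len + loop_len + mature_len
  if (position + 120 > glen) stop("precursor does not fit at this position")
  pre_start <- as.integer(position)
  pre_end <- pre_start + pre_len - 1L
  if (!is.null(existing) && nrow(existing) > 0) {
    clash <- existing$chrom == chrom &
      existing$pre_start <= pre_end & existing$pre_end >= pre_start
    if (any(clash))
      stop("placement error: locus overlaps an existing planted locus")
  }

  build <- function(attempt) {
    with_seed(derive_seed(seed, attempt), {
      mature <- random_dna(mature_len, gc = 0.5)
      star <- strsplit(revcomp(mature), "")[[1]]
      pos <- sample(seq(2L, mature_len - 1L), star_mismatches)
      for (p in pos) {
        star[p] <- sample(setdiff(c("A", "C", "G", "T"), star[p]), 1)
      }
      loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                    collapse = "")
      list(mature = mature,
           precursor = paste0(mature, loop, paste(star, collapse = "")))
    })
  }

  preset <- hairpin_presets()$default
  rec <- NULL
  for (attempt in seq_len(30L)) {
    cand <- build(attempt)
    fr <- fold_nussinov(cand$precursor)
    cl <- classify_hairpin(fr, c(1L, mature_len), preset)
    if (cl$pass) { rec <- cand; break }
  }
  if (is.null(rec))
    stop("failed to construct a hairpin passing the default preset")

  genomic <- if (strand == "+") rec$precursor else revcomp(rec$precursor)
  Biostrings::subseq(genome[[chrom]], pre_start, pre_end) <-
    Biostrings::DNAString(genomic)
  if (strand == "+") {
    mat_start <- pre_start; mat_end <- pre_start + mature_len - 1L
  } else {
    mat_end <- pre_end; mat_start <- pre_end - mature_len + 1L
  }
  mirna <- data.frame(mirna_id = mirna_id, chrom = chrom, strand = strand,
                      pre_start = pre_start, pre_end = pre_end,
                      mat_start = as.integer(mat_start),
                      mat_end = as.integer(mat_end),
                      mature_seq = rec$mature, is_known = is_known,
                      stringsAsFactors = FALSE)
  list(genome = genome, mirna = mirna)
}

#' Build a complete simulated miRNome study
#'
#' Generates a toy genome, plants non-overlapping known and novel miRNA
#' hairpins (mixed strands), carves disjoint "transcribed" windows used as the
#' mRNA reference (the source of mRNA-fragment contaminants), and verifies
#' that every planted mature sequence occurs exactly once in the final genome
#' on either strand.
#'
#' @param genome_length toy genome size (default 1e5).
#' @param n_known,n_novel number of known / novel hairpins planted.
#' @param n_mrna,mrna_len number and width of mRNA reference windows.
#' @param gc_fraction genome GC content.
#' @param seed RNG seed controlling the whole construction.
#' @return list with `genome` (`DNAStringSet`), `mirnas` (annotation
#'   data.frame), `mrna` (`DNAStringSet` of reference transcripts) and
#'   `mrna_regions` (their genomic windows).
#' @export
build_simulation <- function(genome_length = 1e5, n_known = 12L,
                             n_novel = 10L, n_mrna = 4L, mrna_len = 600L,
                             gc_fraction = 0.45, seed = 1L) {
  genome <- generate_genome(genome_length, gc_fraction, seed = seed)
  chrom <- names(genome)[1]
  n_loci <- n_known + n_novel
  n_slots <- n_loci + n_mrna
  slot <- floor((genome_length - 200) / n_slots)
  if (slot < max(300, mrna_len + 50))
    stop("genome too small for the requested loci")
  slot_start <- 100L + slot * (seq_len(n_slots) - 1L)
  ids <- c(sprintf("mir-k%02d", seq_len(n_known)),
           sprintf("mir-n%02d", seq_len(n_novel)))
  known <- c(rep(TRUE, n_known), rep(FALSE, n_novel))
  strands <- with_seed(derive_seed(seed, 1L),
                       sample(c("+", "-"), n_loci, replace = TRUE))

  mirnas <- empty_mirna_table()
  for (i in seq_len(n_loci)) {
    planted <- FALSE
    for (attempt in seq_len(20L)) {
      res <- plant_hairpin(genome, position = slot_start[i] + 20L * attempt,
                           chrom = chrom, strand = strands[i],
                           is_known = known[i], mirna_id = ids[i],
                           seed = derive_seed(seed, 100L * i + attempt),
                           existing = mirnas)
      # require the mature tag to be unique genome-wide (both strands)
      n_occ <- Biostrings::countPattern(res$mirna$mature_seq,
                                        res$genome[[chrom]]) +
        Biostrings::countPattern(revcomp(res$mirna$mature_seq),
                                 res$genome[[chrom]])
      if (n_occ == 1L) {
        genome <- res$genome
        mirnas <- rbind(mirnas, res$mirna)
        planted <- TRUE
        break
      }
    }
    if (!planted) stop("could not plant a unique hairpin for ", ids[i])
  }

  mrna_start <- slot_start[n_loci + seq_len(n_mrna)]
  mrna_regions <- data.frame(mrna_id = sprintf("mrna%02d", seq_len(n_mrna)),
                             chrom = chrom, start = mrna_start,
                             end = mrna_start + mrna_len - 1L,
                             stringsAsFactors = FALSE)
  mrna <- Biostrings::DNAStringSet(vapply(seq_len(n_mrna), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], mrna_regions$start[i],
                                    mrna_regions$end[i]))
  }, character(1)))
  names(mrna) <- mrna_regions$mrna_id
  list(genome = genome, mirnas = mirnas, mrna = mrna,
       mrna_regions = mrna_regions)
}

#' Ground-truth abundance table for the three study conditions
#'
#' Per-condition multinomial weights over planted miRNAs; the true fold change
#' between two conditions is the ratio of their (normalised) weights. The
#' default design assigns Kaposin-B-vs-vector folds from \{0.5, 1, 2, 4\} and
#' c-Myc-vs-Kaposin-B folds from \{0.5, 1, 2\}, with baseline weights solved
#' so that weights in every condition sum to one and the planted folds are
#' realised exactly.
#'
#' @param mirnas planted annotation table from [build_simulation()].
#' @param contaminants named fractions for `polyA`, `ambiguous`, `adapter5`
#'   and `mrna` contaminant reads (must sum to < 1).
#' @param known_mass total baseline weight given to known miRNAs (the rest
#'   goes to novel ones; ignored when only one group is present).
#' @return object of class `mirnome_truth`: list with `weights` (per-condition
#'   multinomial weights), `folds` (true per-miRNA fold changes),
#'   `contaminants` and `conditions`.
#' @export
default_truth <- function(mirnas,
                          contaminants = c(polyA = 0.03, ambiguous = 0.02,
                                           adapter5 = 0.02, mrna = 0.05),
                          known_mass = 0.8) {
  stopifnot(nrow(mirnas) >= 1, sum(contaminants) < 1, all(contaminants >= 0))
  groups <- split(mirnas$mirna_id, mirnas$is_known)
  masses <- if (length(groups) == 2) {
    stats::setNames(c(1 - known_mass, known_mass), names(groups))
  } else stats::setNames(1, names(groups))

  f1_levels <- c(0.5, 1, 2, 4)
  f1_mass <- c(0.5, 0.35, 0.1, 0.05) # solves sum(w) = sum(w * f1) = 1

  rows <- list()
  for (g in names(groups)) {
    ids <- sort(groups[[g]])
    n <- length(ids)
    if (n < 4) stop("default_truth needs >= 4 miRNAs per group")
    cuts <- floor(seq(0, n, length.out = 5L))
    sizes <- diff(cuts)
    idx <- 0L
    for (k in seq_along(f1_levels)) {
      m <- sizes[k]
      class_ids <- ids[idx + seq_len(m)]
      idx <- idx + m
      W <- masses[g] * f1_mass[k]
      if (m == 1L) {
        f2 <- 1; w <- W
      } else if (m == 2L) {
        f2 <- c(0.5, 2); w <- W * c(2 / 3, 1 / 3)
      } else {
        # f2 in {0.5, 1, ..., 1, 2}; weights (W/2, W/4 split, W/4) keep the
        # class's weighted mean fold at exactly 1
        f2 <- c(0.5, rep(1, m - 2L), 2)
        w <- c(W / 2, rep(W / 4 / (m - 2L), m - 2L), W / 4)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(mirna_id = class_ids, vec = w, f1 = f1_levels[k], f2 = f2,
                   stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  d <- d[radix_order(d$mirna_id), ]
  weights <- data.frame(mirna_id = d$mirna_id, vec = d$vec,
                        kapb = d$vec * d$f1, kapb_myc = d$vec * d$f1 * d$f2,
                        stringsAsFactors = FALSE)
  truth_table(weights, contaminants)
}

#' Construct a truth table from explicit per-condition weights
#'
#' @param weights data.frame with `mirna_id` plus one numeric column per
#'   condition; each condition column must sum to 1.
#' @param contaminants named contaminant fractions (sum < 1).
#' @return `mirnome_truth` object; `folds` holds the realised fold change of
#'   every non-baseline condition versus the first condition column and
#'   between consecutive condition columns.
#' @export
truth_table <- function(weights,
                        contaminants = c(polyA = 0, ambiguous = 0,
                                         adapter5 = 0, mrna = 0)) {
  conds <- setdiff(names(weights), "mirna_id")
  stopifnot(length(conds) >= 1, !anyDuplicated(weights$mirna_id),
            all(contaminants >= 0), sum(contaminants) < 1)
  for (cn in conds) {
    s <- sum(weights[[cn]])
    if (abs(s - 1) > 1e-8)
      stop("weights for condition '", cn, "' sum to ", s, ", not 1")
  }
  folds <- data.frame(mirna_id = weights$mirna_id, stringsAsFactors = FALSE)
  for (cn in conds[-1]) {
    folds[[paste0(cn, "_vs_", conds[1])]] <-
      weights[[cn]] / weights[[conds[1]]]
  }
  if (length(conds) >= 3) {
    for (i in 3:length(conds)) {
      folds[[paste0(conds[i], "_vs_", conds[i - 1])]] <-
        weights[[conds[i]]] / weights[[conds[i - 1]]]
    }
  }
  structure(list(weights = weights, folds = folds,
                 contaminants = contaminants, conditions = conds),
            class = "mirnome_truth")
}

#' Simulate one adapter-ligated small-RNA library
#'
#' Each miRNA read is the mature sequence followed by a 3' adapter prefix of
#' length drawn uniformly from the configured tail range. Contaminant reads
#' (poly-A-tailed inserts, N-containing inserts, 5'-adapter dimers and random
#' mRNA fragments) are emitted at the configured fractions. Quality strings
#' are constant ("I"); no sequencing errors are introduced. Output is
#' deterministic for a fixed seed and contains exactly `cfg$n_reads` reads.
#'
#' @param planted annotation table of planted miRNAs.
#' @param truth `mirnome_truth` object.
#' @param cfg [library_config()].
#' @param condition condition name (must be a truth condition).
#' @param mrna `DNAStringSet` of mRNA reference sequences (required when the
#'   mRNA contaminant fraction is positive).
#' @return data.frame of reads: `id`, `seq`, `qual`.
#' @export
simulate_library <- function(planted, truth, cfg, condition, mrna = NULL) {
  stopifnot(inherits(truth, "mirnome_truth"), inherits(cfg, "library_config"))
  if (!condition %in% truth$conditions)
    stop("condition '", condition, "' not present in the truth table")
  ct <- truth$contaminants
  for (nm in c("polyA", "ambiguous", "adapter5", "mrna"))
    if (is.na(ct[nm])) ct[nm] <- 0
  p_mirna <- 1 - sum(ct)
  if (p_mirna > 0 && nrow(planted) == 0)
    stop("config error: no planted miRNAs but nonzero miRNA fraction")
  if (ct["mrna"] > 0 && (is.null(mrna) || length(mrna) == 0))
    stop("config error: mRNA contaminant fraction set but no mRNA sequences")
  w <- truth$weights[[condition]][match(planted$mirna_id,
                                        truth$weights$mirna_id)]
  if (p_mirna > 0 && anyNA(w))
    stop("planted miRNAs missing from the truth table")
  n <- cfg$n_reads
  a3 <- cfg$adapter_3p
  a5 <- cfg$adapter_5p
  tr <- cfg$adapter_tail_range

  with_seed(cfg$seed, {
    classes <- sample(c("mirna", "polyA", "ambiguous", "adapter5", "mrna"),
                      n, replace = TRUE,
                      prob = c(p_mirna, ct["polyA"], ct["ambiguous"],
                               ct["adapter5"], ct["mrna"]))
    tails <- substr(rep(a3, n), 1, sample(seq(tr[1], tr[2]), n,
                                          replace = TRUE))
    seqs <- character(n)

    i <- which(classes == "mirna")
    if (length(i)) {
      mi <- sample.int(nrow(planted), length(i), replace = TRUE, prob = w)
      seqs[i] <- paste0(planted$mature_seq[mi], tails[i])
    }
    i <- which(classes == "polyA")
    if (length(i)) {
      pre <- vapply(seq_along(i), function(j) random_dna(10), character(1))
      seqs[i] <- paste0(pre, strrep("A", 10), tails[i])
    }
    i <- which(classes == "ambiguous")
    if (length(i)) {
      ins <- vapply(seq_along(i), function(j) {
        x <- strsplit(random_dna(22), "")[[1]]
        x[sample.int(22, 2)] <- "N"
        paste(x, collapse = "")
      }, character(1))
      seqs[i] <- paste0(ins, tails[i])
    }
    i <- which(classes == "adapter5")
    if (length(i)) {
      dimer <- substr(a5, nchar(a5) - 11L, nchar(a5))
      pre <- vapply(seq_along(i), function(j) random_dna(8), character(1))
      seqs[i] <- paste0(dimer, pre, tails[i])
    }
    i <- which(classes == "mrna")
    if (length(i)) {
      src <- sample.int(length(mrna), length(i), replace = TRUE)
      len <- sample(18:24, length(i), replace = TRUE)
      width <- Biostrings::width(mrna)[src]
      start <- floor(stats::runif(length(i), 1, width - len + 1))
      frag <- substr(as.character(mrna)[src], start, start + len - 1)
      seqs[i] <- paste0(frag, tails[i])
    }
    data.frame(id = sprintf("%s_%06d_%s", condition, seq_len(n), classes),
               seq = seqs, qual = strrep("I", nchar(seqs)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate Ago1/2 RIP-seq libraries
#'
#' Emulates public Argonaute RNA-immunoprecipitation sequencing datasets:
#' every supported candidate receives at least `depth_per_candidate` reads
#' overlapping its mature interval in every dataset; unsupported candidates
#' receive none.
#'
#' @param planted annotation table of planted miRNAs.
#' @param supported_ids subset of `planted$mirna_id` with Ago support.
#' @param depth_per_candidate reads per supported candidate per dataset.
#' @param n_datasets number of independent RIP libraries (>= 1).
#' @param cfg [library_config()] supplying adapter and tail settings (its
#'   `n_reads` is ignored).
#' @param seed RNG seed.
#' @return list of read data.frames, one per dataset.
#' @export
simulate_agoip <- function(planted, supported_ids, depth_per_candidate = 10L,
                           n_datasets = 2L, cfg = library_config(1L),
                           seed = 1L) {
  if (n_datasets < 1) stop("config error: n_datasets must be >= 1")
  if (!all(supported_ids %in% planted$mirna_id))
    stop("supported_ids must be a subset of planted miRNA ids")
  sup <- planted[planted$mirna_id %in% supported_ids, , drop = FALSE]
  sup <- sup[radix_order(sup$mirna_id), , drop = FALSE]
  a3 <- cfg$adapter_3p
  tr <- cfg$adapter_tail_range
  lapply(seq_len(n_datasets), function(d) {
    with_seed(derive_seed(seed, d), {
      n <- nrow(sup) * depth_per_candidate
      if (n == 0) {
        return(data.frame(id = character(), seq = character(),
                          qual = character(), stringsAsFactors = FALSE))
      }
      mat <- rep(sup$mature_seq, each = depth_per_candidate)
      tails <- substr(rep(a3, n), 1,
                      sample(seq(tr[1], tr[2]), n, replace = TRUE))
      seqs <- paste0(mat, tails)
      data.frame(id = sprintf("ago%02d_%06d", d, seq_len(n)), seq = seqs,
                 qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
    })
  })
}

#' Read and write FASTQ files
#'
#' Four-line FASTQ with Sanger qualities, via Biostrings.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path file path.
#' @return `write_fastq` returns the path invisibly; `read_fastq` a read
#'   data.frame.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' miRNA annotation GFF3 I/O
#'
#' Writes planted/known miRNA annotations in miRBase-style GFF3: one
#' `miRNA_primary_transcript` feature per precursor and a `miRNA` child
#' feature (Derives_from) per mature arm, 1-based closed coordinates.
#'
#' @param mirnas annotation data.frame (see [build_simulation()]).
#' @param path GFF3 file path.
#' @return `export_mirna_gff` the path, invisibly; `import_mirna_gff` an
#'   annotation data.frame (without mature sequences, which are recovered
#'   from the genome by the reference set constructor).
#' @export
export_mirna_gff <- function(mirnas, path) {
  pre <- GenomicRanges::GRanges(
    mirnas$chrom,
    IRanges::IRanges(mirnas$pre_start, mirnas$pre_end),
    strand = mirnas$strand,
    type = "miRNA_primary_transcript",
    ID = mirnas$mirna_id, Name = mirnas$mirna_id)
  mat <- GenomicRanges::GRanges(
    mirnas$chrom,
    IRanges::IRanges(mirnas$mat_start, mirnas$mat_end),
    strand = mirnas$strand,
    type = "miRNA",
    ID = paste0(mirnas$mirna_id, "_mature"),
    Name = paste0(mirnas$mirna_id, "_mature"),
    Derives_from = mirnas$mirna_id)
  rtracklayer::export(c(pre, mat), path, format = "gff3")
  invisible(path)
}

#' @rdname export_mirna_gff
#' @export
import_mirna_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  pre <- gr[gr$type == "miRNA_primary_transcript"]
  mat <- gr[gr$type == "miRNA"]
  m <- match(unlist(mat$Derives_from), pre$ID)
  data.frame(mirna_id = pre$ID[m],
             chrom = as.character(GenomicRanges::seqnames(pre))[m],
             strand = as.character(GenomicRanges::strand(pre))[m],
             pre_start = GenomicRanges::start(pre)[m],
             pre_end = GenomicRanges::end(pre)[m],
             mat_start = GenomicRanges::start(mat),
             mat_end = GenomicRanges::end(mat),
             stringsAsFactors = FALSE)
}

#' Write a truth table as TSV
#'
#' @param truth `mirnome_truth` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- merge(truth$weights, truth$folds, by = "mirna_id", sort = FALSE)
  df <- df[radix_order(df$mirna_id), ]
  write_tsv(df, path)
}
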