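test_that("Nussinov folding matches exhaustive enumeration on short RNAs", {
  fr <- fold_nussinov("GGGAAACCC")
  expect_identical(fr$n_pairs, 3L)
  expect_identical(fold_nussinov("AAAAAAAA")$n_pairs, 0L)
  expect_error(fold_nussinov("A"), "input error")
  expect_error(fold_nussinov(strrep("ACGT", 200)), "input error")

  set.seed(23)
  for (rep in 1:60) {
    n <- sample(5:12, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    expect_identical(fold_nussinov(s)$n_pairs, as.integer(enum_max_pairs(s)),
                     info = s)
  }
})

test_that("dot-bracket output round-trips to the pair list", {
  set.seed(29)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1),
                      replace = TRUE), collapse = "")
    fr <- fold_nussinov(s)
    expect_identical(nchar(fr$structure), nchar(s))
    back <- parse_dotbracket(fr$structure)
    expect_identical(unname(back), unname(fr$pairs))
    # non-crossing and min-loop invariants
    if (fr$n_pairs > 1) {
      for (r in seq_len(fr$n_pairs)) {
        expect_true(all(fr$pairs[, 2] - fr$pairs[, 1] > 3))
        crossing <- fr$pairs[, 1] < fr$pairs[r, 1] &
          fr$pairs[r, 1] < fr$pairs[, 2] & fr$pairs[, 2] < fr$pairs[r, 2]
        expect_false(any(crossing))
      }
    }
  }
})

test_that("read stacks follow single-linkage clustering within max_gap", {
  two <- data.frame(tag_seq = c("A1", "A2"), chrom = "c", strand = "+",
                    start = c(100L, 125L), end = c(121L, 146L),
                    count = c(5L, 5L), stringsAsFactors = FALSE)
  expect_length(build_stacks(two, max_gap = 10), 1) # 3-nt gap joins
  apart <- two; apart$start[2] <- 321L; apart$end[2] <- 342L
  expect_length(build_stacks(apart, max_gap = 10), 2) # 200 nt splits
  expect_length(build_stacks(apart, max_gap = 10, min_reads = 6), 0)
  expect_length(build_stacks(apart[0, ]), 0)

  # oracle: brute-force transitive closure on random placements
  set.seed(37)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    pl <- data.frame(
      tag_seq = sprintf("t%03d", 1:n),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = sample(1:2000, n), count = 5L, stringsAsFactors = FALSE)
    pl$end <- pl$start + 21L
    stacks <- build_stacks(pl, max_gap = 10, min_reads = 1)
    grp <- cluster_oracle(pl, max_gap = 10)
    expect_identical(length(stacks), length(unique(grp)))
    member <- lapply(stacks, function(s) sort(s$tags$tag_seq))
    oracle_member <- lapply(split(pl$tag_seq, grp), sort)
    expect_setequal(vapply(member, paste, "", collapse = ","),
                    vapply(oracle_member, paste, "", collapse = ","))
  }
})

test_that("hairpin classification accepts planted stems and rejects decoys", {
  sim <- small_sim()
  m <- sim$mirnas[1, ]
  pre <- as.character(Biostrings::subseq(sim$genome[[1]], m$pre_start,
                                         m$pre_end))
  if (m$strand == "-") pre <- revcomp(pre)
  fr <- fold_nussinov(pre)
  mat <- c(1, nchar(m$mature_seq))
  for (p in hairpin_presets()) {
    expect_true(classify_hairpin(fr, mat, p)$pass, info = p$name)
  }
  # a mature straddling the terminal loop fails criterion (b)
  mid <- c(25, 46) # covers the loop region of the 54-nt precursor
  cl <- classify_hairpin(fr, mid, hairpin_presets()$default)
  expect_false(cl$pass)
  expect_true("mature_overlaps_terminal_loop" %in% cl$reasons)
  expect_error(classify_hairpin(fr, c(0, 10)), "within")

  # dinucleotide-shuffled precursors almost never classify as hairpins
  set.seed(41)
  passes <- vapply(1:100, function(i) {
    classify_hairpin(fold_nussinov(dinucleotide_shuffle(pre)), mat,
                     hairpin_presets()$default)$pass
  }, logical(1))
  expect_lte(mean(passes), 0.05)
})

test_that("consensus detection recovers planted loci and is quorum-monotone", {
  sim <- small_sim()
  refset <- small_refset()
  truth <- default_truth(sim$mirnas)
  lib <- simulate_library(sim$mirnas, truth, library_config(20000, seed = 3),
                          "kapb_myc", mrna = sim$mrna)
  q <- qc_reads(lib)
  ann <- annotate_tags(q$tags, refset)
  un <- ann[ann$category == "unannotated", ]
  pl <- attr(ann, "placements")
  pl <- pl[pl$tag_seq %in% un$tag_seq, ]
  pl$count <- un$count[match(pl$tag_seq, un$tag_seq)]
  stacks <- build_stacks(pl)
  cands <- list()
  for (qm in 3:1) {
    cands[[qm]] <- consensus_detect(stacks, sim$genome, quorum = qm)
  }
  novel <- sim$mirnas[!sim$mirnas$is_known, ]
  hit <- novel$mature_seq %in% cands[[3]]$mature_seq[cands[[3]]$consensus]
  expect_gte(sum(hit), nrow(novel) - 1)
  # lowering the quorum never removes a consensus candidate
  for (qm in 2:1) {
    expect_true(all(
      cands[[qm + 1]]$candidate_id[cands[[qm + 1]]$consensus] %in%
        cands[[qm]]$candidate_id[cands[[qm]]$consensus]))
  }
  expect_error(consensus_detect(stacks, sim$genome, quorum = 4),
               "config error")
})

test_that("Ago verification recovers exactly the supported candidates", {
  sim <- small_sim()
  refset <- small_refset()
  novel <- sim$mirnas[!sim$mirnas$is_known, ]
  sup <- novel$mirna_id[c(1, 3)]
  ago <- simulate_agoip(sim$mirnas, sup, depth_per_candidate = 10,
                        n_datasets = 2, seed = 5)
  ago_pl <- lapply(ago, function(lib) place_tags(qc_reads(lib)$tags, refset))
  cands <- data.frame(
    candidate_id = novel$mirna_id, chrom = novel$chrom,
    strand = novel$strand, mat_start = novel$mat_start,
    mat_end = novel$mat_end, stringsAsFactors = FALSE)
  out <- verify_agoip(cands, ago_pl, min_reads = 5, min_datasets = 1)
  expect_identical(out$candidate_id[out$ago_verified], sup)
  expect_true(all(out$ago_datasets_supporting[out$ago_verified] == 2))
  expect_true(all(out$ago_datasets_supporting[!out$ago_verified] == 0))
  expect_warning(out2 <- verify_agoip(cands, list()), "unverified")
  expect_false(any(out2$ago_verified))
})
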