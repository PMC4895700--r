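test_that("exact placement agrees with a naive substring-scan oracle", {
  sim <- small_sim()
  refset <- small_refset()
  set.seed(31)
  # planted matures, their reverse complements, and random probes
  probes <- c(sim$mirnas$mature_seq[1:4],
              revcomp(sim$mirnas$mature_seq[5]),
              replicate(15, paste(sample(c("A", "C", "G", "T"), 14,
                                         replace = TRUE), collapse = "")))
  for (tag in probes) {
    got <- place_tag(tag, refset)
    want <- scan_placements(tag, sim$genome)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    # round-trip invariant: the genomic window reproduces the tag
    for (r in seq_len(nrow(got))) {
      win <- as.character(Biostrings::subseq(
        sim$genome[[got$chrom[r]]], got$start[r], got$end[r]))
      expect_identical(if (got$strand[r] == "-") revcomp(win) else win, tag)
    }
  }
  expect_identical(nrow(place_tag(strrep("ACGT", 5), refset)), 0L)
  expect_error(place_tag("ACGTACGTA422", refset))
  expect_error(place_tag("ACGTACG", refset), "12")
  expect_error(place_tag("ACGTNACGTACGTN", refset), "N")
})

test_that("a reverse-complement window is placed on the minus strand", {
  sim <- small_sim()
  win <- as.character(Biostrings::subseq(sim$genome[[1]], 1501, 1518))
  got <- place_tag(revcomp(win), sim$genome)
  minus <- got[got$strand == "-", ]
  expect_true(any(minus$start == 1501 & minus$end == 1518))
})

test_that("tags are annotated by mRNA screen, mature overlap and unmapped", {
  sim <- small_sim()
  refset <- small_refset()
  known <- sim$mirnas[sim$mirnas$is_known, ]
  novel <- sim$mirnas[!sim$mirnas$is_known, ]
  mrna_frag <- substr(as.character(sim$mrna[[1]]), 101, 122)
  tags <- data.frame(
    seq = c(known$mature_seq[1], novel$mature_seq[1], mrna_frag,
            strrep("ACGT", 6)),
    count = c(10L, 5L, 3L, 2L), stringsAsFactors = FALSE)
  ann <- annotate_tags(tags, refset)
  expect_identical(ann$category,
                   c("known_miRNA", "unannotated", "mRNA", "unmapped"))
  expect_identical(ann$matched_mirna_ids[1], known$mirna_id[1])
  expect_identical(ann$multiplicity[1], 1L)
  expect_identical(ann$n_placements[4], 0L)
  # mRNA fragments come from genomic windows, so they still map
  expect_gte(ann$n_placements[3], 1L)
})

test_that("a tag planted at two miRNA loci gets multiplicity two", {
  sim <- small_sim()
  genome <- sim$genome
  known <- sim$mirnas[sim$mirnas$is_known, ]
  m1 <- known[known$strand == "+", ][1, ]
  # copy the whole precursor to a free locus and annotate it as a second miRNA
  pre <- Biostrings::subseq(genome[[1]], m1$pre_start, m1$pre_end)
  at <- 19500L
  Biostrings::subseq(genome[[1]], at, at + length(pre) - 1L) <- pre
  shift <- at - m1$pre_start
  m2 <- m1
  m2$mirna_id <- "mir-dup"
  m2[c("pre_start", "pre_end", "mat_start", "mat_end")] <-
    m1[c("pre_start", "pre_end", "mat_start", "mat_end")] + shift
  refset <- reference_set(genome, sim$mrna, rbind(known, m2))
  ann <- annotate_tags(data.frame(seq = m1$mature_seq, count = 1L), refset)
  expect_identical(ann$category, "known_miRNA")
  expect_identical(ann$multiplicity, 2L)
  expect_identical(ann$matched_mirna_ids,
                   paste(sort(c(m1$mirna_id, "mir-dup")), collapse = ","))
})

test_that("E-box scanning reports all overlapping CANNTG matches", {
  expect_identical(scan_ebox("GGCACGTGGG"), 3L)
  expect_identical(scan_ebox("ACGTAC"), integer(0))
  expect_identical(scan_ebox("CAGCTGCATTTG"), c(1L, 7L))
  # exhaustive window-check oracle on random sequences
  set.seed(17)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    want <- integer(0)
    for (i in 1:55) {
      w <- substr(s, i, i + 5)
      if (substr(w, 1, 2) == "CA" && substr(w, 5, 6) == "TG")
        want <- c(want, i)
    }
    expect_identical(scan_ebox(s), want)
  }
})
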