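test_that("genome generation is seed-deterministic with controlled GC", {
  g1 <- generate_genome(10000, 0.5, seed = 7)
  g2 <- generate_genome(10000, 0.5, seed = 7)
  g3 <- generate_genome(10000, 0.5, seed = 8)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(as.character(g1[[1]]) == as.character(g3[[1]]))

  g <- generate_genome(100000, 0.4, seed = 1)
  comp <- Biostrings::letterFrequency(g[[1]], c("G", "C"))
  expect_gte(sum(comp) / 100000, 0.37)
  expect_lte(sum(comp) / 100000, 0.43)

  expect_error(generate_genome(500), "1000")
})

test_that("planted hairpins fold, are unique, and refuse to overlap", {
  g <- generate_genome(5000, seed = 3)
  res <- plant_hairpin(g, 1000, mirna_id = "m1", seed = 5)
  m <- res$mirna
  expect_true(m$mat_start >= m$pre_start && m$mat_end <= m$pre_end)
  expect_true(m$pre_end - m$pre_start + 1 >= 50)
  expect_true(nchar(m$mature_seq) >= 18 && nchar(m$mature_seq) <= 24)

  pre <- as.character(Biostrings::subseq(res$genome[[1]], m$pre_start,
                                         m$pre_end))
  fr <- fold_nussinov(pre)
  cl <- classify_hairpin(fr, c(1, nchar(m$mature_seq)),
                         hairpin_presets()$default)
  expect_true(cl$pass)

  # mature occurs exactly once genome-wide (exhaustive scan, both strands)
  occ <- scan_placements(m$mature_seq, res$genome)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$start, m$mat_start)

  expect_error(plant_hairpin(res$genome, 1010, mirna_id = "m2", seed = 6,
                             existing = m),
               "placement error")
})

test_that("the default truth design realises its planted fold changes", {
  sim <- small_sim()
  truth <- default_truth(sim$mirnas)
  w <- truth$weights
  for (cn in truth$conditions) expect_equal(sum(w[[cn]]), 1)
  expect_true(all(truth$folds$kapb_vs_vec %in% c(0.5, 1, 2, 4)))
  expect_true(all(truth$folds$kapb_myc_vs_kapb %in% c(0.5, 1, 2)))
  expect_lt(sum(truth$contaminants), 1)
  expect_error(truth_table(data.frame(mirna_id = "a", vec = 0.9)), "sum")
})

test_that("simulated libraries are exact-size, seeded and class-balanced", {
  sim <- small_sim()
  truth <- default_truth(sim$mirnas)
  cfg <- library_config(4000, seed = 11)
  lib1 <- simulate_library(sim$mirnas, truth, cfg, "kapb", mrna = sim$mrna)
  lib2 <- simulate_library(sim$mirnas, truth, cfg, "kapb", mrna = sim$mrna)
  expect_identical(nrow(lib1), 4000L)
  expect_identical(lib1, lib2)

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(lib1, f1); write_fastq(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_identical(back$seq, lib1$seq)

  # read classes recorded in the ids sum to n_reads
  cls <- sub("^.*_", "", lib1$id)
  expect_identical(sum(table(cls)), 4000L)

  expect_error(simulate_library(sim$mirnas, truth, cfg, "nope"),
               "not present")

  # with all contaminant fractions at zero every read passes QC
  clean <- truth_table(truth$weights)
  lib <- simulate_library(sim$mirnas, clean, library_config(500, seed = 2),
                          "vec")
  dec <- classify_read(lib$seq, cfg$adapter_3p, cfg$adapter_5p)
  expect_true(all(dec == "keep"))
})

test_that("Ago-RIP simulation covers supported candidates only", {
  sim <- small_sim()
  nov <- sim$mirnas$mirna_id[!sim$mirnas$is_known]
  sup <- nov[1:2]
  libs <- simulate_agoip(sim$mirnas, sup, depth_per_candidate = 6,
                         n_datasets = 3, seed = 9)
  expect_length(libs, 3)
  for (lib in libs) {
    mature <- sim$mirnas$mature_seq[match(sup, sim$mirnas$mirna_id)]
    for (ms in mature) {
      expect_gte(sum(startsWith(lib$seq, ms)), 6)
    }
    unsup <- sim$mirnas$mature_seq[!sim$mirnas$mirna_id %in% sup]
    expect_false(any(startsWith(lib$seq, unsup[1])))
  }
  expect_error(simulate_agoip(sim$mirnas, sup, n_datasets = 0),
               "config error")
  expect_error(simulate_agoip(sim$mirnas, "absent-id"), "subset")
})

test_that("annotations survive a GFF3 round trip", {
  sim <- small_sim()
  path <- tempfile(fileext = ".gff3")
  export_mirna_gff(sim$mirnas, path)
  back <- import_mirna_gff(path)
  back <- back[match(sim$mirnas$mirna_id, back$mirna_id), ]
  for (col in c("chrom", "strand", "pre_start", "pre_end", "mat_start",
                "mat_end")) {
    expect_equal(back[[col]], sim$mirnas[[col]], ignore_attr = TRUE)
  }
})
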