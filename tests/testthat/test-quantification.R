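test_that("the RPM formula is applied exactly", {
  expect_identical(rpm(100, 1, 1e6), 1e5)
  expect_identical(rpm(0, 1, 1e6), 0)
  expect_identical(rpm(100, 2, 1e6), 5e4)
  expect_error(rpm(10, 0, 1e6), "domain")
  expect_error(rpm(10, 1, 0), "domain")
  expect_error(rpm(-1, 1, 10), "domain")
  expect_error(rpm(20, 1, 10), "domain")
})

test_that("quantification aggregates counts, multiplicities and totals", {
  ann <- data.frame(
    tag_seq = c("T1", "T2", "T3", "T4"),
    count = c(10L, 6L, 4L, 80L),
    category = c("known_miRNA", "known_miRNA", "mRNA", "unannotated"),
    matched_mirna_ids = c("mirA", "mirB,mirC", "", ""),
    multiplicity = c(1L, 2L, 0L, 0L),
    n_placements = c(1L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  prof <- quantify(ann)
  # N counts every genome-mapped tag, including the excluded mRNA one
  expect_true(all(prof$N == 100))
  expect_identical(prof$mirna_id, c("mirA", "mirB", "mirC"))
  expect_equal(prof$C, c(10, 6, 6))
  expect_equal(prof$M, c(1, 2, 2))
  expect_equal(prof$rpm, prof$C / (prof$M * prof$N) * 1e9)
  # a multi-mapping miRNA has half the RPM of a unique one at equal C
  expect_equal(prof$rpm[prof$mirna_id == "mirB"],
               rpm(6, 1, 100) / 2)
  # zero-read miRNAs are absent, empty input gives an empty profile
  expect_false("mirZ" %in% prof$mirna_id)
  expect_identical(nrow(quantify(ann[0, ])), 0L)

  pr <- quantify(ann, m_mode = "per_read")
  expect_equal(pr$C[pr$mirna_id == "mirB"], 3)
  expect_true(all(pr$M == 1))
})

test_that("RPM matches a per-read brute-force oracle on a small library", {
  sim <- small_sim()
  truth <- default_truth(sim$mirnas, contaminants = c(polyA = 0, ambiguous = 0,
                                                      adapter5 = 0, mrna = 0.1))
  lib <- simulate_library(sim$mirnas, truth, library_config(8000, seed = 21),
                          "kapb", mrna = sim$mrna)
  q <- qc_reads(lib)
  refset <- small_refset()
  ann <- annotate_tags(q$tags, refset)
  prof <- quantify(ann)

  # oracle: classify every kept read independently by exhaustive scanning
  tr <- trim_3adapter(lib$seq, default_adapters()$adapter_3p)
  kept <- tr$insert[classify_read(lib$seq, default_adapters()$adapter_3p,
                                  default_adapters()$adapter_5p) == "keep"]
  known <- sim$mirnas[sim$mirnas$is_known, ]
  mapped <- 0; Cs <- stats::setNames(numeric(nrow(known)), known$mirna_id)
  mrna_chr <- as.character(sim$mrna)
  g <- as.character(sim$genome[[1]])
  wins <- lapply(stats::setNames(16:27, 16:27), function(L) {
    substring(g, 1:(nchar(g) - L + 1), L:nchar(g))
  })
  for (u in unique(kept)) {
    cnt <- sum(kept == u)
    w <- wins[[as.character(nchar(u))]]
    if (any(w == u) || any(w == revcomp(u))) mapped <- mapped + cnt
    if (any(vapply(mrna_chr, function(m) grepl(u, m, fixed = TRUE),
                   logical(1)))) next
    hit <- known$mirna_id[known$mature_seq == u]
    if (length(hit)) Cs[hit] <- Cs[hit] + cnt
  }
  Cs <- Cs[Cs > 0]
  expect_identical(sort(names(Cs)), prof$mirna_id)
  expect_equal(unname(Cs[prof$mirna_id]), prof$C)
  expect_true(all(prof$N == mapped))
  expect_equal(prof$rpm, unname(Cs[prof$mirna_id]) / (1 * mapped) * 1e9)
})

test_that("fold changes reproduce the published worked example", {
  expect_equal(fold_change(3.0, 1.5, floor = 1e-12), 2.0)
  # hsa-miR-193b-5p: RPM 2.56436 against the baseline implied by its
  # Kaposin-B column (1.05956 RPM at fold 3.614457009)
  baseline <- 1.05956 / 3.614457009
  expect_equal(fold_change(2.56436, baseline, floor = 1e-12), 8.747752819,
               tolerance = 1e-3)
  # antisymmetry above the floor
  set.seed(3)
  a <- runif(20, 0.1, 50); b <- runif(20, 0.1, 50)
  expect_equal(fold_change(a, b, 1e-6) * fold_change(b, a, 1e-6),
               rep(1, 20))
  expect_error(fold_change(-1, 1, 1), "domain")
})

test_that("differential calls use the inclusive 1.5-fold rule", {
  pa <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                   C = 1, M = 1, N = 1e6,
                   rpm = c(2.0, 1.2, 0.5, 1.5))
  pb <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                   C = 1, M = 1, N = 1e6, rpm = c(1, 1, 1, 1))
  call <- call_differential(pa, pb, floor = 1e-9)
  expect_identical(call$up, c("m1", "m4")) # the exact-1.5 fold is "up"
  expect_identical(call$down, "m3")
  expect_length(intersect(call$up, call$down), 0)

  same <- call_differential(pa, pa, floor = 1e-9)
  expect_length(same$up, 0); expect_length(same$down, 0)
  expect_error(call_differential(pa, pb, threshold = 1), "config")

  # threshold duality: up(A vs B) == down(B vs A)
  rev <- call_differential(pb, pa, floor = 1e-9)
  expect_identical(sort(call$up), sort(rev$down))
  expect_identical(sort(call$down), sort(rev$up))
})

test_that("published table rows satisfy the internal ratio identity", {
  # hsa-miR-9-5p (reduced table)
  chk <- check_table_row(2.10847, 7.9467, 0.139661522, 0.526376101)
  expect_true(chk$consistent)
  expect_lt(chk$residual, 1e-3)
  # hsa-miR-210-3p (induced table)
  chk <- check_table_row(66.5023, 47.8789, 4.606251818, 3.316310416)
  expect_true(chk$consistent)
  # hsa-miR-193b-5p, including its implied baseline RPM
  chk <- check_table_row(2.56436, 1.05956, 8.747752819, 3.614457009)
  expect_true(chk$consistent)
  expect_equal(chk$baseline_rpm, 1.05956 / 3.614457009)
  # a genuinely broken row is flagged
  chk <- check_table_row(10, 1, 2, 2)
  expect_false(chk$consistent)
  expect_error(check_table_row(0, 1, 1, 1), "domain")
})
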