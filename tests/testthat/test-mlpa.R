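test_that("normalization divides by the mean size-adjusted reference signal", {
  panel <- tiny_panel()
  # unit scaling: probe A1 = 200 against refs 100 and 300 -> exactly 1.0
  areas <- c(A1 = 200, A2 = 100, B1 = 100, r1 = 100, r2 = 300)
  norm <- normalize_sample(areas, panel)
  expect_equal(unname(norm["A1"]), 1.0)

  # scale invariance: doubling every area changes nothing
  expect_equal(normalize_sample(areas * 2, panel), norm)

  # a zero reference probe is excluded with a warning, mean over the rest
  areas0 <- c(A1 = 200, A2 = 100, B1 = 100, r1 = 0, r2 = 100)
  expect_warning(norm0 <- normalize_sample(areas0, panel),
                 class = "gistddr_mlpa_warning")
  expect_equal(unname(norm0["A1"]), 2.0)

  # all references dead -> normalization error
  areasX <- c(A1 = 200, A2 = 100, B1 = 100, r1 = 0, r2 = 0)
  expect_error(suppressWarnings(normalize_sample(areasX, panel)),
               class = "gistddr_normalization_error")
})

test_that("dosage quotients are tumor-over-pooled-reference ratios", {
  # tumor identical to the reference normal -> DQ 1 everywhere
  dq1 <- compute_dq(peaks_from_dq(c(A1 = 1, A2 = 1, B1 = 1)), tiny_panel())
  expect_equal(dq1$dq, rep(1, 3), tolerance = 1e-12)

  # hand-planted ratio 0.5
  dq2 <- compute_dq(peaks_from_dq(c(A1 = 0.5, A2 = 1, B1 = 1)), tiny_panel())
  expect_equal(dq2$dq[dq2$probe_id == "A1"], 0.5, tolerance = 1e-12)

  # discordant replicates are flagged uninformative
  peaks <- dplyr::bind_rows(
    dplyr::mutate(peaks_from_dq(c(A1 = 0.4)), replicate = 1L),
    dplyr::mutate(peaks_from_dq(c(A1 = 1.0)), replicate = 2L)
  )
  dq3 <- compute_dq(peaks, tiny_panel())
  expect_false(dq3$informative[dq3$probe_id == "A1"])
  expect_true(all(dq3$informative[dq3$probe_id != "A1"]))
})

test_that("median-mode calling applies the DQ thresholds", {
  expect_equal(call_gene_median(c(0.55, 0.60, 0.80))$call, "heterozygous_deletion")
  expect_equal(call_gene_median(c(1.0, 1.05, 0.98))$call, "normal")
  expect_equal(call_gene_median(c(1.30, 1.40))$call, "heterozygous_duplication")
  expect_equal(call_gene_median(c(0.05, 0.0, 0.1))$call, "homozygous_deletion")
  expect_equal(call_gene_median(numeric(0))$call, "no_call")
  expect_equal(call_gene_median(c(0.7, 0.7))$call, "heterozygous_deletion") # inclusive
})

test_that("any-probe calling flags one aberrant exon, deletion first", {
  expect_equal(call_gene_anyprobe(c(0.65, 0.90))$call, "heterozygous_deletion")
  expect_equal(call_gene_anyprobe(c(1.0, 1.0))$call, "normal")
  expect_equal(call_gene_anyprobe(c(1.35, 1.0))$call, "heterozygous_duplication")
  mixed <- call_gene_anyprobe(c(0.6, 1.4))
  expect_equal(mixed$call, "heterozygous_deletion")
  expect_true(mixed$mixed_pattern)
})

test_that("calling is monotone: lowering DQs never moves away from deletion", {
  rank_call <- c(heterozygous_duplication = 4, normal = 3,
                 heterozygous_deletion = 2, homozygous_deletion = 1)
  set.seed(9)
  for (i in 1:40) {
    dqs <- runif(5, 0, 1.6)
    shrunk <- dqs * runif(1, 0.3, 1)
    expect_lte(rank_call[call_gene_median(shrunk)$call],
               rank_call[call_gene_median(dqs)$call])
    expect_lte(rank_call[call_gene_anyprobe(shrunk[1:2])$call],
               rank_call[call_gene_anyprobe(dqs[1:2])$call])
  }
})

test_that("noiseless planted copy numbers are recovered exactly", {
  set.seed(2)
  n <- 60
  genes <- c("RB1", "BRCA2", "CHEK2")
  truth <- tidyr::expand_grid(sample_id = sprintf("S%03d", 1:n), gene = genes) %>%
    dplyr::mutate(copy_number = sample(0:3, dplyr::n(), TRUE))
  peaks <- synth_mlpa_peaks(truth, noise_cv = 0, seed = 1)
  calls <- mlpa_call(peaks, default_panel())
  merged <- dplyr::left_join(calls, truth, by = c("sample_id", "gene"))
  expected <- c("homozygous_deletion", "heterozygous_deletion", "normal",
                "heterozygous_duplication")[merged$copy_number + 1]
  # CHEK2 is called in any-probe mode, which reports any loss as HetDel
  expected[merged$gene == "CHEK2" & merged$copy_number == 0] <-
    "heterozygous_deletion"
  expect_equal(merged$call, expected)

  # a reference normal processed as a tumor stays within 5% of DQ 1
  normals <- dplyr::mutate(truth, copy_number = 2L)
  dq <- compute_dq(synth_mlpa_peaks(normals, noise_cv = 0, seed = 3),
                   default_panel())
  expect_true(all(abs(dq$dq - 1) < 0.05))
})

test_that("cohort summaries report one-decimal prevalences and co-deletions", {
  calls <- mlpa_calls_long_fixture()
  s <- summarize_mlpa(calls)
  expect_equal(s$per_gene$percent_hetdel[s$per_gene$gene == "CHEK2"], 75.6)
  expect_equal(s$per_gene$percent_hetdel[s$per_gene$gene == "RB1"], 9.8)
  expect_equal(s$per_gene$percent_hetdel[s$per_gene$gene == "BRCA2"], 12.2)
  co <- s$co_deletion
  expect_equal(co$n_co[co$gene_a == "BRCA2" & co$gene_b == "RB1"], 2L)

  none <- summarize_mlpa(tibble::tibble(sample_id = c("a", "b"),
                                        gene = "RB1", call = "normal"))
  expect_equal(none$per_gene$percent_hetdel, 0.0)
})
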