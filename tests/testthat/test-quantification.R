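qpcr_row <- function(sample_id, strain, assay, channel, cq) {
  tibble::tibble(sample_id = sample_id, strain = strain, assay = assay,
                 channel = channel, cq1 = cq[1], cq2 = cq[2], cq3 = cq[3])
}

two_channel <- function(sample_id, strain, assay, target, normalizer) {
  dplyr::bind_rows(
    qpcr_row(sample_id, strain, assay, "target", target),
    qpcr_row(sample_id, strain, assay, "normalizer", normalizer)
  )
}

test_that("triplicate QC applies the 0.4-cycle SD rule on worked examples", {
  q <- dplyr::bind_rows(
    two_channel("a", "s1", "g", c(20, 20, 20), c(18, 18, 18)),
    two_channel("b", "s1", "g", c(20, 20.5, 21), c(18, 18, 18)),
    two_channel("c", "s1", "g", c(20, 20.2, 20.4), c(18, 18, 18))
  )
  qc <- qc_triplicates(q)
  expect_equal(qc$sd_target[qc$sample_id == "a"], 0)
  expect_equal(qc$sd_target[qc$sample_id == "b"], 0.5)
  expect_equal(qc$sd_target[qc$sample_id == "c"], 0.2)
  expect_equal(qc$pass, c(TRUE, FALSE, TRUE))
  expect_error(qc_triplicates(dplyr::mutate(q, cq1 = NA)), "non-finite")
})

test_that("delta-Ct is the target-minus-normalizer mean and drops QC failures", {
  q <- dplyr::bind_rows(
    two_channel("a", "s1", "g", c(20, 20, 20), c(18, 18, 18)),
    two_channel("b", "s1", "g", c(18, 18, 18), c(20, 20, 20)),
    two_channel("c", "s1", "g", c(19, 19, 19), c(19, 19, 19)),
    two_channel("d", "s1", "g", c(19, 20, 21), c(19, 19, 19))
  )
  expect_message(dct <- delta_ct(q), "excluded 1")
  expect_equal(dct$delta_ct[dct$sample_id == "a"], 2)
  expect_equal(dct$delta_ct[dct$sample_id == "b"], -2)
  expect_equal(dct$delta_ct[dct$sample_id == "c"], 0)
  expect_false("d" %in% dct$sample_id)
})

test_that("fold change is exactly 2^-ddCt with log2_fc = -ddCt", {
  dct <- tibble::tibble(sample_id = c("a", "b", "c"), strain = "s",
                        assay = "g", delta_ct = c(2, 1, 4))
  fc <- fold_change(dct, reference_dct = 2)
  expect_equal(fc$fc, c(1, 2, 0.25))
  expect_equal(fc$log2_fc, -fc$ddct, tolerance = 1e-15)
  expect_equal(log2(fc$fc), -fc$ddct, tolerance = 1e-12)
})

test_that("fold change is invariant to a constant Cq shift on both channels", {
  q <- dplyr::bind_rows(
    two_channel("a", "s1", "g", c(20, 20.1, 19.9), c(18, 18.2, 17.8)),
    two_channel("b", "s2", "g", c(22, 22.1, 21.9), c(18, 18.1, 17.9))
  )
  shifted <- dplyr::mutate(q, cq1 = cq1 + 3.7, cq2 = cq2 + 3.7, cq3 = cq3 + 3.7)
  f1 <- fold_change(delta_ct(q), 0)
  f2 <- fold_change(delta_ct(shifted), 0)
  expect_equal(f1$fc, f2$fc, tolerance = 1e-12)
})

test_that("log2 fold-change estimates are nearly unbiased at Cq noise 0.1", {
  set.seed(88)
  true_log2 <- 1.7
  n <- 1000
  rows <- lapply(seq_len(n), function(i) {
    two_channel(sprintf("s%04d", i), "s", "g",
                rnorm(3, 20 - true_log2, 0.1), rnorm(3, 20, 0.1))
  })
  fc <- fold_change(delta_ct(dplyr::bind_rows(rows), max_sd = Inf), 0)
  expect_lt(abs(mean(fc$log2_fc) - true_log2), 0.05)
})

test_that("density quantification uses a seeded calibrator sample", {
  study <- make_study(n_strains = 4, seed = 12)
  f1 <- quantify_density(study$qpcr_density, reference_strain = "s01", seed = 4)
  f2 <- quantify_density(study$qpcr_density, reference_strain = "s01", seed = 4)
  expect_identical(attr(f1, "reference_sample"), attr(f2, "reference_sample"))
  expect_equal(f1$fc, f2$fc)
  expect_true(startsWith(attr(f1, "reference_sample"), "ftsZ_s01"))
  # the calibrator sample itself has fc = 1
  expect_equal(f1$fc[f1$sample_id == attr(f1, "reference_sample")], 1)
  expect_error(quantify_density(study$qpcr_density, reference_strain = "nope"),
               "reference strain")
})

test_that("transcript quantification calibrates on the reference assay groups", {
  study <- make_study(n_strains = 5, cq_sd = 0, seed = 13)
  refs <- study$params$reference_assays_cifB
  fc <- quantify_transcripts(study$qpcr_cifB, reference_assays = refs)
  # noiseless Cq: estimated log2 fc equals the centred generating truth
  truth <- study$truth$cifB_log2 -
    mean(study$truth$cifB_log2[study$truth$strain %in% study$params$reference_strains])
  est <- tapply(fc$log2_fc, fc$strain, mean)
  expect_equal(as.numeric(est[study$truth$strain]), unname(truth), tolerance = 1e-9)
  expect_error(quantify_transcripts(study$qpcr_cifB, reference_assays = "none"),
               "reference")
})

test_that("strain comparisons are Welch t tests with BH adjustment", {
  set.seed(41)
  fc <- tibble::tibble(
    strain = rep(c("wMel", "hi", "same", "solo"), c(6, 6, 6, 1)),
    log2_fc = c(rnorm(6, 0, 0.2), rnorm(6, 3, 0.2), rnorm(6, 0, 0.2), 5)
  )
  expect_warning(res <- compare_to_reference_strain(fc), "solo")
  expect_setequal(res$strain, c("hi", "same"))
  expect_lt(res$p_adjusted[res$strain == "hi"], 0.01)
  expect_gt(res$p_adjusted[res$strain == "same"], 0.1)
  ref <- fc$log2_fc[fc$strain == "wMel"]
  tt <- t.test(fc$log2_fc[fc$strain == "hi"], ref)
  expect_equal(res$p_value[res$strain == "hi"], tt$p.value)
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
})

test_that("BH adjustment yields the textbook values on a worked example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  set.seed(1)
  fc <- tibble::tibble(strain = rep(c("wMel", "x"), each = 4),
                       log2_fc = rnorm(8))
  res <- compare_to_reference_strain(fc)
  expect_equal(res$p_adjusted, res$p_value)  # single comparison
})
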