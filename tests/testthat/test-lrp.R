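# Layer-wise relevance propagation: hand-computed examples, rule algebra,
# pooling routing, and dataset-level aggregation.

test_that("epsilon rule reproduces hand-computed two-input example", {
  # z = 1*3 + 1*1 = 4; shares 3/4 and 1/4 at epsilon = 0
  r0 <- propagate_affine(1, c(1, 1), matrix(c(3, 1), 2, 1), 0,
                         relevance_rule("epsilon", epsilon = 0))
  expect_equal(r0, c(0.75, 0.25))
  # epsilon = 100: denominator 104, shares 3/104 and 1/104
  r100 <- propagate_affine(1, c(1, 1), matrix(c(3, 1), 2, 1), 0,
                           relevance_rule("epsilon", epsilon = 100))
  expect_equal(r100, c(3 / 104, 1 / 104))
})

test_that("epsilon stabilizer moves negative denominators away from zero", {
  # z = -2; denominator -2 - 1 = -3; shares (-4)/(-3), 2/(-3)
  r <- propagate_affine(1, c(2, 2), matrix(c(-2, 1), 2, 1), 0,
                        relevance_rule("epsilon", epsilon = 1))
  expect_equal(r, c(4 / 3, -2 / 3))
})

test_that("alpha-beta(1,0) keeps only the positive pool", {
  r <- propagate_affine(1, c(1, 1), matrix(c(1, -1), 2, 1), 0,
                        relevance_rule("alphabeta"))
  expect_equal(r, c(1, 0))
})

test_that("alpha-beta(2,1) combines both pools with hand weights", {
  # contributions +1 and -1: P = 1, N = -1
  # R_pos = 2 * 1/1 = 2; R_neg = -1 * (-1)/(-1) = -1
  r <- propagate_affine(1, c(1, 1), matrix(c(1, -1), 2, 1), 0,
                        relevance_rule("alphabeta", alpha = 2, beta = 1))
  expect_equal(r, c(2, -1))
})

test_that("bias participates in the denominator and absorbs relevance", {
  # z = 2 + 2 (bias); epsilon 0 -> input share 2/4, bias share absorbed
  r <- propagate_affine(1, 2, matrix(1), 2, relevance_rule("epsilon", epsilon = 0))
  expect_equal(r, 0.5)
})

test_that("relevance_rule validates its arguments", {
  expect_error(relevance_rule("epsilon", epsilon = -1), "epsilon")
  expect_error(relevance_rule("alphabeta", alpha = 2, beta = 0.5), "alpha - beta")
  expect_error(relevance_rule("alphabeta", alpha = 0.5, beta = -0.5), ">= 0")
})

test_that("maxpool routes relevance winner-take-all with ties to earliest", {
  expect_equal(propagate_maxpool(c(1, 2), c(0.1, 0.9, 0.5, 0.5)),
               c(0, 1, 2, 0))              # tie in second window -> earliest
  expect_equal(propagate_maxpool(5, c(1, 7, 3), size = "global"), c(0, 5, 0))
})

test_that("passthrough layers leave relevance unchanged and flatten reshapes", {
  r <- matrix(1:6, 2, 3)
  expect_identical(propagate_passthrough(r, "dropout"), r)
  reshaped <- propagate_passthrough(r, "flatten", dims = c(3, 2))
  expect_equal(dim(reshaped), c(3, 2))
  expect_equal(as.vector(reshaped), as.vector(r))
})

test_that("assigned class is the argmax and start relevance is exactly 1", {
  W <- toy_weights(6, 3)
  m <- toy_dense_model(list(W), list(c(0.1, 0, -0.1)))
  x <- matrix(sin(1:6), 6, 1)
  out <- assign_output_relevance(m, x)
  logits <- as.numeric(as.numeric(x) %*% W) + c(0.1, 0, -0.1)
  expect_equal(out$class_index, which.max(logits))
  expect_identical(out$start_relevance, 1)
})

test_that("lrp_explain matches the path-enumeration oracle on dense nets", {
  set.seed(42)
  Ws2 <- list(matrix(rnorm(4 * 4), 4, 4), matrix(rnorm(4 * 3), 4, 3))
  bs2 <- list(rnorm(4) * 0.1, rnorm(3) * 0.1)
  Ws3 <- list(matrix(rnorm(5 * 4), 5, 4), matrix(rnorm(4 * 4), 4, 4),
              matrix(rnorm(4 * 3), 4, 3))
  bs3 <- list(rnorm(4) * 0.1, rnorm(4) * 0.1, rnorm(3) * 0.1)
  rules <- list(relevance_rule("epsilon", epsilon = 0.01),
                relevance_rule("epsilon", epsilon = 100),
                relevance_rule("alphabeta"),
                relevance_rule("alphabeta", alpha = 2, beta = 1))
  for (net in list(list(Ws2, bs2), list(Ws3, bs3))) {
    Ws <- net[[1]]; bs <- net[[2]]
    m <- toy_dense_model(Ws, bs)
    x <- matrix(sin(seq_len(nrow(Ws[[1]])) * 1.3), ncol = 1)
    for (rule in rules) {
      oracle <- lrp_path_oracle(x, Ws, bs, rule)
      got <- lrp_explain(m, x, rule)
      expect_equal(as.numeric(got$relevance), oracle$relevance,
                   tolerance = 1e-10)
      expect_equal(match(got$assigned_class, stage_levels()),
                   oracle$class_index)
    }
  }
})

test_that("convolution relevance equals its Toeplitz-unrolled affine oracle", {
  set.seed(7)
  input_len <- 6L; K <- 3L; F_ <- 2L
  Wc <- matrix(rnorm(K * F_), K, F_)
  bc <- c(0.05, -0.05)
  Lo <- input_len - K + 1L
  Wd <- matrix(rnorm(Lo * F_ * 3), Lo * F_, 3)
  bd <- rnorm(3) * 0.1
  m <- toy_conv_model(Wc, bc, Wd, bd, input_len)
  unrolled <- conv_as_dense(Wc, bc, input_len)
  x <- matrix(cos(seq_len(input_len)), ncol = 1)
  for (rule in list(relevance_rule("epsilon", epsilon = 0.01),
                    relevance_rule("alphabeta"))) {
    oracle <- lrp_path_oracle(x, list(unrolled$W, Wd), list(unrolled$b, bd),
                              rule)
    got <- lrp_explain(m, x, rule)
    expect_equal(as.numeric(got$relevance), oracle$relevance,
                 tolerance = 1e-10)
  }
})

test_that("zero-bias toy nets conserve relevance; alpha-beta(1,0) is nonnegative", {
  set.seed(12)                       # a net whose argmax logit is nonzero
  Ws <- list(matrix(rnorm(6 * 5), 6, 5), matrix(rnorm(5 * 4), 5, 4),
             matrix(rnorm(4 * 3), 4, 3))
  bs <- lapply(c(5, 4, 3), numeric)
  m <- toy_dense_model(Ws, bs)
  x <- matrix(sin(1:6 * 2.1), ncol = 1)
  r_eps <- lrp_explain(m, x, relevance_rule("epsilon", epsilon = 0))
  expect_equal(sum(r_eps$relevance), 1, tolerance = 1e-10)
  r_ab <- lrp_explain(m, x, relevance_rule("alphabeta"))
  expect_equal(sum(r_ab$relevance), 1, tolerance = 1e-10)
  expect_gte(min(r_ab$relevance), 0)
})

test_that("lrp_dataset produces consistent per-sample records", {
  tiny <- cached_tiny_fit()
  sub <- subset_samples(tiny$ds, 1:6)
  rec <- lrp_dataset(tiny$fit, sub, relevance_rule("epsilon", epsilon = 0.01),
                     fold = 2L)
  expect_s3_class(rec, "lrp_records")
  expect_equal(nrow(rec), 6 * 3)
  expect_setequal(unique(rec$modality), modality_names())
  expect_true(all(rec$fold == 2L))
  # per-sample percentages sum to 100
  sums <- tapply(rec$percent_abs, rec$sample_id, sum)
  expect_equal(as.numeric(sums), rep(100, 6), tolerance = 1e-8)
  # abs_relevance matches a direct single-sample lrp_explain reduction
  one <- lrp_explain(tiny$fit, sub$samples[3, , ],
                     relevance_rule("epsilon", epsilon = 0.01))
  expect_equal(rec$abs_relevance[rec$sample_id == 3],
               unname(colSums(abs(one$relevance))), tolerance = 1e-10)
  expect_equal(unique(rec$predicted[rec$sample_id == 3]), one$assigned_class)
})

test_that("modality_percent_relevance pools within groups and medians across folds", {
  records <- tibble::tibble(
    sample_id = rep(1:4, each = 3),
    fold = rep(c(1L, 1L, 2L, 2L), each = 3),
    true = "Awake", predicted = "Awake",
    modality = rep(c("EEG", "EOG", "EMG"), 4),
    abs_relevance = c(6, 3, 1,   2, 1, 1,   8, 1, 1,   0, 1, 1),
    percent_abs = NA_real_)
  out <- modality_percent_relevance(records)
  expect_s3_class(out, "modality_relevance")
  # fold 1 pooled: EEG 8/14, EOG 4/14, EMG 2/14; fold 2: 8/12, 2/12, 2/12
  eeg <- out$percent[out$modality == "EEG"]
  expect_equal(eeg, stats::median(c(100 * 8 / 14, 100 * 8 / 12)))
  # pooled percentages of a group sum to 100 within each fold, so the
  # medians of this two-fold case keep that property per construction
  expect_equal(sum(out$percent), 100, tolerance = 1e-10)
  expect_true(all(out$n_folds == 2))
})

test_that("modality_percent_relevance per-sample branch averages percentages", {
  records <- tibble::tibble(
    sample_id = rep(1:2, each = 3), fold = 1L,
    true = "REM", predicted = "REM",
    modality = rep(c("EEG", "EOG", "EMG"), 2),
    abs_relevance = 1,
    percent_abs = c(50, 30, 20, 70, 10, 20))
  out <- modality_percent_relevance(records, per_sample = TRUE)
  expect_equal(out$percent[out$modality == "EEG"], 60)
  expect_equal(out$percent[out$modality == "EOG"], 20)
})

test_that("relevance_time_course requires chronological order and smooths", {
  records <- tibble::tibble(
    sample_id = rep(1:4, each = 3), fold = 1L,
    true = "Awake", predicted = "Awake",
    modality = rep(c("EEG", "EOG", "EMG"), 4),
    abs_relevance = 1,
    percent_abs = rep(c(40, 30, 30), 4) + rep(c(0, 10, -10, 0), each = 3),
    epoch_index = rep(c(1L, 2L, 3L, 4L), each = 3))
  tc <- relevance_time_course(records)
  expect_equal(nrow(tc), 12)
  eeg <- tc$percent[tc$modality == "EEG"]
  expect_equal(eeg, c(40, 50, 30, 40))
  sm <- relevance_time_course(records, window = 3L)
  eeg_sm <- sm$percent[sm$modality == "EEG"]
  expect_equal(eeg_sm[2:3], c(40, 40))
  expect_true(all(is.na(eeg_sm[c(1, 4)])))
  bad <- records
  bad$epoch_index <- rep(c(3L, 1L, 2L, 4L), each = 3)
  expect_error(relevance_time_course(bad), "chronological")
})
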