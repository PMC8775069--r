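test_that("permutation entropy reproduces closed-form cases", {
  expect_equal(permutation_entropy(1:6), 0)
  expect_equal(permutation_entropy(seq(10, 1)), 0)
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), order = 2),
               -(4 / 6) * log2(4 / 6) - (2 / 6) * log2(2 / 6))
  # constant series: single pattern under stable ranking
  expect_equal(permutation_entropy(rep(1, 20)), 0)
  expect_error(permutation_entropy(1:2, order = 3), "too short")
  expect_error(permutation_entropy(1:10, order = 1), "order")
})

test_that("PE agrees with a brute-force enumeration oracle", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    order <- sample(2:4, 1)
    delay <- sample(1:2, 1)
    if (n <= (order - 1) * delay) next
    # mix continuous values and ties
    x <- if (i %% 3 == 0) sample(0:3, n, replace = TRUE) else rnorm(n)
    expect_equal(permutation_entropy(x, order, delay),
                 pe_oracle(x, order, delay), tolerance = 1e-12)
  }
})

test_that("iid series approach the maximum-entropy limit", {
  set.seed(3)
  pe <- permutation_entropy(runif(1e5), order = 3)
  expect_lt(abs(pe - log2(6)), 0.02)
  expect_lte(pe, log2(6))
  # normalised variant
  expect_lt(abs(permutation_entropy(runif(1e4), normalize = TRUE) - 1), 0.05)
})

test_that("PE is invariant under strictly increasing transforms and bounded", {
  set.seed(5)
  x <- rnorm(300)
  for (f in list(function(z) 3 * z + 2, exp, function(z) z^3)) {
    expect_equal(permutation_entropy(f(x)), permutation_entropy(x),
                 tolerance = 1e-12)
  }
  for (order in 2:4) {
    pe <- permutation_entropy(x, order)
    expect_gte(pe, 0)
    expect_lte(pe, log2(factorial(order)))
  }
})

test_that("the PE table covers every subject, layer and channel", {
  tens <- tiny_cohort_tensors(seed = 4, delta = 2, subjects = 2L,
                              epochs = 6L)
  xy <- cohort_xy(tens)
  m <- train_cnn(build_cnn(), xy$X, xy$y,
                 train_config(epochs = 2, batch_size = 12L, seed = 9))
  tab <- layer_pe_table(m, tens)
  expect_equal(nrow(tab), 4L * 3L * 19L)
  expect_setequal(unique(tab$layer), c("input", "Conv1", "Conv2"))
  expect_true(all(tab$pe >= 0 & tab$pe <= log2(6)))
  # one row per (subject, layer, channel)
  expect_equal(anyDuplicated(tab[c("subject_id", "layer", "channel")]), 0L)

  # efficient path agrees with the reference route through
  # extract_feature_maps + filter/epoch averaging
  maps <- extract_feature_maps(m, tens[[1]]$tensor, "Conv2")
  ref <- pnesnet:::channel_pe(maps, 3, 1)
  got <- tab$pe[tab$subject_id == tens[[1]]$subject_id &
                  tab$layer == "Conv2"]
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("per-channel tests and depth counts are consistent", {
  tens <- tiny_cohort_tensors(seed = 4, delta = 2, subjects = 3L,
                              epochs = 6L)
  xy <- cohort_xy(tens)
  m <- train_cnn(build_cnn(), xy$X, xy$y,
                 train_config(epochs = 2, batch_size = 18L, seed = 9))
  tab <- layer_pe_table(m, tens)
  tests <- channel_pe_tests(tab, "Conv1")
  expect_equal(nrow(tests), 19L)
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  ds <- depth_separability(tab, alpha = 0.05)
  expect_named(ds, c("input", "Conv1", "Conv2"))
  expect_equal(unname(ds["Conv1"]),
               sum(channel_pe_tests(tab, "Conv1")$p_value < 0.05))
  # Bonferroni never decreases p-values
  bt <- channel_pe_tests(tab, "Conv1", bonferroni = TRUE)
  expect_true(all(bt$p_value >= tests$p_value - 1e-12))
})

test_that("input-layer PE shows no class difference at delta = 0", {
  tens <- tiny_cohort_tensors(seed = 12, delta = 0, subjects = 5L,
                              epochs = 6L)
  tab <- layer_pe_table(build_cnn(), tens, layers = "input")
  tests <- channel_pe_tests(tab, "input")
  # identical generative law: significant channels only at the alpha rate
  expect_lte(sum(tests$p_value < 0.05), 3L)
})
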