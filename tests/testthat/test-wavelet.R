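test_that("decomposition structure matches the MATLAB-style bookkeeping", {
  set.seed(1)
  d <- dwt_decompose(rnorm(512))
  expect_identical(d$l, c(22L, 22L, 38L, 70L, 133L, 259L, 512L),
                   ignore_attr = TRUE)
  expect_length(d$c, sum(d$l[1:6]))
  # frozen single-step reference values (independent PyWavelets oracle,
  # symmetric half-point extension, db4, x = 1:16)
  st <- pnesnet:::dwt_step(1:16, pnesnet:::db4_filters())
  ca_ref <- c(7.064531462580935, 4.230736111149599, 1.4136071660758236,
              2.8360542803424087, 5.6644814050885985, 8.49290852983479,
              11.32133565458098, 14.14976277932717, 16.97709909776168,
              19.810894449193015, 22.62802339426679)
  expect_equal(st$a, ca_ref, tolerance = 1e-12)
  expect_equal(st$d[4:8], rep(0, 5), tolerance = 1e-12)  # linear ramp: details vanish
})

test_that("the six sub-band reconstructions sum to the original signal", {
  set.seed(4)
  for (x in list(rnorm(512), sin(2 * pi * 7 * (0:511) / 256), rep(0, 512))) {
    dec <- dwt_decompose(x)
    tot <- reconstruct_subband(dec, "approximation", 5)
    for (j in 1:5) tot <- tot + reconstruct_subband(dec, "detail", j)
    expect_lt(max(abs(tot - x)), 1e-8 * max(sd(x), 1e-3))
  }
  # unit impulse reproduces exactly
  imp <- numeric(512); imp[256] <- 1
  dec <- dwt_decompose(imp)
  tot <- reconstruct_subband(dec, "approximation", 5)
  for (j in 1:5) tot <- tot + reconstruct_subband(dec, "detail", j)
  expect_lt(max(abs(tot - imp)), 1e-10)
})

test_that("decomposition is linear", {
  set.seed(9)
  x <- rnorm(512); y <- rnorm(512)
  dxy <- dwt_decompose(2.5 * x - 1.25 * y)
  dx <- dwt_decompose(x); dy <- dwt_decompose(y)
  expect_equal(dxy$c, 2.5 * dx$c - 1.25 * dy$c, tolerance = 1e-10)
})

test_that("pure tones place their energy in the nominal band", {
  fs <- 256
  t <- (0:511) / fs
  band_energy <- function(x) {
    dec <- dwt_decompose(x)
    e <- vapply(1:5, function(j) sum(reconstruct_subband(dec, "detail", j)^2),
                numeric(1))
    c(e, sum(reconstruct_subband(dec, "approximation", 5)^2))
  }
  # 2 Hz -> a5 (0-4); 30 Hz -> d3 (16-32); 6 Hz -> d5 (4-8)
  e2 <- band_energy(sin(2 * pi * 2 * t))
  expect_equal(which.max(e2), 6L)
  expect_gt(e2[6] / sum(e2), 0.9)
  e30 <- band_energy(sin(2 * pi * 30 * t))
  expect_equal(which.max(e30), 3L)
  e6 <- band_energy(sin(2 * pi * 6 * t))
  expect_equal(which.max(e6), 5L)
  # 2 Hz coefficient energy concentrates in the a5 block of (c, l)
  dec <- dwt_decompose(sin(2 * pi * 2 * t))
  blocks <- pnesnet:::dwt_blocks(dec)
  expect_gt(sum(blocks$a5^2) / sum(dec$c^2), 0.9)
})

test_that("invalid arguments are rejected", {
  dec <- dwt_decompose(rnorm(512))
  expect_error(reconstruct_subband(dec, "detail", 7), "depth")
  expect_error(reconstruct_subband(dec, "approximation", 3), "deepest")
  expect_error(dwt_decompose(rnorm(8)), "too short")
  expect_error(dwt_decompose(rnorm(512), wavelet = "db2"), "db4")
})

test_that("tensor build matches the per-signal route and keeps Eq.-4 exactness", {
  tens <- tiny_cohort_tensors(seed = 3, subjects = 1L, epochs = 2L)
  v <- tens[[1]]$tensor$values
  expect_equal(dim(v), c(2L, 19L, 512L, 6L))
  expect_identical(tens[[1]]$tensor$band_order,
                   c("d1", "d2", "d3", "d4", "d5", "a5"))
  # dual route: C++ fast path vs R-level wavedec/wrcoef
  sp <- tiny_spec(seed = 3, subjects = 1L, epochs = 2L)
  coh <- generate_cohort(sp)
  x <- coh[[1]]$recording$data[7, 513:1024]
  dec <- dwt_decompose(x)
  expect_equal(v[2, 7, , 3], reconstruct_subband(dec, "detail", 3),
               tolerance = 1e-12)
  expect_equal(v[2, 7, , 6], reconstruct_subband(dec, "approximation", 5),
               tolerance = 1e-12)
  # per-entry Eq. 4: band axis sums to the original epoch
  recon <- apply(v, c(1, 2, 3), sum)
  expect_equal(recon[2, 7, ], x, tolerance = 1e-8)
  # zero epoch -> zero tensor slice
  ep0 <- structure(list(epochs = array(0, c(1, 2, 512)), epoch_index = 1L,
                        sampling_rate = 256, channel_names = c("Fp1", "Fp2")),
                   class = "epoch_array")
  expect_true(all(build_epoch_tensor(ep0)$values == 0))
})
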