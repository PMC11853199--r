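test_that("the db7 decomposition is linear, energy-conserving and invertible", {
  # zero in, zero out at every level
  z <- dwt_decompose(numeric(24000), levels = 10)
  expect_true(all(vapply(coefficient_sets(z), function(s) all(s == 0),
                         logical(1))))

  # periodized mode on a fully dyadic length is an orthogonal transform
  for (case in list(c(1024L, 6L), c(24576L, 10L))) {
    x <- withr::with_seed(case[1], rnorm(case[1]))
    d <- dwt_decompose(x, levels = case[2], mode = "periodic")
    energy <- sum(vapply(coefficient_sets(d),
                         function(s) sum(s^2), numeric(1)))
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-8)
  }

  # perfect reconstruction in both boundary modes at the working length
  x <- withr::with_seed(8, rnorm(24000))
  for (mode in c("symmetric", "periodic")) {
    d <- dwt_decompose(x, levels = 10, mode = mode)
    expect_lt(max(abs(dwt_reconstruct(d) - x)), 1e-8)
  }

  expect_error(dwt_decompose(rnorm(100), levels = 10),
               class = "respscreen_contract_error")
})

test_that("a 24000-sample segment yields 11 coefficient sets of dyadic lengths", {
  d <- dwt_decompose(withr::with_seed(9, rnorm(24000)), levels = 10)
  sets <- coefficient_sets(d)
  expect_length(sets, 11)
  expect_named(sets, c("cA", paste0("cD", 1:10)))
  lens <- vapply(d$cD, length, integer(1))
  expect_true(all(diff(lens) < 0))          # each level roughly halves
  expect_equal(length(d$cA), length(d$cD$cD10))
})

test_that("Shannon entropy matches closed forms on constructed histograms", {
  expect_equal(shannon_entropy(rep(0.37, 1000)), 0)
  # equal split between two bin centers: 1 bit
  expect_equal(shannon_entropy(c(rep(-0.5, 64), rep(0.5, 64))), 1)
  # probabilities (1/2, 1/4, 1/4): -sum p log2 p = 1.5 bits
  vals <- c(rep(-0.9, 2), rep(0.1, 1), rep(0.9, 1))
  expect_equal(shannon_entropy(vals), 1.5)
  # never exceeds log2(n_bins)
  x <- withr::with_seed(10, runif(5000, -1, 1))
  expect_lte(shannon_entropy(x, n_bins = 64), log2(64))
  expect_error(shannon_entropy(numeric(0)),
               class = "respscreen_contract_error")
  expect_error(shannon_entropy(1:5, n_bins = 1),
               class = "respscreen_contract_error")
})

test_that("spectral entropy reflects spectral concentration", {
  tone <- sine_recording(500)
  expect_lte(spectral_entropy(tone), 0.05)
  two <- sine_recording(500)$samples + sine_recording(750)$samples
  expect_lt(abs(spectral_entropy(two, 4000) - 1), 0.05)
  # white noise approaches the log2 of the number of frequency bins
  n_bins <- 24000 / 2 + 1
  for (seed in 1:10) {
    se <- spectral_entropy(withr::with_seed(seed, rnorm(24000)), 4000)
    expect_lt(abs(se - log2(n_bins)) / log2(n_bins), 0.05)
  }
  expect_error(spectral_entropy(numeric(24000), 4000),
               class = "respscreen_degenerate_input_error")
})

test_that("rms matches its closed form", {
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  expect_equal(rms(numeric(5) + 0), 0)
  expect_equal(rms(rep(-2.5, 9)), 2.5)
  expect_error(rms(numeric(0)), class = "respscreen_contract_error")
})

test_that("the 13-feature vector is deterministic, named, and recomputable", {
  seg <- segment_recording(normalize_recording(
    generate_recording("copd", tiny_spec(), seed = 3)))[[1]]
  fv1 <- extract_feature_vector(seg)
  fv2 <- extract_feature_vector(seg)
  expect_identical(fv1, fv2)
  expect_named(fv1, feature_names())
  expect_true(all(is.finite(fv1)))
  expect_true(all(fv1[3:13] >= 0))
  # independent recomputation of each RMS entry from the coefficient sets
  sets <- coefficient_sets(dwt_decompose(seg))
  manual <- vapply(sets, function(s) sqrt(sum(s^2) / length(s)), numeric(1))
  expect_equal(unname(fv1[3:13]), unname(manual))
  # entropies are computed on the raw segment, before the wavelet transform
  expect_equal(unname(fv1["Entropy"]), shannon_entropy(seg$samples))
  expect_equal(unname(fv1["Spec.Entropy"]),
               spectral_entropy(seg$samples, seg$sample_rate))
})

test_that("amplitude scaling scales RMS features and fixes spectral entropy", {
  seg <- withr::with_seed(11, rnorm(24000, sd = 0.2))
  fv <- extract_feature_vector(seg, sample_rate = 4000)
  fv_half <- extract_feature_vector(0.5 * seg, sample_rate = 4000)
  expect_equal(unname(fv_half[3:13]), unname(0.5 * fv[3:13]))
  expect_equal(unname(fv_half["Spec.Entropy"]), unname(fv["Spec.Entropy"]))
})

test_that("feature tables round-trip through CSV with provenance headers", {
  corpus <- generate_corpus(tiny_spec(n_per_class = 1))
  tab <- extract_features(corpus$recordings)
  expect_equal(nrow(tab), 4)
  expect_true(all(feature_names() %in% names(tab)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path, metadata = c(config_hash = "abc", seed = "1"))
  back <- read_feature_table(path)
  expect_equal(back$label, tab$label)
  expect_equal(back$Entropy, tab$Entropy, tolerance = 1e-12)
  expect_match(readLines(path, n = 1), "^# config_hash: abc$")
})
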