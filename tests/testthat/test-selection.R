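test_that("the H statistic reproduces hand-computed instances", {
  # ranks (1..9), rank sums (6, 15, 24): H = (12/90)(12+75+192) - 30 = 7.2
  expect_equal(kruskal_wallis_h(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))),
               7.2)
  # symmetric rank sums cancel
  expect_equal(kruskal_wallis_h(list(c(1, 4), c(2, 3))), 0)
  # midranks 1.5 and 3.5: H = 2.4 plain, 3.0 with the tie-correction divisor
  expect_equal(kruskal_wallis_h(list(c(1, 1), c(2, 2))), 2.4)
  expect_equal(kruskal_wallis_h(list(c(1, 1), c(2, 2)),
                                tie_correction = TRUE), 3)
  expect_error(kruskal_wallis_h(list(1:3)),
               class = "respscreen_contract_error")
  expect_error(kruskal_wallis_h(list(1:3, numeric(0))),
               class = "respscreen_contract_error")
})

test_that("for two tie-free groups H is the squared standardized rank-sum statistic", {
  # exhaustive enumeration over all 4+4 splits of 8 distinct values
  values <- c(0.3, 1.1, 2.7, 3.1, 4.9, 5.2, 6.8, 7.4)
  for (idx in asplit(combn(8, 4), 2)) {
    g1 <- values[idx]
    g2 <- values[-idx]
    n1 <- 4; n2 <- 4; n <- 8
    r1 <- sum(rank(values)[idx])
    z <- (r1 - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
    expect_equal(kruskal_wallis_h(list(g1, g2)), z^2)
  }
})

test_that("H is invariant under monotone transformation and permutation", {
  for (seed in 1:5) {
    groups <- withr::with_seed(seed, list(rnorm(7), rnorm(5, 1), rnorm(6, 2)))
    h <- kruskal_wallis_h(groups)
    expect_equal(kruskal_wallis_h(lapply(groups, function(g) exp(3 * g))), h)
    expect_equal(kruskal_wallis_h(lapply(groups, function(g) rank(g) * 0 + g)),
                 h)
    # tie-corrected variant agrees with stats::kruskal.test on tie-free data
    kt <- kruskal.test(unlist(groups),
                       rep(seq_along(groups), lengths(groups)))
    expect_equal(kruskal_wallis_h(groups, tie_correction = TRUE),
                 unname(kt$statistic))
  }
})

test_that("chi-squared critical values match a numerical-integration oracle", {
  dens <- function(x, df) x^(df / 2 - 1) * exp(-x / 2) /
    (2^(df / 2) * gamma(df / 2))
  oracle <- function(alpha, df) {
    uniroot(function(q) integrate(dens, q, Inf, df = df)$value - alpha,
            c(1e-6, 100), tol = 1e-10)$root
  }
  expect_lt(abs(chi2_critical(0.05, 3) - oracle(0.05, 3)), 1e-6)
  expect_lt(abs(chi2_critical(0.05, 3) - 7.815), 1e-3)
  expect_lt(abs(chi2_critical(0.05, 1) - 3.841), 1e-3)
  expect_lt(abs(chi2_critical(0.5, 2) - 2 * log(2)), 1e-9)
  expect_error(chi2_critical(1.2, 3), class = "respscreen_contract_error")
  expect_error(chi2_critical(0.05, 0), class = "respscreen_contract_error")
})

test_that("feature ranking orders by H, applies the acceptance rule, and is row-order invariant", {
  n <- 30
  tab <- withr::with_seed(20, data.frame(
    label = rep(class_labels(), each = n),
    Entropy = rep(1:4, each = n) + rnorm(4 * n, sd = 0.3),   # separates
    RMScD1 = rnorm(4 * n)                                    # pure noise
  ))
  rk <- rank_features(tab)
  expect_s3_class(rk, "feature_ranking")
  expect_identical(rk$feature[1], "Entropy")
  expect_true(rk$accepted[rk$feature == "Entropy"])
  expect_equal(attr(rk, "critical"), qchisq(0.95, 3))

  shuffled <- tab[withr::with_seed(21, sample(nrow(tab))), ]
  expect_equal(as.data.frame(rank_features(shuffled)), as.data.frame(rk))

  # a constant feature has H = 0 and is never accepted
  tab$RMScD2 <- 1
  rk2 <- rank_features(tab)
  expect_equal(rk2$H[rk2$feature == "RMScD2"], 0, tolerance = 1e-9)
  expect_false(rk2$accepted[rk2$feature == "RMScD2"])

  expect_error(rank_features(tab[tab$label == "healthy", ]),
               class = "respscreen_contract_error")
})

test_that("an informative feature outranks noise in nearly all seeded replicates", {
  ok <- vapply(1:20, function(seed) {
    tab <- withr::with_seed(seed, data.frame(
      label = rep(class_labels(), each = 15),
      Entropy = rep(1:4, each = 15) + rnorm(60, sd = 0.4),
      RMScD1 = rnorm(60)))
    rk <- rank_features(tab)
    rk$feature[1] == "Entropy" && rk$accepted[rk$feature == "Entropy"] &&
      !rk$accepted[rk$feature == "RMScD1"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("incremental evaluation walks top-m subsets on a shared split", {
  tab <- toy_table(n_per_class = 12, seed = 30)
  names(tab)[2:3] <- c("Entropy", "Spec.Entropy")
  rk <- rank_features(tab)
  curve <- incremental_feature_evaluation(tab, rk, fast_config(seed = 30))
  expect_equal(nrow(curve), 2)
  expect_identical(curve$features[1], rk$feature[1])
  expect_identical(curve$features[2], paste(rk$feature[1:2], collapse = "+"))
  expect_gte(max(curve$test_accuracy), curve$test_accuracy[1])
  sel <- attr(curve, "selected")
  expect_identical(sel, rk$feature[seq_len(which.max(curve$test_accuracy))])
  expect_error(
    incremental_feature_evaluation(tab, c("Entropy", "RMScD9"),
                                   fast_config()),
    class = "respscreen_contract_error")
})

test_that("the default selected feature set is the documented 10-feature subset", {
  sel <- default_selected_features()
  expect_length(sel, 10)
  expect_true(all(sel %in% feature_names()))
  expect_false(any(c("RMScD1", "RMScD6", "RMScD7") %in% sel))
})
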