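test_that("mse matches hand-derived values and rejects shape mismatch", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_error(mse(1:3, 1:2), class = "fusedta_shape_error")
})

test_that("concordance index handles perfect, reversed and tied rankings", {
  expect_equal(concordance_index(c(1, 2, 3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(0.3, 0.2, 0.1)), 0)
  expect_equal(concordance_index(c(1, 2, 3, 4), c(1, 3, 2, 4)), 5 / 6)
  # prediction ties score one half
  expect_equal(concordance_index(c(1, 2), c(0.5, 0.5)), 0.5)
  expect_error(concordance_index(c(1, 1, 1), c(1, 2, 3)),
               class = "fusedta_undefined_metric_error")
})

test_that("concordance index agrees with the brute-force oracle and is
           invariant to monotone transforms", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(2:50, 1L)
    y <- sample(round(rnorm(n), 2))       # duplicated truth values likely
    p <- rnorm(n)
    if (length(unique(y)) < 2L) next
    expect_equal(concordance_index(y, p), oracle_ci(y, p))
    expect_equal(concordance_index(y, exp(2 * p)),    # strictly increasing
                 concordance_index(y, p))
  }
})

test_that("rm2 matches the lm-based oracle and its bounds", {
  y <- c(1, 2, 3, 4, 5)
  p <- c(1.1, 2.1, 2.9, 4.2, 4.9)
  expect_equal(rm2(y, p), oracle_rm2(y, p), tolerance = 1e-10)
  expect_equal(rm2(y, y), 1)
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(3:40, 1L)
    y <- rnorm(n); p <- 0.6 * y + rnorm(n, sd = 0.5)
    if (var(y) == 0 || var(p) == 0) next
    expect_equal(rm2(y, p), oracle_rm2(y, p), tolerance = 1e-10)
    expect_lte(rm2(y, p), cor(y, p)^2 + 1e-12)
  }
  expect_error(rm2(c(1, 1, 1), c(1, 2, 3)),
               class = "fusedta_undefined_metric_error")
})

test_that("aupr matches hand-enumerated and oracle values", {
  expect_equal(aupr(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(aupr(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 5 / 6)
  expect_equal(aupr(c(0, 1), c(0.9, 0.1)), 0.5)  # worst ranking, 1 pos
  expect_error(aupr(c(1, 1), c(0.2, 0.3)),
               class = "fusedta_undefined_metric_error")
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(2:30, 1L)
    lab <- rbinom(n, 1L, 0.4)
    if (sum(lab) %in% c(0L, n)) next
    sc <- runif(n)
    expect_equal(aupr(lab, sc), oracle_aupr(lab, sc))
  }
})

test_that("aupr of random scores approximates label prevalence", {
  set.seed(5)
  prev <- 0.3
  vals <- replicate(400, {
    lab <- rbinom(200, 1L, prev)
    if (sum(lab) %in% c(0L, 200L)) return(NA_real_)
    aupr(lab, runif(200))
  })
  expect_lt(abs(mean(vals, na.rm = TRUE) - prev), 0.05)
})

test_that("mcnemar test exact and chi-square branches behave", {
  # b = c = 5: perfectly balanced discordance, exact p = 1
  lab <- rep(1L, 10)
  pa <- c(rep(1L, 5), rep(0L, 5))
  pb <- c(rep(0L, 5), rep(1L, 5))
  r <- mcnemar_test(lab, pa, pb)
  expect_equal(r$p_value, 1)
  expect_equal(r$b, 5); expect_equal(r$c, 5)

  # b = 10, c = 0: exact two-sided p = 2 * 2^-10
  r <- mcnemar_test(rep(1L, 10), rep(1L, 10), rep(0L, 10))
  expect_equal(r$p_value, 2 * 2^-10)
  expect_equal(r$p_value, oracle_mcnemar_exact(10, 0))

  # identical prediction vectors: degenerate, p = 1 with warning
  expect_warning(r <- mcnemar_test(lab, pa, pa),
                 class = "fusedta_degenerate_warning")
  expect_equal(r$p_value, 1)

  # exact and chi-square agree closely for moderate discordance
  for (b in c(14, 16, 18)) {
    cc <- 26 - b
    lab <- rep(1L, 26)
    pa <- c(rep(1L, b), rep(0L, cc))
    pb <- c(rep(0L, b), rep(1L, cc))
    pe <- mcnemar_test(lab, pa, pb, method = "exact")$p_value
    px <- mcnemar_test(lab, pa, pb, method = "chisq")$p_value
    expect_lt(abs(pe - px), 0.02)
  }
})

test_that("evaluate_predictions assembles the full report", {
  set.seed(9)
  y <- runif(100, 5, 10)
  r <- evaluate_predictions(y, y, threshold = 7)
  expect_s3_class(r, "evaluation_report")
  expect_equal(r$mse, 0); expect_equal(r$ci, 1)
  expect_equal(r$rm2, 1); expect_equal(r$aupr, 1)
  expect_equal(r$threshold, 7); expect_equal(r$n, 100L)

  # fold-wise standard deviations; constant metric across folds -> sd 0
  fold <- rep(1:5, each = 20L)
  r2 <- evaluate_predictions(y, y, threshold = 7, fold = fold)
  expect_equal(r2$std_ci, 0)
  expect_equal(r2$std_rm2, 0)

  # constant predictions exercise the undefined-CI error path
  expect_error(evaluate_predictions(y, rep(1, 100), threshold = 7),
               class = "fusedta_undefined_metric_error")
})

test_that("evaluate_file reads a predictions CSV and write_report round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(2)
  y <- runif(50, 5, 10); p <- y + rnorm(50, sd = 0.3)
  utils::write.csv(data.frame(drug_id = "d", protein_id = paste0("p", 1:50),
                              y_true = y, y_pred = p), path,
                   row.names = FALSE)
  r <- evaluate_file(path, threshold = 7)
  expect_equal(r$mse, mse(y, p))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, out)
  kv <- read.delim(out, header = FALSE)
  expect_equal(kv$V2[kv$V1 == "ci"], r$ci, tolerance = 1e-9)
})
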