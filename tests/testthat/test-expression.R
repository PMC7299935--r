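test_that("median-of-ratios reproduces the hand-computed 2x2 example", {
  # geometric means: sqrt(2*4) = 2.828..., sqrt(6*12) = 8.485...
  # donor ratios: d1 = {2/2.828, 6/8.485} -> median 1/sqrt(2); d2 -> sqrt(2)
  m <- matrix(c(2L, 6L, 4L, 12L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("d1", "d2")))
  norm <- median_of_ratios(m)
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(norm$values),
               matrix(c(2 * sqrt(2), 6 * sqrt(2), 4 / sqrt(2), 12 / sqrt(2)),
                      nrow = 2),
               tolerance = 1e-12)
})

test_that("median-of-ratios degenerate and edge inputs", {
  one <- matrix(c(5L, 9L), nrow = 2,
                dimnames = list(c("g1", "g2"), "d1"))
  norm <- median_of_ratios(one)
  expect_equal(unname(norm$size_factors), 1)
  expect_equal(norm$values, one)

  # all-zero gene is excluded from the reference set but still normalized
  m <- matrix(c(2L, 6L, 0L, 4L, 12L, 0L), nrow = 3,
              dimnames = list(c("g1", "g2", "g0"), c("d1", "d2")))
  norm <- median_of_ratios(m)
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(norm$values["g0", ]), c(0, 0))

  zeroes <- matrix(c(0L, 1L, 1L, 0L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("d1", "d2")))
  expect_error(median_of_ratios(zeroes), "reference gene")
})

test_that("size factors recover scalar column multiples up to a constant", {
  withr::with_seed(1, {
    base <- rpois(50, 100) + 1L
    scalars <- c(0.5, 1, 2, 4)
    m <- sapply(scalars, function(s) as.integer(round(base * s)))
    dimnames(m) <- list(sprintf("g%02d", 1:50), sprintf("d%d", 1:4))
    sf <- median_of_ratios(m)$size_factors
    expect_equal(unname(sf / sf[2]), scalars, tolerance = 0.02)
    # geometric mean of size factors is 1 by construction of the reference
    expect_equal(exp(mean(log(sf))), 1, tolerance = 0.02)
  })
})

test_that("size factors agree with the reference RNA-seq implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(9, {
    m <- matrix(rnbinom(300 * 8, mu = 50, size = 5), nrow = 300,
                dimnames = list(sprintf("g%03d", 1:300),
                                sprintf("d%d", 1:8)))
    ours <- median_of_ratios(m)$size_factors
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  })
})

test_that("gene_stats uses linear-interpolation quantiles", {
  m <- rbind(
    a = c(1, 2, 3, 4, 5),
    b = c(7, 7, 7, 7, 7),
    c = c(1, 2, 3, 4, 0)
  )
  colnames(m) <- sprintf("d%d", 1:5)
  norm <- structure(list(values = m, size_factors = rep(1, 5)),
                    class = "norm_matrix")
  st <- gene_stats(norm)
  expect_equal(st$median[st$gene_id == "a"], 3)
  expect_equal(st$iqr[st$gene_id == "a"], 2)
  expect_equal(st$iqr[st$gene_id == "b"], 0)

  st4 <- gene_stats(norm, donor_scope = c("d1", "d2", "d3", "d4"))
  expect_equal(st4$median[st4$gene_id == "a"], 2.5)
  expect_equal(st4$iqr[st4$gene_id == "a"], 3.25 - 1.75)
  expect_equal(st4$n_donors_used, rep(4, 3))

  expect_error(gene_stats(norm, donor_scope = c("d1", "d2", "d3")),
               "at least 4")
  expect_error(gene_stats(norm, donor_scope = c("d1", "d2", "d3", "dX")),
               "unknown")
})

test_that("gene_stats agrees with a sort-and-interpolate oracle", {
  withr::with_seed(21, {
    for (rep in 1:500) {
      n <- sample(4:30, 1)
      x <- round(runif(n, 0, 100), 2)
      m <- matrix(x, nrow = 1, dimnames = list("g", sprintf("d%02d", 1:n)))
      norm <- structure(list(values = m, size_factors = rep(1, n)),
                        class = "norm_matrix")
      st <- gene_stats(norm)
      expect_equal(st$median, quantile_oracle(x, 0.5))
      expect_equal(st$iqr,
                   quantile_oracle(x, 0.75) - quantile_oracle(x, 0.25))
    }
  })
})

make_norm <- function(values_row, gene = "g1") {
  m <- matrix(values_row, nrow = 1,
              dimnames = list(gene, sprintf("d%d", seq_along(values_row))))
  structure(list(values = m, size_factors = rep(1, length(values_row))),
            class = "norm_matrix")
}

test_that("outlier thresholds are strict and gated by the expression floor", {
  st <- tibble::tibble(gene_id = "g1", median = 10, iqr = 2,
                       n_donors_used = 5)
  # deviation 2.5 -> primary; deviation exactly 2.0 -> recurrence only;
  # deep downregulation below the floor -> nothing
  oc <- call_outliers(make_norm(c(15, 14, 5)), st)
  expect_equal(oc$deviation_iqr, c(2.5, 2.0, -2.5))
  expect_equal(oc$passes_primary, c(TRUE, FALSE, FALSE))
  expect_equal(oc$passes_recurrence, c(TRUE, TRUE, FALSE))

  low <- call_outliers(make_norm(5), tibble::tibble(
    gene_id = "g1", median = 100, iqr = 10, n_donors_used = 5))
  expect_equal(low$deviation_iqr, -9.5)
  expect_false(low$passes_primary)
  expect_false(low$passes_recurrence)
})

test_that("zero-IQR genes use the documented +/-Inf convention", {
  st <- tibble::tibble(gene_id = "g1", median = 20, iqr = 0,
                       n_donors_used = 5)
  oc <- call_outliers(make_norm(c(20, 25, 15)), st)
  expect_equal(oc$deviation_iqr, c(0, Inf, -Inf))
  expect_equal(oc$passes_primary, c(FALSE, TRUE, TRUE))
})

test_that("directional mode only passes upregulation", {
  st <- tibble::tibble(gene_id = "g1", median = 100, iqr = 10,
                       n_donors_used = 5)
  oc <- call_outliers(make_norm(c(150, 50)), st, directional = TRUE)
  expect_equal(oc$passes_primary, c(TRUE, FALSE))
})

test_that("outlier calling is donor-order invariant and monotone in k", {
  withr::with_seed(5, {
    vals <- round(runif(12, 0, 100))
    norm <- make_norm(vals)
    st <- gene_stats(norm)
    oc <- call_outliers(norm, st, k_primary = 1.5)
    perm <- sample(ncol(norm$values))
    norm_p <- structure(
      list(values = norm$values[, perm, drop = FALSE],
           size_factors = norm$size_factors[perm]),
      class = "norm_matrix")
    oc_p <- call_outliers(norm_p, gene_stats(norm_p), k_primary = 1.5)
    expect_equal(dplyr::arrange(oc, donor_id), dplyr::arrange(oc_p, donor_id))

    counts <- sapply(c(0.5, 1, 1.5, 2, 3), function(k) {
      sum(call_outliers(norm, st, k_primary = k, k_recurrence = 0)$passes_primary)
    })
    expect_true(all(diff(counts) <= 0))
  })
})
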