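# Expression stage: median-of-ratios normalization and per-gene
# median/IQR outlier statistics over the donor cohort.

#' Median-of-ratios count normalization
#'
#' Computes per-donor size factors as the median, over reference genes, of
#' the ratio of the donor's count to the gene's geometric mean across
#' donors; reference genes are those with a strictly positive count in
#' every donor. Normalized expression is the raw count divided by the
#' donor's size factor. This is the size-factor normalization used by
#' standard RNA-seq differential-expression workflows.
#'
#' @param counts Non-negative integer matrix, genes x donors, with
#'   dimnames.
#' @return Object of class `norm_matrix`: list with `values` (normalized
#'   matrix, same shape as `counts`) and `size_factors` (named positive
#'   vector, one per donor).
#' @export
#' @examples
#' m <- matrix(c(2, 6, 4, 12), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("d1", "d2")))
#' median_of_ratios(m)$size_factors
median_of_ratios <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) abort("Counts must be non-negative.")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    abort(paste("No reference gene with positive counts in every donor;",
                "pseudo-reference fallback is off."))
  }
  log_geo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  structure(
    list(values = sweep(counts, 2, sf, "/"), size_factors = sf),
    class = "norm_matrix"
  )
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d genes x %d donors\n",
              nrow(x$values), ncol(x$values)))
  cat("size factors: ", paste(sprintf("%.3f", head(x$size_factors, 6)),
                              collapse = ", "),
      if (length(x$size_factors) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn median_of_ratios Long-tibble view of a normalized matrix
#'   (`gene_id`, `donor_id`, `value`).
#' @param x A `norm_matrix`.
#' @param ... Unused.
#' @export
tidy.norm_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "donor_id",
                        values_to = "value")
}

#' Per-gene median and interquartile range
#'
#' Median and IQR (Q3 - Q1, quantiles by linear interpolation of order
#' statistics) of normalized expression per gene, computed over a declared
#' donor scope — by convention the donors for which structural-variant
#' data is available.
#'
#' @param norm A `norm_matrix` from [median_of_ratios()].
#' @param donor_scope Character vector of donor ids to use; `NULL` means
#'   all donors in the matrix. Must contain at least 4 donors.
#' @return Tibble with `gene_id`, `median`, `iqr`, `n_donors_used`.
#' @export
gene_stats <- function(norm, donor_scope = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  donors <- colnames(norm$values)
  if (is.null(donor_scope)) donor_scope <- donors
  missing <- setdiff(donor_scope, donors)
  if (length(missing)) {
    abort(sprintf("Donor scope contains unknown donors: %s",
                  toString(head(missing, 5))))
  }
  if (length(donor_scope) < 4) {
    abort("Donor scope must contain at least 4 donors.")
  }
  v <- norm$values[, donor_scope, drop = FALSE]
  q <- t(apply(v, 1, quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE, type = 7))
  tibble(
    gene_id = rownames(v),
    median = unname(q[, 2]),
    iqr = unname(q[, 3] - q[, 1]),
    n_donors_used = length(donor_scope)
  )
}

#' Call per-donor expression outliers in IQR units
#'
#' Each donor's deviation from the gene median is expressed in IQR units:
#' `deviation_iqr = (value - median) / iqr`. A donor passes the primary
#' filter when `|deviation_iqr| > k_primary` and its normalized value
#' exceeds `min_norm_expr` (both strict); the recurrence filter uses
#' `k_recurrence` with the same expression floor. With `directional =
#' TRUE` only positive deviations (upregulation) count. When a gene's IQR
#' is zero the deviation is `+/-Inf` for values off the median and 0 at
#' the median.
#'
#' @param norm A `norm_matrix`.
#' @param stats Tibble from [gene_stats()]; must cover every gene scored.
#' @param k_primary,k_recurrence Outlier thresholds in IQR units.
#' @param min_norm_expr Expression floor applied to the donor's value.
#' @param directional If `TRUE`, only upregulation passes.
#' @param genes Optional subset of gene ids to score (default: all genes
#'   in `stats`).
#' @return Tibble with `gene_id`, `donor_id`, `normalized_value`,
#'   `deviation_iqr`, `passes_primary`, `passes_recurrence`.
#' @export
call_outliers <- function(norm, stats, k_primary = 2, k_recurrence = 1,
                          min_norm_expr = 10, directional = FALSE,
                          genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"), is.data.frame(stats))
  if (k_primary < k_recurrence) {
    abort("Need k_primary >= k_recurrence.")
  }
  if (is.null(genes)) genes <- stats$gene_id
  missing <- setdiff(genes, stats$gene_id)
  if (length(missing)) {
    abort(sprintf("No gene stats for: %s", toString(head(missing, 5))))
  }
  missing_mat <- setdiff(genes, rownames(norm$values))
  if (length(missing_mat)) {
    abort(sprintf("Genes absent from matrix: %s",
                  toString(head(missing_mat, 5))))
  }
  long <- as_tibble(norm$values[genes, , drop = FALSE],
                    rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "donor_id",
                        values_to = "normalized_value") |>
    left_join(stats[c("gene_id", "median", "iqr")], by = "gene_id")
  dev <- (long$normalized_value - long$median) / long$iqr
  zero <- long$iqr == 0
  dev[zero] <- sign(long$normalized_value[zero] - long$median[zero]) * Inf
  dev[zero & long$normalized_value == long$median] <- 0
  eff <- if (directional) dev else abs(dev)
  long |>
    mutate(
      deviation_iqr = dev,
      passes_primary = eff > .env$k_primary &
        .data$normalized_value > .env$min_norm_expr,
      passes_recurrence = eff > .env$k_recurrence &
        .data$normalized_value > .env$min_norm_expr
    ) |>
    select(-"median", -"iqr")
}
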