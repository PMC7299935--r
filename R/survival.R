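# Survival stage: median-split Kaplan-Meier / log-rank screen with
# Benjamini-Hochberg correction. Estimation and testing are delegated to
# the survival package; this module fixes the split and family
# conventions of the screen.

#' Split donors at the median expression value
#'
#' Donors strictly above the median go to the high group; ties at the
#' median go to the low group. At least 4 donors are required, and a
#' constant vector (empty high group) is an error.
#'
#' @param expr_values Tibble with `donor_id` and `value` columns.
#' @return The input with a `group` column (`"high"`/`"low"`).
#' @export
#' @examples
#' median_split(tibble::tibble(donor_id = LETTERS[1:4], value = 1:4))
median_split <- function(expr_values) {
  stopifnot(is.data.frame(expr_values))
  if (nrow(expr_values) < 4) abort("Need at least 4 donors to split.")
  med <- median(expr_values$value)
  grp <- ifelse(expr_values$value > med, "high", "low")
  if (!any(grp == "high")) {
    abort("Degenerate split: no donor above the median (constant values?).")
  }
  expr_values |> mutate(group = grp)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function; censored donors
#' leave the risk set without a survival drop. A time-0 row with
#' survival 1 is prepended so the curve starts at `S(0) = 1`.
#'
#' @param records Tibble with `time` (non-negative) and `event` (0/1)
#'   columns.
#' @return Tibble of class `km_tbl`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (right-continuous step function).
#' @export
km_estimate <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) abort("Need at least one record.")
  if (any(records$time < 0)) abort("Survival times must be >= 0.")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = records, conf.type = "none"
  )
  out <- tibble(
    time = c(0, fit$time),
    n_risk = c(nrow(records), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv)
  )
  class(out) <- c("km_tbl", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic,
#' `chi2 = (sum O - sum E)^2 / sum V`, referred to a chi-square
#' distribution with 1 df; no continuity correction. Requires both
#' groups non-empty and at least one observed event.
#'
#' @param records Tibble with `time`, `event` and `group` columns
#'   (exactly two group levels).
#' @return One-row tibble: `chi2`, `p`, `n_a`, `n_b`, `n_events`.
#' @export
logrank <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "group") %in% names(records)))
  groups <- unique(records$group)
  if (length(groups) != 2) abort("Exactly two groups are required.")
  if (sum(records$event) == 0) {
    abort("Log-rank test undefined with zero events.")
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = records, rho = 0
  )
  chi2 <- unname(sd$chisq)
  tibble(
    chi2 = chi2,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    n_a = sum(records$group == groups[1]),
    n_b = sum(records$group == groups[2]),
    n_events = sum(records$event)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1; input order is preserved. Inputs must lie in (0, 1].
#'
#' @param pvals Numeric vector of p-values.
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Median-split survival screen over candidate genes
#'
#' For each candidate gene, donors present in both the expression matrix
#' and the survival table are split at the median expression value —
#' within each cohort separately by default (cohorts may use different
#' expression platforms), or pooled with `config$pooled_split` — and the
#' pooled high/low groups are compared by log-rank test. BH correction is
#' applied over exactly the genes tested, and a gene is flagged
#' significant below `config$padj_threshold`. Genes absent from the
#' matrix, or with a degenerate split, are skipped with a warning; donors
#' lacking expression or survival data are dropped (counts reported via
#' a message).
#'
#' @param candidates Candidate tibble from [call_candidates()] (any
#'   tibble with a `gene_id` column works).
#' @param norm A `norm_matrix`, or a named list of `norm_matrix` objects
#'   keyed by cohort label for multi-platform cohorts.
#' @param survival_records Tibble from [read_survival()].
#' @param config A [pipeline_config()].
#' @return `candidates` with `n_high`, `n_low`, `chi2`, `p`, `padj`,
#'   `significant` columns appended (NA for skipped genes).
#' @export
survival_screen <- function(candidates, norm, survival_records,
                            config = pipeline_config()) {
  stopifnot(is.data.frame(candidates), is.data.frame(survival_records),
            inherits(config, "hijack_config"))
  if (nrow(candidates) == 0) {
    return(candidates |>
             mutate(n_high = integer(), n_low = integer(), chi2 = numeric(),
                    p = numeric(), padj = numeric(), significant = logical()))
  }
  mats <- if (inherits(norm, "norm_matrix")) {
    setNames(list(norm), unique(survival_records$cohort)[1])
  } else {
    norm
  }
  expr_of <- function(gene) {
    purrr::imap_dfr(mats, function(m, cohort_label) {
      if (!gene %in% rownames(m$values)) return(NULL)
      tibble(donor_id = colnames(m$values),
             value = m$values[gene, ],
             expr_cohort = cohort_label)
    })
  }

  donors_with_expr <- unique(unlist(purrr::map(mats,
                                               ~ colnames(.x$values))))
  n_dropped <- sum(!survival_records$donor_id %in% donors_with_expr)
  if (n_dropped > 0) {
    inform(sprintf(
      "survival_screen: %d survival donor(s) lack expression data",
      n_dropped))
  }

  results <- purrr::map_dfr(candidates$gene_id, function(gene) {
    na_row <- tibble(gene_id = gene, n_high = NA_integer_,
                     n_low = NA_integer_, chi2 = NA_real_, p = NA_real_)
    ev <- expr_of(gene)
    if (nrow(ev) == 0) {
      warn(sprintf("survival_screen: gene %s absent from expression data; skipped",
                   gene))
      return(na_row)
    }
    dat <- survival_records |>
      inner_join(ev, by = "donor_id")
    if (nrow(dat) < 4 || sum(dat$event) == 0) return(na_row)
    split_key <- if (config$pooled_split) "pooled" else dat$cohort
    dat <- dat |>
      mutate(.split = split_key) |>
      group_by(.data$.split) |>
      group_modify(function(d, key) {
        if (nrow(d) < 4 || length(unique(d$value)) == 1) {
          return(d |> mutate(group = NA_character_))
        }
        median_split(d |> rename(value = "value"))
      }) |>
      ungroup() |>
      filter(!is.na(.data$group))
    if (length(unique(dat$group)) != 2 || sum(dat$event) == 0) {
      warn(sprintf("survival_screen: degenerate split for gene %s; skipped",
                   gene))
      return(na_row)
    }
    lr <- logrank(dat)
    tibble(gene_id = gene,
           n_high = sum(dat$group == "high"),
           n_low = sum(dat$group == "low"),
           chi2 = lr$chi2, p = lr$p)
  })

  tested <- !is.na(results$p)
  results$padj <- NA_real_
  if (any(tested)) results$padj[tested] <- bh_adjust(results$p[tested])
  results$significant <- !is.na(results$padj) &
    results$padj < config$padj_threshold
  candidates |> left_join(results, by = "gene_id")
}
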