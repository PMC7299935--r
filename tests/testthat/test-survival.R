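test_that("median split sends ties to the low group", {
  ev4 <- tibble::tibble(donor_id = c("A", "B", "C", "D"), value = 1:4)
  sp <- median_split(ev4)
  expect_setequal(sp$donor_id[sp$group == "high"], c("C", "D"))
  expect_setequal(sp$donor_id[sp$group == "low"], c("A", "B"))

  ev5 <- tibble::tibble(donor_id = c("A", "B", "C", "D", "E"),
                        value = c(1, 2, 2, 3, 4))
  sp <- median_split(ev5)  # median 2: B and C tie -> low
  expect_setequal(sp$donor_id[sp$group == "high"], c("D", "E"))

  expect_error(median_split(ev4[1:3, ]), "at least 4")
  expect_error(
    median_split(tibble::tibble(donor_id = c("A", "B", "C", "D"),
                                value = rep(7, 4))),
    "Degenerate"
  )
})

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  none <- km_estimate(tibble::tibble(time = c(5, 8, 10, 20, 30),
                                     event = 0))
  expect_true(all(none$survival == 1))

  one <- km_estimate(tibble::tibble(time = c(10, 12, 15, 20),
                                    event = c(1, 0, 0, 0)))
  expect_equal(one$survival[one$time == 10], 0.75)

  # events at 1 and 2 with a censor at 1.5 among n = 3:
  # S(1) = 2/3, then risk set = 1, S(2) = (2/3) * (1 - 1/1) = 0
  km <- km_estimate(tibble::tibble(time = c(1, 1.5, 2),
                                   event = c(1, 0, 1)))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 2], 0)

  expect_true(all(diff(km$survival) <= 0))  # non-increasing
  expect_equal(km$survival[km$time == 0], 1)

  expect_error(km_estimate(tibble::tibble(time = -1, event = 1)), ">= 0")
})

test_that("log-rank matches the hand O/E/V table and is label-symmetric", {
  # A: events at 1, 2; B: events at 3, 4 (no censoring)
  # t=1: E_A = 0.5, V = 2*2*1*3/(16*3) = 0.25
  # t=2: E_A = 1/3, V = 1*2*1*2/(9*2)  = 2/9
  # O_A = 2, E_A = 5/6, V = 0.25 + 2/9 -> chi2 = (7/6)^2 / (17/36)
  rec <- tibble::tibble(time = c(1, 2, 3, 4), event = 1,
                        group = c("A", "A", "B", "B"))
  lr <- logrank(rec)
  chi2_hand <- (7 / 6)^2 / (17 / 36)
  expect_equal(lr$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(chi2_hand, 1, lower.tail = FALSE))

  oracle <- logrank_oracle(rec$time, rec$event, rec$group == "A")
  expect_equal(lr$chi2, oracle$chi2, tolerance = 1e-12)

  swapped <- rec |> dplyr::mutate(group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank(swapped)$chi2, lr$chi2)

  same <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1,
                         group = rep(c("A", "B"), each = 3))
  lr0 <- logrank(same)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  expect_error(
    logrank(tibble::tibble(time = 1:4, event = 0,
                           group = c("A", "A", "B", "B"))),
    "zero events"
  )
})

test_that("log-rank agrees with the hand oracle on random censored data", {
  withr::with_seed(44, {
    for (rep in 1:25) {
      n <- sample(10:40, 1)
      rec <- tibble::tibble(
        time = round(rexp(n, 0.01), 1),
        event = rbinom(n, 1, 0.7),
        group = sample(c("A", "B"), n, replace = TRUE)
      )
      if (sum(rec$event) == 0 || length(unique(rec$group)) < 2) next
      oracle <- logrank_oracle(rec$time, rec$event, rec$group == "A")
      expect_equal(logrank(rec)$chi2, oracle$chi2, tolerance = 1e-8)
    }
  })
})

test_that("BH adjustment matches the direct step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  withr::with_seed(3, {
    for (rep in 1:100) {
      p <- runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p))
      expect_true(all(adj >= p & adj <= 1))
    }
  })
})

test_that("survival screen flags a strong planted hazard effect", {
  cfg <- sim_config(seed = 101, n_donors = 200, n_genes = 50,
                    n_interactions = 25, n_breakpoints = 100,
                    n_planted_genes = 1, hazard_ratio = 3,
                    censoring_fraction_target = 0.2)
  sim <- simulate_cohort(cfg)
  cands <- tibble::tibble(gene_id = c(sim$truth$survival_gene, "G0049"))
  res <- survival_screen(cands, sim$norm, sim$survival,
                         pipeline_config())
  hit <- res[res$gene_id == sim$truth$survival_gene, ]
  expect_lt(hit$p, 0.05)
  expect_equal(hit$n_high + hit$n_low, 200)
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
})

test_that("survival screen handles empty input and missing genes", {
  sim <- simulate_cohort(sim_config(seed = 5, n_donors = 20, n_genes = 30,
                                    n_interactions = 15,
                                    n_breakpoints = 40))
  empty <- survival_screen(tibble::tibble(gene_id = character()),
                           sim$norm, sim$survival, pipeline_config())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p", "padj", "significant") %in% names(empty)))

  expect_warning(
    res <- survival_screen(tibble::tibble(gene_id = "NOT_A_GENE"),
                           sim$norm, sim$survival, pipeline_config()),
    "absent"
  )
  expect_true(is.na(res$p))
})
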