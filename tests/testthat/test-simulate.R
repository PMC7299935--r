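small_cfg <- function(seed = 1, n_planted_genes = 3, ...) {
  sim_config(seed = seed, n_donors = 20, n_genes = 60, n_interactions = 30,
             n_breakpoints = 60, n_planted_genes = n_planted_genes, ...)
}

test_that("the generator is bit-for-bit reproducible under a seed", {
  s1 <- simulate_cohort(small_cfg(seed = 99))
  s2 <- simulate_cohort(small_cfg(seed = 99))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  s3 <- simulate_cohort(small_cfg(seed = 100))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("interactome layout is non-overlapping with shared anchors", {
  cfg <- small_cfg()
  pi <- simulate_interactome(cfg)
  expect_equal(nrow(pi), cfg$n_interactions)
  expect_true(all(lengths(pi$gene_ids) == 2))
  expect_true(all(pi$bait_end <= pi$pir_start))
  # fragments on one chromosome never overlap
  frags <- dplyr::bind_rows(
    tibble::tibble(chrom = pi$bait_chrom, start = pi$bait_start,
                   end = pi$bait_end),
    tibble::tibble(chrom = pi$pir_chrom, start = pi$pir_start,
                   end = pi$pir_end)
  ) |> dplyr::arrange(chrom, start)
  by_chrom <- split(frags, frags$chrom)
  for (fr in by_chrom) {
    expect_true(all(fr$start[-1] >= fr$end[-nrow(fr)]))
  }

  none <- simulate_interactome(sim_config(n_interactions = 0))
  expect_equal(nrow(none), 0)

  expect_error(simulate_interactome(sim_config(chrom_length = 1000)),
               "chrom_length")
})

test_that("planted breakpoints map to their gene; background maps nowhere", {
  sim <- simulate_cohort(small_cfg(seed = 4))
  ev <- map_disruptions(sim$breakpoints, sim$interactome, flank_bp = 50,
                        mode = "anchor")
  hits <- dplyr::semi_join(sim$truth$planted, ev,
                           by = c("gene_id", "donor_id"))
  expect_equal(nrow(hits), nrow(sim$truth$planted))

  bg_only <- simulate_cohort(small_cfg(seed = 4, n_planted_genes = 0))
  ev_bg <- map_disruptions(bg_only$breakpoints, bg_only$interactome,
                           flank_bp = 50, mode = "anchor")
  expect_equal(nrow(ev_bg), 0)
})

test_that("breakpoint counts and donors are preserved at cohort scale", {
  cfg <- sim_config(seed = 2, n_donors = 92, n_genes = 200,
                    n_interactions = 100, n_breakpoints = 750,
                    n_planted_genes = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$breakpoints), 750)
  expect_true(all(sim$breakpoints$donor_id %in% sprintf("D%03d", 1:92)))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_equal(nrow(read_breakpoints(file.path(dir, "breakpoints.tsv"))),
               750)
})

test_that("counts follow the configured negative-binomial means", {
  cfg <- sim_config(seed = 31, n_donors = 20, n_genes = 200,
                    n_interactions = 0, n_breakpoints = 0,
                    n_planted_genes = 0, nb_dispersion = 0.1)
  truth <- plant_truth(cfg, simulate_interactome(cfg))
  counts <- simulate_counts(cfg, truth)
  mu <- outer(attr(counts, "baseline_means"), attr(counts, "size_factors"))
  ratio <- counts / mu
  # each entry has mean 1 and variance alpha + 1/mu; compare the grand
  # mean of 4,000 draws against 3 standard errors
  se <- sqrt(sum(cfg$nb_dispersion + 1 / mu)) / length(mu)
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("the low-dispersion limit approaches Poisson", {
  cfg <- sim_config(seed = 32, n_donors = 400, n_genes = 3,
                    n_interactions = 0, n_breakpoints = 0,
                    n_planted_genes = 0, nb_dispersion = 1e-8,
                    size_factor_range = c(1, 1),
                    baseline_mean_range = c(200, 200))
  counts <- simulate_counts(cfg, plant_truth(cfg, simulate_interactome(cfg)))
  vmr <- apply(counts, 1, var) / rowMeans(counts)
  expect_equal(mean(vmr), 1, tolerance = 0.25)
})

test_that("planted pairs receive the multiplicative effect", {
  cfg <- small_cfg(seed = 6, effect_multiplier = 8)
  sim <- simulate_cohort(cfg)
  planted <- sim$truth$planted
  q <- attr(sim$counts, "baseline_means")
  sf <- attr(sim$counts, "size_factors")
  obs <- sim$counts[cbind(planted$gene_id, planted$donor_id)]
  expected <- 8 * q[planted$gene_id] * sf[planted$donor_id]
  # with alpha = 0.1 an 8x effect keeps draws far above the baseline mean
  expect_true(all(obs > q[planted$gene_id] * sf[planted$donor_id]))
  expect_equal(mean(obs / expected), 1, tolerance = 0.5)
})

test_that("survival generator honors censoring settings and groups", {
  cfg <- sim_config(seed = 12, n_donors = 400, n_genes = 20,
                    n_interactions = 10, n_breakpoints = 40,
                    n_planted_genes = 1, censoring_fraction_target = 0)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$survival$event == 1))

  cfg30 <- sim_config(seed = 12, n_donors = 400, n_genes = 20,
                      n_interactions = 10, n_breakpoints = 40,
                      n_planted_genes = 1,
                      censoring_fraction_target = 0.3)
  sim30 <- simulate_cohort(cfg30)
  frac <- mean(sim30$survival$event == 0)
  # binomial 3-sigma band around the calibrated target
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 400))

  groups <- attr(sim30$survival, "groups")
  expect_equal(sort(table(groups$group), decreasing = TRUE)[[1]], 200)
})
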