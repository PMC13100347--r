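test_that("zero TIL rates produce no TIL tiles; labels stay exclusive", {
  cfg <- recovery_config(itil_rate = c(0, 0), stil_rate = c(0, 0))
  tta <- simulate_tta_image(cfg, group = 1L, seed = 1L)
  expect_equal(nrow(extract_compartment(tta, "TIL")), 0L)
  # |TIL| = |ITIL| + |STIL| under the default rates
  tta2 <- simulate_tta_image(recovery_config(), 1L, seed = 2L)
  expect_equal(nrow(extract_compartment(tta2, "TIL")),
               nrow(extract_compartment(tta2, "ITIL")) +
                 nrow(extract_compartment(tta2, "STIL")))
})

test_that("tile maps are reproducible by seed and vary across seeds", {
  cfg <- recovery_config()
  a <- simulate_tta_image(cfg, 0L, seed = 5L)
  b <- simulate_tta_image(cfg, 0L, seed = 5L)
  d <- simulate_tta_image(cfg, 0L, seed = 6L)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, d$grid))
})

test_that("central-tile tumor coverage matches its closed-form rate", {
  # single disc of radius r placed uniformly on the interior rectangle:
  # P(center tile in tumor) = pi r^2 / placement area, valid because the
  # radius-r disc around the central tile lies inside the placement region
  cfg <- sim_config(grid_rows = 40L, grid_cols = 40L, tumor_seed_count = 1L,
                    tumor_disc_radius = 5, stroma_band = 3)
  m <- 5 + 3 + 1
  p_true <- pi * 25 / (40 - 2 * m)^2
  hits <- 0L
  for (s in 1:200) {
    tta <- simulate_tta_image(cfg, group = 0L, seed = 4000L + s)
    hits <- hits + (tta$grid[20, 20] %in% c("T", "N", "I"))
  }
  band <- 2.576 * sqrt(p_true * (1 - p_true) / 200)
  expect_gte(hits / 200, p_true - band)
  expect_lte(hits / 200, p_true + band)
})

test_that("embeddings have the configured dimension and planted
           separability", {
  cfg <- recovery_config(embedding_effect = 4)
  tta0 <- simulate_tta_image(cfg, 0L, seed = 7L)
  tta1 <- simulate_tta_image(cfg, 1L, seed = 8L)
  e0 <- simulate_embeddings(tta0, 0L, cfg, seed = 9L)
  e1 <- simulate_embeddings(tta1, 1L, cfg, seed = 10L)
  expect_equal(ncol(e0$matrix), 1024L)
  expect_equal(nrow(e0$matrix), nrow(e0$index))
  # a linear rule on the class-mean direction separates at >= 0.95
  s0 <- e0$matrix[e0$index$compartment == "STROMA", ]
  s1 <- e1$matrix[e1$index$compartment == "STROMA", ]
  u <- colMeans(s1) - colMeans(s0)
  proj <- c(s0 %*% u, s1 %*% u)
  y <- rep(c(0, 1), c(nrow(s0), nrow(s1)))
  acc <- max(mean((proj > mean(proj)) == y), mean((proj < mean(proj)) == y))
  expect_gte(acc, 0.95)
})

test_that("a zero embedding effect leaves group means together", {
  cfg <- recovery_config(embedding_effect = 0)
  tta0 <- simulate_tta_image(cfg, 0L, seed = 11L)
  tta1 <- simulate_tta_image(cfg, 1L, seed = 12L)
  e0 <- simulate_embeddings(tta0, 0L, cfg, seed = 13L)
  e1 <- simulate_embeddings(tta1, 1L, cfg, seed = 14L)
  gap <- sqrt(sum((colMeans(e0$matrix) - colMeans(e1$matrix))^2))
  # chance-level gap for d-dim isotropic noise is sqrt(d (1/n0 + 1/n1));
  # allow 30% slack, far below what any planted shift would add
  null_gap <- sqrt(1024 * (1 / nrow(e0$matrix) + 1 / nrow(e1$matrix)))
  expect_lt(gap, 1.3 * null_gap)
})

test_that("clinical records follow the response conventions", {
  cfg <- recovery_config()
  pcr <- simulate_clinical(1L, cfg, seed = 15L)
  expect_equal(pcr$ris_cm, 0)
  expect_equal(pcr$pcr, 1L)
  non <- simulate_clinical(0L, cfg, seed = 16L)
  expect_gt(non$ris_cm, 0)
  expect_true(all(c(non$cep17, non$her2_cep17_ratio) > 0))
  expect_true(non$er_status %in% c(0L, 1L))
})

test_that("the HER2/CEP17 ratio shift is detectable at cohort scale", {
  coh <- simulate_cohort(150L, recovery_config(), seed = 17L)
  clin <- cohort_clinical(coh)
  p <- suppressWarnings(stats::wilcox.test(
    her2_cep17_ratio ~ pcr, data = clin, exact = FALSE)$p.value)
  expect_lt(p, 0.05)
  expect_gt(median(clin$her2_cep17_ratio[clin$pcr == 1]),
            median(clin$her2_cep17_ratio[clin$pcr == 0]))
})

test_that("residual infiltration couples to the TIL-dispersion latent", {
  # non-responders with more dispersed TILs carry larger residual lesions
  cfg <- recovery_config()
  set.seed(18)
  disp <- exp(stats::rnorm(60, 0, 0.4))
  ris <- vapply(seq_along(disp), function(i)
    simulate_clinical(0L, cfg, seed = 200L + i,
                      dispersion_factor = disp[i])$ris_cm, numeric(1))
  expect_gt(spearman_with_ris(disp, ris)$rho, 0.3)
})

test_that("cohort labels follow the configured prevalence", {
  coh <- simulate_cohort(50L, recovery_config(), seed = 19L)
  n_pcr <- sum(cohort_labels(coh))
  band <- stats::qbinom(c(0.005, 0.995), 50L, 0.42)
  expect_gte(n_pcr, band[1]); expect_lte(n_pcr, band[2])
  expect_equal(unname(cohort_labels(coh)),
               cohort_clinical(coh)$pcr)
})

test_that("cohorts round-trip through their disk formats", {
  cfg <- sim_config(grid_rows = 16L, grid_cols = 16L,
                    tumor_seed_count = 1L, tumor_disc_radius = 3,
                    stroma_band = 2)
  coh <- simulate_cohort(10L, cfg, seed = 20L, with_embeddings = TRUE)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$patients), names(coh$patients))
  for (pid in names(coh$patients)) {
    expect_identical(back$patients[[pid]]$tta$grid,
                     coh$patients[[pid]]$tta$grid)
    expect_equal(back$patients[[pid]]$embeddings$matrix,
                 coh$patients[[pid]]$embeddings$matrix,
                 tolerance = 1e-9)
    expect_equal(back$patients[[pid]]$clinical$her2_cep17_ratio,
                 coh$patients[[pid]]$clinical$her2_cep17_ratio,
                 tolerance = 1e-9)
  }
  expect_equal(unname(cohort_labels(back)), unname(cohort_labels(coh)))
})

test_that("different cohort seeds give disjoint patient ids", {
  a <- simulate_cohort(12L, recovery_config(), seed = 1L)
  b <- simulate_cohort(12L, recovery_config(), seed = 2L)
  expect_length(intersect(names(a$patients), names(b$patients)), 0L)
})
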