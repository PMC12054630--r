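# synthetic-data module: determinism, null behaviour, NB moment identity,
# homolog map saturation, clinical generator calibration, serialization.

small_cfg <- function(...) {
  sim_config(n_genes = 60, n_cells_per_group = 50, n_planted = 10, ...)
}

test_that("simulation is deterministic given the seed and validates config", {
  cfg <- small_cfg(seed = 7)
  a1 <- simulate_species(cfg, "mouse")
  a2 <- simulate_species(cfg, "mouse")
  expect_identical(a1$counts, a2$counts)
  expect_identical(a1$meta, a2$meta)
  expect_identical(a1$truth$stress, a2$truth$stress)
  # a different stage gives independent noise
  b <- simulate_species(cfg, "mouse", stage = 2L)
  expect_false(identical(a1$counts, b$counts))

  expect_error(sim_config(n_genes = 10, n_planted = 10), "n_planted")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(homolog_fraction = 1.2), "homolog_fraction")
})

test_that("counts are nonnegative integers with matching labels", {
  d <- simulate_species(small_cfg(seed = 3), "mouse")
  expect_true(all(d$counts@x >= 0))
  expect_true(all(d$counts@x == round(d$counts@x)))
  expect_identical(colnames(d$counts), d$meta$barcode)
  expect_false(anyDuplicated(rownames(d$counts)) > 0)
  expect_setequal(unique(d$meta$cell_type), c("CM", "FB", "EC"))
})

test_that("effect_size = 0 yields null anchor correlations for planted genes", {
  # 2000 CM cells per replicate (the contract needs >= 1000; the larger n
  # keeps the per-gene sampling tail of rho well inside +/- 0.1). A realistic
  # gene count matters too: with very few genes each gene dominates its own
  # cell total and CP10K's shared denominator induces compositional
  # correlation of ~0.1 even without signal.
  reps <- 20
  per_rep <- sapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_genes = 300, n_cells_per_group = 1000,
                      cell_types = "CM", n_planted = 10,
                      effect_size = 0, seed = 100 + r)
    d <- simulate_species(cfg, "mouse")
    norm <- lognormalize(d$counts)
    m <- as.matrix(norm)
    av <- m["Nppa", ]
    rhos <- apply(m[d$truth$planted_genes, , drop = FALSE], 1,
                  function(g) cor(rank(g), rank(av)))
    expect_true(all(abs(rhos) < 0.1))
    mean(rhos)
  })
  expect_lt(abs(mean(per_rep)), 0.03)
})

test_that("counts follow the NB moment identity v = m + phi m^2", {
  phi <- 0.4
  cfg <- sim_config(n_genes = 15, n_cells_per_group = 5000,
                    cell_types = "CM", conditions = c("control", "stressed"),
                    n_planted = 0, effect_size = 0, dispersion = phi,
                    libsize_sigma = 0,     # fixed library factor L = 1
                    baseline_logmean_range = c(0.5, 2.5), seed = 11)
  d <- simulate_species(cfg, "mouse")
  m <- as.matrix(d$counts)        # 10,000 cells per gene
  means <- rowMeans(m)
  vars <- apply(m, 1, var)
  expected <- means + phi * means^2
  expect_true(all(abs(vars - expected) / expected < 0.15))
})

test_that("anchor-planted correlation is monotone in effect_size", {
  effs <- c(0, 0.5, 1.0, 2.0)
  mean_rho <- sapply(effs, function(e) {
    cfg <- sim_config(n_genes = 40, n_cells_per_group = 300,
                      cell_types = "CM", n_planted = 10,
                      effect_size = e, seed = 5)  # common random numbers
    d <- simulate_species(cfg, "mouse")
    m <- as.matrix(lognormalize(d$counts))
    av <- rank(m["Nppa", ])
    mean(apply(m[d$truth$planted_genes, , drop = FALSE], 1,
               function(g) cor(rank(g), av)))
  })
  expect_true(all(diff(mean_rho) >= 0))
})

test_that("homolog map density matches homolog_fraction", {
  cfg1 <- small_cfg(homolog_fraction = 1, seed = 2)
  p1 <- simulate_pair(cfg1)
  expect_equal(nrow(p1$homologs), cfg1$n_genes)
  expect_false(anyDuplicated(p1$homologs$gene_a) > 0)
  expect_false(anyDuplicated(p1$homologs$gene_b) > 0)
  expect_identical(p1$homologs$gene_b, toupper(p1$homologs$gene_a))

  cfg0 <- small_cfg(homolog_fraction = 0, seed = 2)
  expect_equal(nrow(simulate_pair(cfg0)$homologs), 0L)

  # binomial expectation 50 * 0.88 = 44 mappable genes
  n_map <- sapply(1:200, function(s) {
    cfg <- sim_config(n_genes = 50, n_cells_per_group = 1, n_planted = 5,
                      homolog_fraction = 0.88, seed = s)
    nrow(simulate_pair(cfg)$homologs)
  })
  expect_gte(mean(n_map), 42)
  expect_lte(mean(n_map), 46)
})

test_that("pair shares planted identity across species with distinct labels", {
  p <- simulate_pair(small_cfg(seed = 9))
  expect_identical(p$truth$planted_genes$b,
                   toupper(p$truth$planted_genes$a))
  expect_length(intersect(rownames(p$a$counts), rownames(p$b$counts)), 0)
  expect_true(all(p$homologs$gene_a %in% rownames(p$a$counts)))
  expect_true(all(p$homologs$gene_b %in% rownames(p$b$counts)))
})

test_that("clinical generator: null calibration and perfect predictor", {
  # with no true covariates the univariable pass rate is the type-I error
  frac_sig <- sapply(1:50, function(s) {
    cfg <- sim_config(n_true_covariates = 0, n_covariates = 42,
                      n_subjects = 95, seed = s)
    clin <- simulate_clinical(cfg)$clinical
    rep_ <- regression_cascade(clin)
    mean(rep_$univariable$significant)
  })
  expect_gte(mean(frac_sig), 0.02)
  expect_lte(mean(frac_sig), 0.09)

  # with no signal at all (5 covariates), backward elimination retains a
  # stage-1 survivor essentially always, so P(nothing retained) is the
  # probability that stage 1 passes nothing: 0.95^5 = 0.774 (confirmed by
  # brute-force simulation over 200 seeds). Assert the oracle-derived band.
  empty_null <- vapply(1:50, function(s) {
    cfg <- sim_config(n_subjects = 95, n_covariates = 5,
                      n_true_covariates = 0, seed = 200 + s)
    nrow(regression_cascade(simulate_clinical(cfg)$clinical)$retained) == 0
  }, logical(1))
  expect_gte(mean(empty_null), 0.774 - 2.96 * sqrt(0.774 * 0.226 / 50))
  expect_lte(mean(empty_null), 0.774 + 2.96 * sqrt(0.774 * 0.226 / 50))

  # a covariate equal to the target is retained with p ~ 0
  cfg <- sim_config(n_true_covariates = 0, n_covariates = 5,
                    n_subjects = 40, seed = 1)
  clin <- simulate_clinical(cfg)$clinical
  clin$cov01 <- clin$target_expr
  rep_ <- suppressWarnings(regression_cascade(clin))  # perfect-fit warning
  expect_true("cov01" %in% rep_$retained$covariate)
  expect_lt(rep_$retained$p[rep_$retained$covariate == "cov01"], 1e-12)

  expect_error(simulate_clinical(sim_config(n_subjects = 5)), "n_subjects")
})

test_that("ground truth round-trips through JSON serialization", {
  p <- simulate_pair(small_cfg(seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(p$truth, path)
  back <- read_truth(path)
  expect_identical(back$anchor, p$truth$anchor)
  expect_identical(back$planted_genes$a, p$truth$planted_genes$a)
  expect_identical(back$planted_genes$b, p$truth$planted_genes$b)
  expect_identical(back$homolog_pairs, p$truth$homolog_pairs)
  expect_equal(back$stress$a, p$truth$stress$a, tolerance = 1e-12)
  expect_equal(back$effect_size, p$truth$effect_size)
})
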