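# anchor correlation, top-K, homolog transport, intersection, stress DE

norm_from <- function(m) {
  # wrap a dense numeric matrix as the normalized-matrix input
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("anchor_correlation matches hand-computed Spearman values", {
  m <- rbind(anchor = c(1, 2, 3, 4, 5),
             same = c(1, 2, 3, 4, 5) * 2,     # rho 1
             near = c(2, 1, 4, 3, 5),          # rho 0.8 (sum d^2 = 4)
             flat = c(1, 1, 1, 1, 1))
  colnames(m) <- paste0("c", 1:5)
  tab <- anchor_correlation(norm_from(m), colnames(m), "anchor",
                            min_cells = 3, min_frac_expressing = 0)
  expect_equal(tab$rho[tab$gene == "same"], 1)
  expect_equal(tab$rank[tab$gene == "same"], 1L)
  expect_equal(tab$rho[tab$gene == "near"], 0.8, tolerance = 1e-12)
  expect_equal(tab$rho[tab$gene == "near"],
               1 - 6 * 4 / (5 * (5^2 - 1)), tolerance = 1e-12)
  # constant gene: ineligible, undefined rho, absent from the ranking
  expect_false(tab$eligible[tab$gene == "flat"])
  expect_true(is.na(tab$rho[tab$gene == "flat"]))
  expect_true(is.na(tab$rank[tab$gene == "flat"]))
  # the anchor itself is never eligible
  expect_false(tab$eligible[tab$gene == "anchor"])
  # ranks are a permutation of 1..n_eligible
  expect_setequal(tab$rank[tab$eligible], seq_len(sum(tab$eligible)))
})

test_that("anchor_correlation enforces its preconditions", {
  m <- rbind(anchor = c(0, 0, 0), g2 = c(1, 2, 3))
  colnames(m) <- paste0("c", 1:3)
  nm <- norm_from(m)
  expect_error(anchor_correlation(nm, colnames(m), "missing", min_cells = 3),
               "not found")
  expect_error(anchor_correlation(nm, colnames(m), "anchor", min_cells = 50),
               "at least 50")
  expect_error(anchor_correlation(nm, colnames(m), "anchor", min_cells = 3),
               "no nonzero")
})

test_that("anchor_correlation equals the brute-force oracle on random data", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    g <- sample(3:8, 1)
    m <- matrix(rpois(n * g, 2), g, n)   # heavy ties on purpose
    rownames(m) <- c("anchor", paste0("g", seq_len(g - 1)))
    colnames(m) <- paste0("c", seq_len(n))
    m["anchor", 1] <- m["anchor", 1] + 1  # ensure anchor nonzero somewhere
    tab <- anchor_correlation(norm_from(m), colnames(m), "anchor",
                              min_cells = 3, min_frac_expressing = 0)
    for (gene in setdiff(rownames(m), "anchor")) {
      if (var(m[gene, ]) == 0) next
      expect_lt(abs(tab$rho[tab$gene == gene] -
                      oracle_spearman(m[gene, ], m["anchor", ])), 1e-12)
    }
  }
})

test_that("top_k applies the boundary tie-break and contract errors", {
  tab <- data.frame(
    gene = c("gB", "gA", "gC", "gE", "gD", "gF"),
    rho = c(0.9, 0.9, 0.8, 0.7, 0.7, 0.1),
    p_two_tailed = 0.01, n_cells = 10, frac_expressing = 1,
    eligible = TRUE, stringsAsFactors = FALSE
  )
  ord <- order(-tab$rho, tab$gene)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  # brute-force oracle: sort by (-rho, gene) and take 4
  oracle <- tab$gene[order(-tab$rho, tab$gene)][1:4]
  expect_identical(top_k(tab, 4), oracle)
  expect_identical(top_k(tab, 4), c("gA", "gB", "gC", "gD"))
  expect_identical(top_k(tab, 1), "gA")
  expect_identical(top_k(tab, 100), tab$gene[order(tab$rank)])  # no padding
  expect_error(top_k(tab, 0), "positive")
  tab$eligible <- FALSE
  expect_error(top_k(tab, 4), "eligible")
})

test_that("map_homologs expands many-to-many and reports the unmapped", {
  hom <- data.frame(gene_a = c("a", "a", "c"),
                    gene_b = c("A1", "A2", "C"), stringsAsFactors = FALSE)
  res <- map_homologs(c("a", "b"), hom)
  expect_setequal(res$mapped$gene_b, c("A1", "A2"))
  expect_equal(res$n_mappable, 1)
  expect_identical(res$unmapped, "b")

  ident <- data.frame(gene_a = c("x", "y"), gene_b = c("x", "y"),
                      stringsAsFactors = FALSE)
  res2 <- map_homologs(c("x", "y"), ident)
  expect_identical(res2$mapped$gene_b, c("x", "y"))
  expect_equal(res2$n_mappable, 2)

  res3 <- map_homologs(c("x", "y"), hom[0, ])
  expect_equal(nrow(res3$mapped), 0)
  expect_identical(res3$unmapped, c("x", "y"))

  # reverse direction
  res4 <- map_homologs(c("A2", "C"), hom, direction = "b_to_a")
  expect_setequal(res4$mapped$gene_b, c("a", "c"))
})

test_that("conserved_intersection annotates ranks on both sides", {
  hom <- data.frame(gene_a = c("x", "y", "z"), gene_b = c("X", "Y", "Z"),
                    stringsAsFactors = FALSE)
  mp <- map_homologs(c("x", "y", "z"), hom)
  cons <- conserved_intersection(mp, c("W", "X", "Y"))
  expect_identical(cons$gene_b, c("X", "Y"))
  expect_equal(cons$rank_b, c(2, 3))
  expect_equal(cons$rank_a, c(1, 2))
  # disjoint lists
  expect_equal(nrow(conserved_intersection(mp, c("Q", "R"))), 0)
  # identical K-lists with identity map conserve everything
  ident <- data.frame(gene_a = c("p", "q"), gene_b = c("p", "q"),
                      stringsAsFactors = FALSE)
  cons2 <- conserved_intersection(map_homologs(c("p", "q"), ident),
                                  c("p", "q"))
  expect_equal(nrow(cons2), 2)
})

test_that("stress_de matches enumeration and the BH step-up", {
  # genes x cells: 3 control then 3 stressed
  m <- rbind(gA = c(1, 2, 3, 4, 5, 6),
             gB = c(2, 2, 2, 2, 2, 2),
             gC = c(5, 6, 4, 1, 2, 3))
  colnames(m) <- paste0("c", 1:6)
  meta <- data.frame(barcode = colnames(m), species = "m",
                     cell_type = "CM",
                     condition = rep(c("control", "stressed"), each = 3),
                     sample_id = "s", stringsAsFactors = FALSE)
  de <- stress_de(norm_from(m), meta, c("gA", "gB", "gC"))
  # (1,2,3) vs (4,5,6): 2 of the 20 assignments are as extreme -> p = 0.1
  expect_equal(de$p[de$gene == "gA"], 0.1)
  expect_equal(de$p[de$gene == "gB"], 1)   # identical groups
  expect_equal(de$p[de$gene == "gC"], 0.1) # symmetric, downregulated
  expect_gt(de$log2fc[de$gene == "gA"], 0)
  expect_lt(de$log2fc[de$gene == "gC"], 0)
  expect_equal(de$q, oracle_bh(de$p), tolerance = 1e-12)

  meta$condition <- "control"
  expect_error(stress_de(norm_from(m), meta, "gA"), "per condition")
})

test_that("BH q-values follow the hand step-up on the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p matches bitmask enumeration, ties included", {
  set.seed(21)
  for (i in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(0:4, nx, replace = TRUE)
    y <- sample(0:4, ny, replace = TRUE)
    expect_equal(wilcox_rank_sum_p(x, y), oracle_wilcox_exact(x, y),
                 tolerance = 1e-12)
  }
  # tie-free case agrees with the classical exact distribution
  expect_equal(wilcox_rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcox_rank_sum_p(1:4, 5:9),
               stats::wilcox.test(1:4, 5:9, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("pipeline identity: conserved set within both top-K lists, no anchor", {
  cfg <- sim_config(n_genes = 300, n_cells_per_group = 80, n_planted = 15,
                    seed = 17)
  pair <- simulate_pair(cfg)
  scr <- anchor_screen(pair$a, pair$b, pair$homologs, "Nppa", "NPPA", k = 40)
  mapped_b <- scr$mapping$mapped$gene_b
  expect_true(all(scr$conserved$gene_b %in% mapped_b))
  expect_true(all(scr$conserved$gene_b %in% scr$top_b))
  expect_true(all(scr$conserved$gene_a %in% scr$top_a))
  expect_false("Nppa" %in% c(scr$top_a, scr$conserved$gene_a))
  expect_false("NPPA" %in% c(scr$top_b, scr$conserved$gene_b))
  expect_true(all(scr$conserved$rank_a <= 40 & scr$conserved$rank_b <= 40))
})
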