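test_that("Shannon index matches closed forms and a direct-sum oracle", {
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(c(3, 3)), log(2))
  expect_error(shannon_index(c(0, 0)), "all-zero")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
  set.seed(8)
  for (i in 1:10) {
    x <- runif(10, 0, 5)
    p <- x / sum(x)
    expect_equal(shannon_index(x), -sum(p * log(p)))
  }
})

test_that("richness and Pielou behave at the boundaries", {
  x <- c(0, 2, 0, 1, 4, 0, 0, 0, 0, 3)
  expect_equal(richness(x), 4)
  expect_equal(pielou_evenness(rep(2, 7)), 1)
  expect_true(is.na(pielou_evenness(c(0, 9, 0))))  # one species: undefined
  set.seed(13)
  for (i in 1:1000) {
    x <- rexp(sample(2:12, 1))
    j <- pielou_evenness(x)
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("alpha diversity table lines up rows with samples", {
  m <- matrix(c(1, 1, 1, 1, 4, 0, 0, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  tbl <- alpha_diversity(m)
  expect_equal(tbl$sample_id, c("a", "b"))
  expect_equal(tbl$richness, c(4L, 1L))
  expect_equal(tbl$shannon, c(log(4), 0))
  expect_equal(tbl$pielou, c(1, NA))
})

test_that("group comparisons follow the stated small-sample contracts", {
  g <- rep(c("A", "B"), each = 4)
  same <- c(1, 2, 3, 4, 1, 2, 3, 4)
  # symmetric ties: two-sided rank-sum p = 1 (tie-corrected approximation)
  expect_equal(group_compare(same, g, "wilcoxon")$p_value, 1)
  ident <- group_compare(c(1, 3, 5, 7, 2, 4, 6, 8), g, "wilcoxon")
  expect_gt(ident$p_value, 0.5)

  expect_error(group_compare(c(0, 0, 0, 1, 1, 1), rep(c("A", "B"), each = 3),
                             "t"), "zero variance")
  expect_error(group_compare(c(1, 2), c("A", "B"), "t"), ">= 2")

  # exact p for n = (4, 4): enumeration over all choose(8, 4) = 70 splits
  vals <- c(1.1, 2.3, 3.7, 4.1, 5.2, 6.9, 7.4, 8.8)
  obs <- group_compare(vals, g, "wilcoxon")
  rk <- rank(vals)
  w_obs <- sum(rk[g == "A"]) - 4 * 5 / 2
  combos <- combn(8, 4)
  ws <- apply(combos, 2, function(i) sum(rk[i]) - 10)
  p_exact <- mean(abs(ws - 8) >= abs(w_obs - 8))  # center = n1*n2/2 = 8
  expect_equal(obs$p_value, p_exact)
})

test_that("Bray-Curtis and Horn match their defining formulas", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(max(dissimilarity_matrix(m, "bray")), 0)
  expect_equal(max(dissimilarity_matrix(m, "horn")), 0)
  disjoint <- matrix(c(1, 2, 0, 0, 0, 0, 3, 4), 2, 4, byrow = TRUE)
  expect_equal(as.numeric(dissimilarity_matrix(disjoint, "bray")), 1)
  expect_equal(as.numeric(dissimilarity_matrix(disjoint, "horn")), 1)

  set.seed(21)
  m <- matrix(rexp(40), 5, 8)
  bc <- as.matrix(dissimilarity_matrix(m, "bray"))
  ho <- as.matrix(dissimilarity_matrix(m, "horn"))
  for (i in 1:4) for (j in (i + 1):5) {
    x <- m[i, ]; y <- m[j, ]
    expect_equal(bc[i, j], sum(abs(x - y)) / sum(x + y))
    mh <- 2 * sum(x * y) /
      ((sum(x^2) / sum(x)^2 + sum(y^2) / sum(y)^2) * sum(x) * sum(y))
    expect_equal(ho[i, j], 1 - mh)
  }
})

test_that("Horn is scale-invariant per row; Bray-Curtis is not", {
  set.seed(31)
  m <- matrix(rexp(24), 4, 6)
  scaled <- m * c(1, 10, 0.5, 3)
  expect_equal(as.matrix(dissimilarity_matrix(scaled, "horn")),
               as.matrix(dissimilarity_matrix(m, "horn")),
               ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(
    as.matrix(dissimilarity_matrix(scaled, "bray")),
    as.matrix(dissimilarity_matrix(m, "bray")), check.attributes = FALSE)))
  perm <- sample(6)
  expect_equal(as.matrix(dissimilarity_matrix(m[, perm], "bray")),
               as.matrix(dissimilarity_matrix(m, "bray")),
               ignore_attr = TRUE)
})

test_that("PCoA reproduces closed-form configurations", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa_ordination(d2)
  expect_equal(abs(ord$coordinates[, 1]), c(a = 1.5, b = 1.5))
  expect_gt(ord$coordinates[which.max(abs(ord$coordinates[, 1])), 1], 0)

  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoa_ordination(d3)
  ev <- ord3$eigenvalues[ord3$eigenvalues > 1e-10]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2])

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA coordinates reconstruct Euclidean-embeddable distances", {
  set.seed(4)
  pts <- matrix(rnorm(18), 6, 3)
  d <- dist(pts)
  ord <- pcoa_ordination(d)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - as.matrix(d))), 1e-8)
})

test_that("PERMANOVA matches an exhaustive brute-force oracle", {
  set.seed(61)
  m <- matrix(rexp(48), 6, 8)
  d <- dissimilarity_matrix(m, "bray")
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g, seed = 7)
  expect_true(res$exhaustive)
  expect_equal(res$pseudo_F, oracle_permanova_f(d, g))
  # brute-force p: recompute F over all 20 balanced relabelings
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(i) {
    oracle_permanova_f(d, ifelse(seq_len(6) %in% i, "A", "B"))
  })
  expect_equal(res$p_value, mean(fs >= res$pseudo_F - 1e-12))
  # R2 + residual fraction = 1
  expect_equal(res$R2 + (1 - res$R2), 1, tolerance = 1e-12)
})

test_that("PERMANOVA agrees with vegan::adonis2 on F, R2 and exhaustive p", {
  set.seed(71)
  m <- matrix(rexp(60), 6, 10)
  d <- dissimilarity_matrix(m, "bray")
  g <- factor(rep(c("A", "B"), times = c(2, 4)))
  res <- permanova(d, g, seed = 3)
  ref <- vegan::adonis2(d ~ g, permutations = 10000)
  expect_equal(res$pseudo_F, ref$F[1])
  expect_equal(res$R2, ref$R2[1])
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("PERMANOVA handles degenerate and well-separated inputs", {
  d0 <- matrix(0, 6, 6)
  res <- permanova(d0, rep(c("A", "B"), 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  clusters <- rbind(matrix(rnorm(9, 0, 0.01), 3),
                    matrix(rnorm(9, 10, 0.01), 3))
  d <- dist(clusters)
  res <- permanova(d, rep(c("A", "B"), each = 3))
  expect_equal(res$p_value, 1 / choose(6, 3) * 2)  # both extreme splits
  expect_error(permanova(d, rep("A", 6)), "two groups")
})

test_that("sampled-permutation p is seed-reproducible and sample-order invariant", {
  set.seed(91)
  m <- matrix(rexp(16 * 6), 16, 6)
  d <- as.matrix(dissimilarity_matrix(m, "bray"))
  g <- rep(c("A", "B"), each = 8)
  r1 <- permanova(d, g, n_permutations = 199, seed = 42)
  r2 <- permanova(d, g, n_permutations = 199, seed = 42)
  expect_false(r1$exhaustive)
  expect_equal(r1$p_value, r2$p_value)
  perm <- sample(16)
  r3 <- permanova(d[perm, perm], g[perm], n_permutations = 199, seed = 42)
  expect_equal(r3$pseudo_F, r1$pseudo_F)
})

test_that("venn partition recovers printed shared/unique percentages", {
  a <- c(paste0("shared", 1:4), "a1")
  b <- c(paste0("shared", 1:4), "b1", "b2")
  out <- venn_partition(a, b)
  expect_equal(out$count, c(4L, 1L, 2L))
  expect_equal(out$percent, c(57.1, 14.3, 28.6))
  expect_error(venn_partition(character(), character()), "no features")
})
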