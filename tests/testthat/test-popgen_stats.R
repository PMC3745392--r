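test_that("haplotype diversity reproduces the printed per-site values", {
  tab <- unclass(reference_distribution())
  bb <- haplotype_diversity(tab[, "BB"])
  expect_equal(round(bb$h, 3), 0.968)
  expect_equal(round(bb$ci, 3), c(0.942, 0.993))
  expect_equal(round(haplotype_diversity(tab[, "EST"])$h, 3), 0.957)
  expect_equal(round(haplotype_diversity(tab[, "STA"])$h, 3), 0.939)
})

test_that("haplotype diversity degenerate cases and unbiasedness identity", {
  one <- haplotype_diversity(5)
  expect_equal(one$h, 0)
  expect_equal(one$V_h, 0)
  expect_equal(haplotype_diversity(c(1, 1))$h, 1)
  expect_error(haplotype_diversity(1), "at least 2")

  # h == 1 - sum c_i (c_i - 1) / (n (n-1)): probability that two distinct
  # individuals drawn without replacement differ, by exhaustive pair count
  set.seed(61)
  for (i in 1:20) {
    cnt <- rpois(sample(2:8, 1), 2) + 1
    n <- sum(cnt)
    same_pairs <- sum(cnt * (cnt - 1))
    expect_equal(haplotype_diversity(cnt)$h, 1 - same_pairs / (n * (n - 1)))
  }
})

test_that("pairwise differences match a position-by-position oracle", {
  expect_equal(pairwise_diff_matrix(c("ACGT", "ACGA"))[1, 2], 1L)
  expect_equal(pairwise_diff_matrix(c("ACGT", "ACGT"))[1, 2], 0L)
  # unresolved positions are pairwise-deleted
  expect_equal(pairwise_diff_matrix(c("ANGT", "ACGA"))[1, 2], 1L)
  expect_equal(pairwise_diff_matrix(c("A-GT", "ACGA"))[1, 2], 1L)

  set.seed(67)
  seqs <- vapply(1:20, function(i) rand_seq(30), "")
  d <- pairwise_diff_matrix(seqs)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  for (i in 1:19) for (j in (i + 1):20)
    expect_equal(d[i, j], oracle_diff(seqs[i], seqs[j]))
  expect_error(pairwise_diff_matrix(c("ACG", "ACGT")), "equal")
})

test_that("nucleotide diversity equals the all-pairs brute force to 1e-12", {
  # one haplotype
  expect_equal(nucleotide_diversity(5, matrix(0, 1, 1), 10)$pi, 0)
  # n = 2 with one difference over 10 sites
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(nucleotide_diversity(c(1, 1), d, 10)$pi, 0.1)

  set.seed(71)
  for (rep in 1:5) {
    haps <- vapply(1:6, function(i) rand_seq(40), "")
    haps <- haps[!duplicated(haps)]
    cnt <- rpois(length(haps), 3) + 1
    nd <- nucleotide_diversity(cnt, pairwise_diff_matrix(haps), 40)
    indiv <- rep(haps, cnt)
    expect_equal(nd$pi, oracle_pi(indiv), tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(c(1, 1), matrix(0, 3, 3), 10),
               "dimension")
})

test_that("segregating sites and base composition", {
  expect_equal(segregating_sites(c("ACGT", "ACGT")), 0L)
  expect_equal(segregating_sites(c("AAA", "AAT")), 1L)
  # unresolved bases do not make a column segregating
  expect_equal(segregating_sites(c("AAN", "AAT")), 0L)

  bc <- base_composition("ACGT")
  expect_equal(unname(bc[c("A", "C", "G", "T")]), rep(25, 4))
  expect_equal(unname(bc["GC"]), 50)
  expect_equal(unname(base_composition("GGCC")["GC"]), 100)

  set.seed(73)
  seqs <- vapply(1:10, function(i) rand_seq(50), "")
  bc2 <- base_composition(seqs)
  chars <- unlist(strsplit(seqs, ""))
  for (b in c("A", "C", "G", "T"))
    expect_equal(unname(bc2[b]), 100 * sum(chars == b) / length(chars))
  expect_equal(sum(bc2[c("A", "C", "G", "T")]), 100)
})

test_that("chi-square on unique proportions matches the printed statistic", {
  chi <- chi_square_unique(reference_distribution())
  expect_equal(round(chi$statistic, 2), 1.42)
  expect_equal(chi$df, 2L)
  expect_equal(unname(chi$observed["unique", ]), c(8, 5, 6))
  expect_equal(unname(chi$observed["shared", ]), c(16, 16, 8))
  # expected table preserves the observed margins
  expect_equal(rowSums(chi$expected), rowSums(chi$observed))
  expect_equal(colSums(chi$expected), colSums(chi$observed))
})

test_that("chi-square equals the direct Pearson formula and null cases", {
  # sites X, Y each have 3 haplotypes, 1 unique -> equal proportions,
  # statistic 0, p 1
  m0 <- matrix(c(2L, 0L, 4L, 4L, 0L, 2L, 4L, 4L), ncol = 2,
               dimnames = list(c("a", "b", "c", "d"), c("X", "Y")))
  chi0 <- chi_square_unique(count_table(m0))
  expect_equal(chi0$statistic, 0)
  expect_equal(chi0$p_value, 1)

  set.seed(79)
  for (i in 1:10) {
    obs <- matrix(rpois(4, 8) + 1, 2, 2)
    got <- hapaudit:::pearson_chisq(obs)
    # hand-computed Pearson sum
    expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    stat <- 0
    for (r in 1:2) for (cc in 1:2)
      stat <- stat + (obs[r, cc] - expected[r, cc])^2 / expected[r, cc]
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$df, 1L)
  }
})

test_that("chi-square p-values are uniform under the null", {
  # haplotypes assigned independently to 3 sites and to unique/shared
  # status: the 2x3 Pearson p-values must be ~U(0,1)
  set.seed(83)
  pvals <- replicate(2000, {
    site <- sample(1:3, 120, replace = TRUE)
    uniq <- sample(0:1, 120, replace = TRUE, prob = c(0.6, 0.4))
    obs <- rbind(tabulate(site[uniq == 1], 3), tabulate(site[uniq == 0], 3))
    hapaudit:::pearson_chisq(obs)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_diversity reproduces the t-to-p path", {
  eq <- compare_diversity(0.5, 0.1, 0.5, 0.1, df = 2)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # t = 4.467 on 2 df is the printed borderline case p = 0.047
  se <- 1 / sqrt(2)
  cmp <- compare_diversity(4.467, se, 0, se, df = 2)
  expect_equal(cmp$t, 4.467)
  expect_equal(round(cmp$p, 3), 0.047)
  # symmetric in the two estimates
  swapped <- compare_diversity(0, se, 4.467, se, df = 2)
  expect_equal(swapped$t, cmp$t)
  expect_equal(swapped$p, cmp$p)
  expect_error(compare_diversity(1, 0, 2, 0, 2), "zero pooled")
})
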