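test_that("gen_haplotypes realises the reference table exactly", {
  tab <- reference_distribution()
  cfg <- synthetic_config(L = 435, S = 37, seed = 11)
  gen <- gen_haplotypes(cfg, tab)
  expect_equal(nrow(gen$records), 103L)
  expect_equal(length(unique(gen$records$seq)), 35L)
  expect_equal(unique(nchar(gen$records$seq)), 435L)
  # exactly S segregating sites among the cohort haplotypes
  expect_equal(segregating_sites(unique(gen$records$seq)), 37L)
  expect_equal(gen$realized_S, 37L)
  # identical sequences iff identical haplotype assignment
  split_by_hap <- split(gen$records$seq, gen$assignment[gen$records$id])
  expect_true(all(vapply(split_by_hap, function(s) length(unique(s)) == 1L, TRUE)))
  expect_equal(length(split_by_hap), 35L)
  # auxiliary-only haplotypes are distinct from every cohort haplotype
  aux <- gen$haplotypes[!gen$haplotypes$baltic, ]
  expect_equal(nrow(aux), 3L)
  expect_false(any(aux$seq %in% gen$records$seq))
})

test_that("generators are pure functions of (inputs, seed)", {
  tab <- reference_distribution()
  cfg <- synthetic_config(seed = 99)
  g1 <- gen_haplotypes(cfg, tab)
  g2 <- gen_haplotypes(cfg, tab)
  expect_identical(g1, g2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1$records, f1); write_fasta(g2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different world
  g3 <- gen_haplotypes(synthetic_config(seed = 100), tab)
  expect_false(identical(g1$records$seq, g3$records$seq))
  # no global RNG state is consumed
  set.seed(7); before <- .Random.seed
  invisible(gen_haplotypes(cfg, tab))
  expect_identical(before, .Random.seed)
})

test_that("gen_haplotypes round-trips through collapse and tabulation", {
  tab <- reference_distribution()
  gen <- gen_haplotypes(synthetic_config(seed = 5), tab)
  haps <- collapse_haplotypes(gen$records)
  back <- build_count_table(haps, setNames(gen$records$site, gen$records$id))
  baltic <- bare_counts(tab)[rowSums(unclass(tab)) > 0, colnames(back)]
  expect_equal(unname(bare_counts(back)), unname(baltic))
  expect_equal(rownames(back), rownames(baltic))
})

test_that("degenerate haplotype tables are flagged", {
  m <- matrix(4L, 1, 1, dimnames = list("HT1", "BB"))
  tab1 <- count_table(m)
  expect_warning(gen <- gen_haplotypes(synthetic_config(S = 5, seed = 1), tab1),
                 "segregating")
  expect_equal(nrow(gen$records), 4L)
  expect_equal(length(unique(gen$records$seq)), 1L)
  expect_equal(gen$realized_S, 0L)
  # more haplotypes than single-step mutations can keep distinct
  m2 <- matrix(1L, 8, 1, dimnames = list(paste0("HT", 1:8), "BB"))
  expect_error(gen_haplotypes(synthetic_config(S = 3, seed = 1),
                              count_table(m2)), "S >=")
})

test_that("gen_editor_pair obeys its noise model", {
  truth <- rand_seq(435)
  clean <- gen_editor_pair(truth, synthetic_config(disagreement_rate = 0),
                           seed = 3)
  expect_identical(clean$calls_a, truth)
  expect_identical(clean$calls_b, truth)

  poor <- gen_editor_pair(paste(rep("A", 9), collapse = ""),
                          synthetic_config(L = 9, S = 3,
                                           poor_read_fraction = 1), seed = 4)
  dis <- sum(strsplit(poor$calls_a, "")[[1]] != strsplit(poor$calls_b, "")[[1]])
  expect_true(poor$poor)
  expect_gte(dis, 3)

  # mean disagreement fraction ~ Binomial(L, rate) over 1000 reads
  rate <- 0.1; L <- 435; n_reads <- 1000
  cfg <- synthetic_config(L = L, disagreement_rate = rate)
  fracs <- vapply(seq_len(n_reads), function(i) {
    p <- gen_editor_pair(truth, cfg, seed = 1000 + i)
    mean(strsplit(p$calls_a, "")[[1]] != strsplit(p$calls_b, "")[[1]])
  }, 0)
  se <- sqrt(rate * (1 - rate) / (L * n_reads))
  expect_lt(abs(mean(fracs) - rate), 3 * se)
})

test_that("gen_repository injects duplicates and unsupported variants", {
  src <- setNames(vapply(1:31, function(i) rand_seq(50), ""),
                  paste0("H", 1:31))
  # keep sources distinct
  expect_equal(length(unique(src)), 31L)
  cfg <- synthetic_config(L = 50, S = 10, seed = 8, error_rate = 0,
                          duplicate_spec = c(4, 3, 2, 2, 2, 2))
  repo <- gen_repository(src, cfg)
  expect_equal(nrow(repo), 40L)
  expect_equal(length(unique(repo$seq)), 31L)
  dd <- dedup_repository(repo)
  expect_equal(sort(lengths(dd$groups), decreasing = TRUE),
               c(4L, 3L, 2L, 2L, 2L, 2L))

  plain <- gen_repository(src, synthetic_config(L = 50, S = 10, seed = 9,
                                                error_rate = 0))
  expect_setequal(plain$seq, unname(src))

  five <- src[1:5]
  corrupt <- gen_repository(five, synthetic_config(L = 50, S = 10, seed = 10,
                                                   error_rate = 1))
  expect_equal(nrow(corrupt), 5L)
  expect_false(any(corrupt$seq %in% five))
  prov <- attr(corrupt, "provenance")
  expect_true(all(prov$corrupted))
  expect_error(gen_repository(five,
    synthetic_config(duplicate_spec = rep(2, 6))), "more duplicate groups")
})

test_that("synthetic_config validates its parameters", {
  expect_error(synthetic_config(S = 500, L = 435), "0 <= S <= L")
  expect_error(synthetic_config(error_rate = 1.5), "rates")
  expect_error(synthetic_config(duplicate_spec = 1), ">= 2")
})
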