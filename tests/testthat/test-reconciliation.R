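test_that("dedup_repository finds the packaged duplicate structure", {
  world <- study_world(4)
  dd <- dedup_repository(world$repository)
  expect_length(dd$groups, 6L)
  expect_equal(sort(lengths(dd$groups), decreasing = TRUE),
               c(4L, 3L, 2L, 2L, 2L, 2L))
  expect_equal(nrow(dd$representatives), 31L)
  # groups ordered by size descending; members sorted; labelled by
  # smallest member
  expect_equal(lengths(dd$groups), sort(lengths(dd$groups), decreasing = TRUE))
  expect_true(all(vapply(dd$groups, function(g) !is.unsorted(g), TRUE)))
  # the packaged group listing is realised exactly
  ref_groups <- lapply(strsplit(reference_duplicate_groups()$members, ","),
                       function(ids) sort(sprintf("GB%02d", as.integer(ids))))
  expect_setequal(lapply(dd$groups, identity), ref_groups)

  none <- dedup_repository(seq_records(c("a", "b"), c("ACGT", "ACGA")))
  expect_length(none$groups, 0L)
  all_same <- dedup_repository(seq_records(paste0("x", 1:5), rep("ACGT", 5)))
  expect_length(all_same$groups, 1L)
  expect_length(all_same$groups[[1]], 5L)
})

test_that("classify_support reproduces the reference reconciliation", {
  world <- study_world(6)
  haps <- collapse_haplotypes(world$records)
  rep <- reconcile(world$repository, haps, world$aux_haplotypes)
  expect_equal(rep$n_repo_entries, 40L)
  expect_equal(rep$n_repo_distinct, 31L)
  expect_length(rep$supported, 16L)
  expect_length(rep$aux_supported, 3L)
  expect_length(rep$unsupported, 12L)
  expect_length(rep$novel, 19L)
  expect_equal(round(100 * rep$support_rate, 1), 61.3)
  expect_equal(nrow(rep$reference_set), 38L)
  # the three partitions cover the distinct repository haplotypes
  expect_length(c(rep$supported, rep$aux_supported, rep$unsupported), 31L)
  expect_equal(rep$support_rate, 19 / 31)
})

test_that("classify_support trivial cases", {
  reps <- collapse_haplotypes(seq_records(c("a", "b"), c("ACGT", "AGGT")))
  same <- classify_support(reps, reps)
  expect_length(same$supported, 2L)
  expect_length(same$novel, 0L)

  other <- collapse_haplotypes(seq_records(c("x", "y"), c("TTTT", "CCCC")))
  disj <- classify_support(reps, other)
  expect_length(disj$supported, 0L)
  expect_length(disj$unsupported, 2L)
  expect_length(disj$novel, 2L)
})

test_that("support classes partition random repositories and recover truth", {
  set.seed(41)
  for (rep_i in 1:5) {
    src <- setNames(vapply(1:12, function(i) rand_seq(40), ""),
                    paste0("H", 1:12))
    src <- src[!duplicated(src)]
    cfg <- synthetic_config(L = 40, S = 10, seed = 100 + rep_i,
                            error_rate = 0.3, duplicate_spec = c(3, 2))
    repo <- gen_repository(src, cfg)
    prov <- attr(repo, "provenance")
    dd <- dedup_repository(repo)
    reedited <- collapse_haplotypes(
      seq_records(names(src), unname(src)), exclude_ambiguous = FALSE)
    out <- classify_support(dd$representatives, reedited)
    # partition property
    all_labels <- dd$representatives$label
    expect_setequal(c(out$supported, out$aux_supported, out$unsupported),
                    all_labels)
    expect_length(intersect(out$supported, out$unsupported), 0L)
    expect_equal(out$n_repo_distinct,
                 out$n_repo_entries - sum(lengths(out$duplicate_groups) - 1))
    # truth recovery: clean entries supported, corrupted ones not
    rep_seq <- setNames(dd$representatives$seq, dd$representatives$label)
    for (lab in out$supported)
      expect_true(rep_seq[[lab]] %in% src)
    for (lab in out$unsupported)
      expect_false(rep_seq[[lab]] %in% src)
    corrupted_seqs <- repo$seq[prov$corrupted]
    expect_true(all(corrupted_seqs %in% rep_seq[out$unsupported]))
  }
})

test_that("windowed comparison handles unequal lengths", {
  core <- c(a = "ACGTACGT", b = "TTTTACGT")
  long <- paste0("GG", core, "CC")        # deposit with extra flanks
  repo <- collapse_haplotypes(seq_records(c("r1", "r2"), unname(long)))
  reedited <- collapse_haplotypes(seq_records(names(core), unname(core)))
  expect_error(classify_support(repo, reedited), "window")
  out <- classify_support(repo, reedited, window = c(3, 8))
  expect_length(out$supported, 2L)
})

test_that("build_erroneous expands a distribution over ordinal haplotypes", {
  world <- study_world(8)
  dist <- synthetic_erroneous_distribution()
  rec <- build_erroneous(world$repository$seq, dist)
  expect_equal(nrow(rec), 108L)
  expect_equal(unname(table(rec$site)[c("BB", "EST", "STA")]),
               c(40L, 40L, 28L), ignore_attr = TRUE)
  # repository duplicates collapse the 40 rows to 31 distinct haplotypes
  expect_equal(nrow(collapse_haplotypes(rec)), 31L)

  empty <- build_erroneous(world$repository$seq,
                           count_table(matrix(integer(0), 0, 2,
                             dimnames = list(NULL, c("BB", "EST")))))
  expect_equal(nrow(empty), 0L)

  over <- count_table(matrix(c(1L, 2L), 2, 1,
                             dimnames = list(c("r1", "r41"), "BB")))
  expect_warning(got <- build_erroneous(c("ACGT"), over), "beyond")
  expect_equal(nrow(got), 1L)            # only row 1 materialises
})

test_that("build_erroneous round-trips through tabulation", {
  set.seed(51)
  haps <- vapply(1:9, function(i) rand_seq(25), "")
  haps <- haps[!duplicated(haps)]
  m <- matrix(rpois(length(haps) * 2, 2), ncol = 2,
              dimnames = list(paste0("GB", seq_along(haps)), c("X", "Y")))
  storage.mode(m) <- "integer"
  m[rowSums(m) == 0, 1] <- 1L
  dist <- count_table(m)
  rec <- build_erroneous(haps, dist)
  back <- build_count_table(collapse_haplotypes(rec),
                            setNames(rec$site, rec$id))
  # same multiset of count rows (tabulation reorders by total)
  sort_rows <- function(x) {
    x <- unclass(x)[, c("X", "Y"), drop = FALSE]
    x[order(x[, 1], x[, 2]), , drop = FALSE]
  }
  expect_equal(unname(sort_rows(back)), unname(sort_rows(dist)))
})
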