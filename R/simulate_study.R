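# Simulate a complete haplotype-reassessment study from the packaged
# reference tables: a re-edited cohort, an auxiliary dataset, a repository
# whose duplicate structure and support pattern follow the reference
# old-ID mapping, and optionally raw dual-editor chromatogram calls.

# parse "5,28" / "New" / "" into integer repository ids
parse_old_ids <- function(old_id) {
  lapply(old_id, function(x) {
    x <- trimws(x)
    if (!nzchar(x) || identical(x, "New")) return(integer(0))
    as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  })
}

#' Simulate the full reassessment study world
#'
#' Builds, from the packaged reference distribution
#' ([reference_distribution()]) and a seed, every dataset of a
#' repository-versus-chromatogram reassessment:
#' \itemize{
#'   \item a re-edited cohort of `sum(table)` individuals whose collapse
#'     reproduces the table exactly;
#'   \item haplotype sequences for every table row, auxiliary-only rows
#'     included;
#'   \item a repository of one entry per old haplotype id, in which ids
#'     listed in the table's `old_id` column carry the corresponding
#'     haplotype sequence (so old ids sharing a row are exact duplicates)
#'     and unmapped ids carry sequences matching nothing;
#'   \item the auxiliary haplotype set (every row with a positive `aux`
#'     count).
#' }
#'
#' @param seed integer seed.
#' @param table a [count_table] with `old_id` annotations; defaults to the
#'   packaged grey seal reference distribution.
#' @param n_repo number of repository entries (old ids `1..n_repo`).
#' @param L,S fragment length and segregating sites for the generator.
#' @return A list: `table`, `records`, `haplotypes`, `assignment`,
#'   `site_of`, `aux_haplotypes` (named character), `repository`
#'   ([seq_records] with ids `GB01..`), `repo_truth` (data frame `gb_id`,
#'   `haplotype`, `status`).
#' @export
simulate_study <- function(seed = 1L, table = reference_distribution(),
                           n_repo = 40L, L = 435L, S = 37L) {
  cfg <- synthetic_config(L = L, S = S, seed = seed)
  gen <- gen_haplotypes(cfg, table)
  haps <- gen$haplotypes
  aux_counts <- attr(table, "aux")
  aux_haps <- setNames(haps$seq[aux_counts > 0L], haps$label[aux_counts > 0L])

  old_ids <- parse_old_ids(attr(table, "old_id"))
  gb_source <- rep(NA_character_, n_repo)
  for (r in seq_along(old_ids)) {
    ids <- old_ids[[r]]
    ids <- ids[ids <= n_repo]
    gb_source[ids] <- haps$label[r]
  }
  # unmapped repository ids: unique sequences supported by nothing
  baltic_rows <- which(haps$baltic)
  repo_seq <- character(n_repo)
  mapped <- !is.na(gb_source)
  repo_seq[mapped] <- haps$seq[match(gb_source[mapped], haps$label)]
  n_un <- sum(!mapped)
  if (n_un > 0L) {
    free <- setdiff(seq_len(L), gen$positions)
    if (length(free) < 2L)
      stop("fragment too short for unsupported-variant injection",
           call. = FALSE)
    repo_seq[!mapped] <- with_seed(seed + 104729L, {
      taken <- haps$seq
      out <- character(n_un)
      for (j in seq_len(n_un)) {
        repeat {
          src <- sample(baltic_rows, 1L)
          chars <- strsplit(haps$seq[src], "", fixed = TRUE)[[1L]]
          cand <- paste(mutate_at(chars, sample(free, 2L)), collapse = "")
          if (!cand %in% taken) break
        }
        taken <- c(taken, cand)
        out[j] <- cand
      }
      out
    })
  }
  status <- ifelse(!mapped, "unsupported",
            ifelse(gb_source %in% haps$label[haps$baltic], "supported",
                   "aux_supported"))
  repository <- seq_records(sprintf("GB%02d", seq_len(n_repo)), repo_seq)
  list(table = table,
       records = gen$records,
       haplotypes = haps,
       assignment = gen$assignment,
       site_of = setNames(gen$records$site, gen$records$id),
       aux_haplotypes = aux_haps,
       repository = repository,
       repo_truth = data.frame(gb_id = seq_len(n_repo),
                               haplotype = gb_source, status = status,
                               stringsAsFactors = FALSE))
}

#' Simulate dual-editor chromatogram calls for a cohort
#'
#' Embeds each truth sequence in a longer read with random flanking bases
#' and terminal N runs (at least one read attains the maximal run on each
#' side, so the shared clean window is exactly the core fragment), then
#' generates a dual-editor call pair per read. `n_poor` additional reads
#' are forced poor (at least one third inconsistent positions), emulating
#' chromatograms the one-third filter must reject.
#'
#' @param records truth [seq_records] (the core fragments).
#' @param seed integer seed.
#' @param flank bases added on each side (read length = core + 2*flank).
#' @param n_poor number of extra forced-poor reads.
#' @param disagreement_rate per-position editor disagreement rate for the
#'   good reads; the default 0 gives fully consistent retained reads.
#' @return A list: `pairs` (list of `calls_a`/`calls_b`/`id`), `site_of`,
#'   `truth` (the input records), `window` (expected clean window).
#' @export
simulate_chromatograms <- function(records, seed = 1L, flank = 27L,
                                   n_poor = 11L, disagreement_rate = 0) {
  L <- unique(nchar(records$seq))
  stopifnot(length(L) == 1L)
  n <- nrow(records)
  cfg_good <- synthetic_config(L = L + 2L * flank, seed = seed,
                               disagreement_rate = disagreement_rate,
                               poor_read_fraction = 0)
  cfg_poor <- synthetic_config(L = L + 2L * flank, seed = seed,
                               poor_read_fraction = 1)
  reads <- with_seed(seed, {
    lead <- sample.int(flank + 1L, n, replace = TRUE) - 1L  # 0..flank
    trail <- sample.int(flank + 1L, n, replace = TRUE) - 1L
    lead[1L] <- flank                       # pin the window to the core
    trail[if (n > 1L) 2L else 1L] <- flank
    embed <- function(core, nl, nt) {
      pad_l <- paste(c(rep("N", nl),
                       sample(BASES, flank - nl, replace = TRUE)),
                     collapse = "")
      pad_r <- paste(c(sample(BASES, flank - nt, replace = TRUE),
                       rep("N", nt)), collapse = "")
      paste0(pad_l, core, pad_r)
    }
    good <- vapply(seq_len(n), function(i)
      embed(records$seq[i], lead[i], trail[i]), "")
    poor_truth <- if (n_poor > 0L)
      vapply(sample.int(n, n_poor, replace = TRUE), function(i)
        embed(records$seq[i], 0L, 0L), "") else character(0)
    list(good = good, poor = poor_truth)
  })
  ids <- c(records$id,
           if (n_poor > 0L) sprintf("POOR%02d", seq_len(n_poor)))
  truths <- c(reads$good, reads$poor)
  cfgs <- c(rep(list(cfg_good), n), rep(list(cfg_poor), n_poor))
  pairs <- lapply(seq_along(truths), function(i) {
    p <- gen_editor_pair(truths[i], cfgs[[i]], seed = seed + i)
    p$id <- ids[i]
    p
  })
  list(pairs = pairs,
       site_of = setNames(records$site, records$id),
       truth = records,
       window = c(start = flank + 1L, end = flank + L))
}
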