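# Synthetic-data generators. These stand in for the raw chromatograms and
# repository accessions of a real haplotype survey: haplotype sequence sets
# matching a given count table, dual-editor call-string pairs with injected
# disagreements, and repositories with duplicate groups and corrupted
# entries. All generators are pure functions of (inputs, seed).

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a 435 bp mtDNA control-region fragment with 37
#' segregating sites, the dimensions of the Baltic grey seal reference
#' dataset shipped with the package.
#'
#' @param L sequence length in bp.
#' @param S number of segregating sites to realise among the haplotypes.
#' @param seed integer seed; identical seeds give identical output.
#' @param error_rate per-entry probability that a repository entry is
#'   corrupted into a sequence matching no source haplotype.
#' @param duplicate_spec integer vector of duplicate-group sizes for
#'   repository generation (each `>= 2`).
#' @param disagreement_rate per-position probability that the two editors
#'   of a chromatogram disagree.
#' @param poor_read_fraction probability that a read is made "poor", i.e.
#'   at least one third of its positions are forced inconsistent.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(L = 435L, S = 37L, seed = 1L,
                             error_rate = 0.05, duplicate_spec = integer(),
                             disagreement_rate = 0.01,
                             poor_read_fraction = 0) {
  L <- as.integer(L); S <- as.integer(S)
  if (S < 0L || S > L) stop("need 0 <= S <= L", call. = FALSE)
  rates <- c(error_rate, disagreement_rate, poor_read_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  if (length(duplicate_spec) && any(duplicate_spec < 2))
    stop("duplicate group sizes must be >= 2", call. = FALSE)
  structure(list(L = L, S = S, seed = as.integer(seed),
                 error_rate = error_rate,
                 duplicate_spec = as.integer(duplicate_spec),
                 disagreement_rate = disagreement_rate,
                 poor_read_fraction = poor_read_fraction),
            class = "synthetic_config")
}

# mutate character vector `chars` at `pos` to bases different from current
mutate_at <- function(chars, pos) {
  for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  chars
}

#' Generate haplotype sequences and an individual cohort from a count table
#'
#' Haplotypes are placed on a random attachment tree (each new haplotype
#' descends from a randomly chosen earlier one) and mutations are dropped
#' on its edges, each at a fresh alignment position, so every pair of
#' haplotypes is connected by a defined single-step mutational path and the
#' realised number of segregating sites among the haplotypes with positive
#' site counts equals `config$S`. Auxiliary-only rows (zero site counts,
#' positive `aux`) receive sequences mutated at positions outside the `S`
#' focal sites so they are distinct from every cohort haplotype without
#' altering its segregating-site count.
#'
#' @param config a [synthetic_config]; needs `S >= nrow - 1` for the rows
#'   with positive site counts (single-step distinctness), and
#'   `nrow <= 2^S`.
#' @param table a [count_table]; one individual record is emitted per
#'   counted cell entry.
#' @return A list with components `records` ([seq_records], one row per
#'   individual, `sum(table)` rows), `haplotypes` (data frame `label`,
#'   `seq`, `baltic` flag for positive-site-count rows), `assignment`
#'   (named character, individual id -> haplotype label), `positions`
#'   (the focal segregating positions) and `realized_S`.
#' @export
gen_haplotypes <- function(config, table) {
  stopifnot(inherits(config, "synthetic_config"), inherits(table, "count_table"))
  counts <- unclass(table)
  baltic <- rowSums(counts) > 0L
  H <- sum(baltic); L <- config$L; S <- config$S
  if (H > 2^min(S, 62)) stop("more haplotypes than 2^S sequences", call. = FALSE)
  n_aux <- sum(!baltic)
  if (S + 2L * n_aux > L)
    stop("L too small for S focal sites plus auxiliary-only mutations",
         call. = FALSE)
  realized <- if (H <= 1L) 0L else S
  if (H > 1L && S < H - 1L)
    stop("need S >= number of haplotypes - 1 for single-step distinctness",
         call. = FALSE)
  res <- with_seed(config$seed, {
    anc <- sample(BASES, L, replace = TRUE)
    pos <- if (H > 1L) sample.int(L, S) else integer(0)
    seqs <- vector("list", H)
    seqs[[1L]] <- anc
    if (H > 1L) {
      parent <- c(NA_integer_, vapply(2:H, function(i)
        sample.int(i - 1L, 1L), 1L))
      # one fresh site per edge, surplus sites spread over random edges
      edge_sites <- vector("list", H)
      first <- pos[seq_len(H - 1L)]
      for (i in 2:H) edge_sites[[i]] <- first[i - 1L]
      extra <- pos[-seq_len(H - 1L)]
      if (length(extra)) {
        tgt <- sample(2:H, length(extra), replace = TRUE)
        for (k in seq_along(extra))
          edge_sites[[tgt[k]]] <- c(edge_sites[[tgt[k]]], extra[k])
      }
      for (i in 2:H)
        seqs[[i]] <- mutate_at(seqs[[parent[i]]], edge_sites[[i]])
    }
    hap_seq <- vapply(seqs, paste, "", collapse = "")
    # auxiliary-only haplotypes: fresh off-focal mutations
    free <- setdiff(seq_len(L), pos)
    aux_seq <- character(n_aux)
    if (n_aux > 0L) {
      aux_pos <- matrix(sample(free, 2L * n_aux), ncol = 2L)
      for (j in seq_len(n_aux)) {
        src <- sample.int(H, 1L)
        aux_seq[j] <- paste(mutate_at(seqs[[src]], aux_pos[j, ]),
                            collapse = "")
      }
    }
    all_seq <- character(nrow(counts))
    all_seq[baltic] <- hap_seq
    all_seq[!baltic] <- aux_seq
    list(all_seq = all_seq, pos = sort(pos))
  })
  if (H == 1L && S > 0L)
    warning("single haplotype: realised segregating sites is 0, not S")

  sites <- colnames(counts)
  ids <- character(sum(counts)); seqv <- character(sum(counts))
  sitev <- character(sum(counts)); hapv <- character(sum(counts))
  k <- 0L; per_site <- setNames(integer(length(sites)), sites)
  for (h in seq_len(nrow(counts))) {
    for (s in sites) {
      c_hs <- counts[h, s]
      if (c_hs > 0L) {
        idx <- per_site[s] + seq_len(c_hs)
        per_site[s] <- per_site[s] + c_hs
        sel <- k + seq_len(c_hs); k <- k + c_hs
        ids[sel] <- sprintf("%s_%03d", s, idx)
        sitev[sel] <- s
        seqv[sel] <- res$all_seq[h]
        hapv[sel] <- rownames(counts)[h]
      }
    }
  }
  records <- seq_records(ids, seqv, sitev)
  list(records = records,
       haplotypes = data.frame(label = rownames(counts), seq = res$all_seq,
                               baltic = baltic, stringsAsFactors = FALSE),
       assignment = setNames(hapv, ids),
       positions = res$pos,
       realized_S = realized)
}

#' Generate a dual-editor call-string pair for one read
#'
#' Emulates two people independently base-calling the same chromatogram.
#' Each position disagrees with probability `disagreement_rate`: one of the
#' two editors (chosen at random) receives a different base or an N. With
#' probability `poor_read_fraction` the read is "poor": `ceiling(L/3)`
#' positions are forced inconsistent, so the downstream one-third filter
#' always rejects it.
#'
#' @param truth a single sequence string (or one-row [seq_records]).
#' @param config a [synthetic_config].
#' @param seed seed for this read; defaults to `config$seed`.
#' @return A list with `calls_a`, `calls_b` (strings of the truth's length)
#'   and logical `poor`.
#' @export
gen_editor_pair <- function(truth, config, seed = config$seed) {
  if (is.data.frame(truth)) truth <- truth$seq[1L]
  chars <- strsplit(truth, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  with_seed(seed, {
    poor <- runif(1) < config$poor_read_fraction
    pos <- if (poor) sample.int(L, ceiling(L / 3)) else
      which(runif(L) < config$disagreement_rate)
    a <- chars; b <- chars
    if (length(pos)) {
      to_a <- runif(length(pos)) < 0.5
      for (k in seq_along(pos)) {
        p <- pos[k]
        alt <- sample(setdiff(c(BASES, "N"), chars[p]), 1L)
        if (to_a[k]) a[p] <- alt else b[p] <- alt
      }
    }
    list(calls_a = paste(a, collapse = ""),
         calls_b = paste(b, collapse = ""),
         poor = poor)
  })
}

#' Generate a sequence repository with duplicate groups and corrupted entries
#'
#' For each group size `g` in `config$duplicate_spec`, one source haplotype
#' is deposited `g` times; every remaining source is deposited once. Each
#' entry is then independently corrupted with probability
#' `config$error_rate`: a corrupted entry is mutated until it matches no
#' source haplotype (an "unsupported variant").
#'
#' @param haplotypes named character vector of source haplotype sequences
#'   (or the `haplotypes` data frame from [gen_haplotypes()]).
#' @param config a [synthetic_config].
#' @param seed seed; defaults to `config$seed`.
#' @return A [seq_records] of repository entries (ids `R001`, ...) with a
#'   `provenance` attribute: data frame `id`, `source` (source haplotype
#'   label) and logical `corrupted`.
#' @export
gen_repository <- function(haplotypes, config, seed = config$seed) {
  if (is.data.frame(haplotypes))
    haplotypes <- setNames(haplotypes$seq, haplotypes$label)
  n_h <- length(haplotypes)
  spec <- config$duplicate_spec
  if (length(spec) > n_h)
    stop("more duplicate groups than source haplotypes", call. = FALSE)
  with_seed(seed, {
    dup_src <- if (length(spec)) sample.int(n_h, length(spec)) else integer(0)
    times <- rep(1L, n_h); times[dup_src] <- spec
    src_idx <- rep(seq_len(n_h), times)
    seqs <- unname(haplotypes[src_idx])
    ids <- sprintf("R%03d", seq_along(seqs))
    corrupted <- runif(length(seqs)) < config$error_rate
    for (i in which(corrupted)) {
      repeat {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        npos <- sample.int(3L, 1L)
        chars <- mutate_at(chars, sample.int(length(chars), npos))
        cand <- paste(chars, collapse = "")
        if (!cand %in% haplotypes) { seqs[i] <- cand; break }
      }
    }
    rec <- seq_records(ids, seqs)
    attr(rec, "provenance") <- data.frame(
      id = ids, source = names(haplotypes)[src_idx],
      corrupted = corrupted, stringsAsFactors = FALSE)
    rec
  })
}
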