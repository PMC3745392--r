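# Repository deduplication and reconciliation against re-edited and
# auxiliary haplotype sets, plus reconstruction of an "erroneous" dataset
# from a haplotype list and a distribution table.

#' Deduplicate a sequence repository
#'
#' Finds identity classes among repository entries. Each distinct sequence
#' is labelled by its smallest member id; groups (classes of size >= 2)
#' are reported with sorted member ids, ordered by size descending then by
#' label.
#'
#' @param records a [seq_records] of repository entries (equal lengths).
#' @return A list with `groups` (list of sorted id vectors, each of size
#'   `>= 2`) and `representatives` (a `haplotype_set` of the distinct
#'   sequences, labelled by smallest member id).
#' @export
dedup_repository <- function(records) {
  check_equal_lengths(records$seq)
  classes <- split(records$id, factor(records$seq,
                                      levels = unique(records$seq)))
  classes <- lapply(classes, function(ids) sort(ids))
  labels <- vapply(classes, `[[`, "", 1L)
  sizes <- lengths(classes)
  ord <- order(-sizes, labels)
  groups <- unname(classes[ord][sizes[ord] >= 2L])
  reps <- data.frame(label = labels, seq = names(classes),
                     n = as.integer(sizes), stringsAsFactors = FALSE,
                     row.names = NULL)
  reps <- reps[order(reps$label), , drop = FALSE]
  rownames(reps) <- NULL
  list(groups = groups,
       representatives = structure(reps,
                                   members = setNames(classes[order(labels)],
                                                      sort(labels)),
                                   class = c("haplotype_set", "data.frame")))
}

# apply a comparison window c(start, length) (1-based) to sequences
apply_window <- function(seqs, window) {
  substr(seqs, window[1L], window[1L] + window[2L] - 1L)
}

#' Classify repository haplotypes by chromatogram support
#'
#' A deduplicated repository haplotype is *supported* when its sequence is
#' exactly identical to a re-edited haplotype; otherwise *aux-supported*
#' when identical to a haplotype of the auxiliary dataset; otherwise
#' *unsupported*. Re-edited haplotypes matching no repository haplotype
#' are *novel*. The corrected reference set is the union of the re-edited
#' haplotypes and the aux-supported repository haplotypes.
#'
#' When repository entries are longer than the re-edited fragments (e.g.
#' untrimmed deposits), pass `window = c(offset, length)` to restrict the
#' longer side to the common analysis window before comparison.
#'
#' @param repo a `haplotype_set` of deduplicated repository haplotypes
#'   (from [dedup_repository()]).
#' @param reedited a `haplotype_set` of re-edited haplotypes, or a named
#'   character vector label -> sequence.
#' @param aux optional auxiliary haplotypes, same forms as `reedited`.
#' @param window optional 1-based `c(start, length)` applied to the longer
#'   sequences; required when lengths differ.
#' @return A list of class `reconciliation_report`; see Details.
#' @details Report fields: `duplicate_groups`, `n_repo_entries`,
#'   `n_repo_distinct`, `supported`, `aux_supported`, `unsupported`
#'   (repository haplotype labels), `novel` (re-edited labels),
#'   `reference_set` (data frame of label + sequence), `support_rate`.
#' @export
classify_support <- function(repo, reedited, aux = NULL, window = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$seq, x$label) else x
  }
  repo_seq <- as_named(repo)
  re_seq <- as_named(reedited)
  aux_seq <- as_named(aux) %||% character(0)

  lens <- c(nchar(repo_seq), nchar(re_seq), nchar(aux_seq))
  if (length(unique(lens)) > 1L) {
    if (is.null(window))
      stop("sequence lengths differ and no comparison window given",
           call. = FALSE)
    target <- window[2L]
    shorten <- function(v) ifelse(nchar(v) > target, apply_window(v, window), v)
    repo_seq <- shorten(repo_seq); re_seq <- shorten(re_seq)
    if (length(aux_seq)) aux_seq <- shorten(aux_seq)
    if (length(unique(nchar(c(repo_seq, re_seq, aux_seq)))) > 1L)
      stop("sequences incomparable even after windowing", call. = FALSE)
  }

  members <- attr(repo, "members")
  n_entries <- if (!is.null(members)) length(unlist(members)) else
    length(repo_seq)
  groups <- if (!is.null(members)) {
    g <- unname(members[lengths(members) >= 2L])
    g[order(-lengths(g), vapply(g, `[[`, "", 1L))]
  } else list()

  supported <- names(repo_seq)[repo_seq %in% re_seq]
  aux_supported <- names(repo_seq)[!repo_seq %in% re_seq &
                                     repo_seq %in% aux_seq]
  unsupported <- setdiff(names(repo_seq), c(supported, aux_supported))
  novel <- names(re_seq)[!re_seq %in% repo_seq]
  reference <- data.frame(
    label = c(names(re_seq), aux_supported),
    seq = c(unname(re_seq), unname(repo_seq[aux_supported])),
    origin = c(rep("re-edited", length(re_seq)),
               rep("repository(aux-supported)", length(aux_supported))),
    stringsAsFactors = FALSE)
  structure(list(duplicate_groups = groups,
                 n_repo_entries = n_entries,
                 n_repo_distinct = length(repo_seq),
                 supported = supported,
                 aux_supported = aux_supported,
                 unsupported = unsupported,
                 novel = novel,
                 reference_set = reference,
                 support_rate = (length(supported) + length(aux_supported)) /
                   length(repo_seq)),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat("Repository reconciliation\n")
  cat(sprintf("  entries: %d, distinct: %d (%d duplicate groups, %d redundant entries)\n",
              x$n_repo_entries, x$n_repo_distinct, length(x$duplicate_groups),
              x$n_repo_entries - x$n_repo_distinct))
  cat(sprintf("  supported: %d, aux-supported: %d, unsupported: %d (support rate %.1f%%)\n",
              length(x$supported), length(x$aux_supported),
              length(x$unsupported), 100 * x$support_rate))
  cat(sprintf("  novel re-edited haplotypes: %d; corrected reference set: %d\n",
              length(x$novel), nrow(x$reference_set)))
  invisible(x)
}

#' Full reconciliation of a repository against re-edited chromatogram data
#'
#' Convenience wrapper: [dedup_repository()] then [classify_support()].
#'
#' @inheritParams classify_support
#' @param repo_records a [seq_records] of raw repository entries.
#' @return A `reconciliation_report`.
#' @export
reconcile <- function(repo_records, reedited, aux = NULL, window = NULL) {
  dd <- dedup_repository(repo_records)
  classify_support(dd$representatives, reedited, aux, window)
}

#' Reconstruct an "erroneous" dataset from haplotypes and a distribution
#'
#' Expands a distribution table into individual records, assuming row `i`
#' of the distribution refers to haplotype `i` of `haplotype_list` by
#' ordinal position (the assumption one is forced to make when a
#' repository's haplotype numbering is the only link to a published
#' distribution). Rows referencing a position beyond the list are skipped
#' with a warning, mirroring the situation where fewer haplotypes were
#' deposited than reported.
#'
#' @param haplotype_list ordered haplotypes: `haplotype_set`, named
#'   character vector, or plain character vector of sequences.
#' @param distribution a [count_table]; row order carries the ordinal
#'   mapping.
#' @return A [seq_records] with one record per counted individual
#'   (ids `<site>_E001`, ...).
#' @export
build_erroneous <- function(haplotype_list, distribution) {
  seqs <- if (is.data.frame(haplotype_list)) haplotype_list$seq
          else as.character(haplotype_list)
  counts <- unclass(distribution)
  n_rows <- nrow(counts)
  usable <- seq_len(min(n_rows, length(seqs)))
  dropped <- setdiff(seq_len(n_rows), usable)
  skipped <- dropped[rowSums(counts[dropped, , drop = FALSE]) > 0L]
  if (length(skipped))
    warning(sprintf(
      "distribution row(s) %s reference haplotypes beyond the %d supplied; skipped",
      paste(skipped, collapse = ","), length(seqs)))
  ids <- character(0); sv <- character(0); qv <- character(0)
  per_site <- setNames(integer(ncol(counts)), colnames(counts))
  for (i in usable) {
    for (s in colnames(counts)) {
      c_is <- counts[i, s]
      if (c_is > 0L) {
        idx <- per_site[s] + seq_len(c_is)
        per_site[s] <- per_site[s] + c_is
        ids <- c(ids, sprintf("%s_E%03d", s, idx))
        sv <- c(sv, rep(s, c_is))
        qv <- c(qv, rep(seqs[i], c_is))
      }
    }
  }
  if (!length(ids)) return(seq_records(character(0), character(0)))
  seq_records(ids, qv, sv)
}
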