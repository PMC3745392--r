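# Zero-mismatch haplotype collapse, count-table construction and
# sharedness summaries.

#' Collapse sequences into haplotypes by exact identity
#'
#' Records are partitioned by exact string equality ("zero mismatches").
#' Records containing any unresolved character (N, ambiguity code, gap)
#' are excluded with a warning by default: wildcard matching could merge
#' distinct haplotypes. Haplotypes are labelled `HT1`, `HT2`, ... by
#' descending member count, ties broken by order of first appearance.
#'
#' @param records a [seq_records] frame of equal-length sequences.
#' @param exclude_ambiguous drop records with unresolved characters
#'   (warning); if `FALSE`, such records are an error.
#' @return A data frame of class `haplotype_set` with columns `label`,
#'   `seq`, `n`, and a `members` attribute (list of member id vectors,
#'   parallel to the rows).
#' @export
collapse_haplotypes <- function(records, exclude_ambiguous = TRUE) {
  if (!nrow(records)) stop("no records to collapse", call. = FALSE)
  check_equal_lengths(records$seq)
  unresolved <- grepl("[^ACGT]", records$seq)
  if (any(unresolved)) {
    if (!exclude_ambiguous)
      stop(sprintf("record '%s' contains unresolved characters",
                   records$id[unresolved][1L]), call. = FALSE)
    warning(sprintf("excluding %d record(s) with unresolved characters from collapse",
                    sum(unresolved)))
    records <- records[!unresolved, , drop = FALSE]
    if (!nrow(records)) stop("no fully resolved records left", call. = FALSE)
  }
  first_seen <- !duplicated(records$seq)
  uniq <- records$seq[first_seen]
  n <- as.integer(table(factor(records$seq, levels = uniq)))
  ord <- order(-n, seq_along(uniq))            # stable: count desc, then appearance
  uniq <- uniq[ord]; n <- n[ord]
  members <- lapply(uniq, function(s) records$id[records$seq == s])
  out <- data.frame(label = paste0("HT", seq_along(uniq)),
                    seq = uniq, n = n, stringsAsFactors = FALSE)
  structure(out, members = setNames(members, out$label),
            class = c("haplotype_set", "data.frame"))
}

#' Build a haplotype-by-site count table
#'
#' `counts[h, s]` is the number of members of haplotype `h` sampled at
#' site `s`. Rows are ordered by descending total, ties by the haplotype
#' order of the input (first appearance). The grand total equals the
#' number of member records.
#'
#' @param haplotypes a `haplotype_set` from [collapse_haplotypes()].
#' @param site_of named character vector mapping member id -> site label.
#' @return A [count_table].
#' @export
build_count_table <- function(haplotypes, site_of) {
  members <- attr(haplotypes, "members")
  all_ids <- unlist(members, use.names = FALSE)
  missing <- setdiff(all_ids, names(site_of))
  if (length(missing))
    stop(sprintf("no site label for record '%s'", missing[1L]), call. = FALSE)
  sites <- unique(unname(site_of[all_ids]))
  if (any(!nzchar(sites))) stop("empty site label", call. = FALSE)
  m <- t(vapply(members, function(ids)
    table(factor(unname(site_of[ids]), levels = sites)),
    integer(length(sites))))
  if (length(sites) == 1L) { m <- matrix(m, ncol = 1L); rownames(m) <- names(members) }
  colnames(m) <- sites
  ord <- order(-rowSums(m), seq_len(nrow(m)))
  m <- m[ord, , drop = FALSE]
  rownames(m) <- paste0("HT", seq_len(nrow(m)))
  count_table(m)
}

#' Sharedness of haplotypes across sites
#'
#' For each haplotype with a positive count, counts the number of sites
#' where it occurs; summarises how many haplotypes occur in exactly
#' 1, 2, ... sites, the proportion of each site's haplotypes that are
#' unique to that site, and the relative frequency of each haplotype among
#' all individuals.
#'
#' @param table a [count_table]; auxiliary-only rows (zero counts) are
#'   ignored.
#' @return A list of class `sharedness_summary`: `n_haplotypes`,
#'   `by_n_sites` (named integer vector, `"1"`, `"2"`, ...),
#'   `prop_unique` (named per-site proportions), `unique_counts`,
#'   `site_hap_counts`, and `freq` (named haplotype relative frequencies,
#'   descending).
#' @export
sharedness <- function(table) {
  counts <- unclass(table)
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  if (!nrow(counts)) stop("empty count table", call. = FALSE)
  n_sites_per_hap <- rowSums(counts > 0L)
  by_n <- table(factor(n_sites_per_hap, levels = seq_len(ncol(counts))))
  present <- counts > 0L
  uniq_site <- colSums(present & n_sites_per_hap == 1L)
  per_site <- colSums(present)
  freq <- sort(rowSums(counts) / sum(counts), decreasing = TRUE)
  structure(list(n_haplotypes = nrow(counts),
                 by_n_sites = setNames(as.integer(by_n), names(by_n)),
                 prop_unique = uniq_site / per_site,
                 unique_counts = uniq_site,
                 site_hap_counts = per_site,
                 freq = freq),
            class = "sharedness_summary")
}

#' @export
print.sharedness_summary <- function(x, ...) {
  cat(sprintf("%d haplotypes; in-k-sites counts: %s\n", x$n_haplotypes,
              paste(sprintf("%s:%d", names(x$by_n_sites), x$by_n_sites),
                    collapse = " ")))
  cat("proportion unique per site:",
      paste(sprintf("%s %.1f%%", names(x$prop_unique), 100 * x$prop_unique),
            collapse = ", "), "\n")
  cat("top frequencies:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$freq, 3)), collapse = ", "),
      "\n")
  invisible(x)
}
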