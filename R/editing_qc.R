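# Dual-editor consensus, the one-third inconsistency filter, and trimming
# of retained reads to the common clean analysis window.

#' Consensus of two independent base-call strings
#'
#' Positions where the two editors agree copy the shared call; positions
#' where they disagree receive the minimal IUPAC code covering both calls
#' (N if either call is N, or if a base is paired with a gap) and count as
#' inconsistent. A read is retained when strictly less than one third of
#' its positions are inconsistent: reads in which one third or more of the
#' nucleotides cannot be scored consistently are classed as poor-quality
#' and rejected (the boundary itself is rejected).
#'
#' @param calls_a,calls_b equal-length call strings from the two editors.
#' @param id read label carried into the result.
#' @return A list of class `edited_read`: `id`, `calls_a`, `calls_b`,
#'   `consensus`, `inconsistent_fraction`, `retained`.
#' @export
consensus_calls <- function(calls_a, calls_b, id = "read") {
  calls_a <- toupper(calls_a); calls_b <- toupper(calls_b)
  if (nchar(calls_a) != nchar(calls_b))
    stop(sprintf("record '%s': call strings differ in length (%d vs %d)",
                 id, nchar(calls_a), nchar(calls_b)), call. = FALSE)
  check_alphabet(calls_a, id); check_alphabet(calls_b, id)
  a <- strsplit(calls_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(calls_b, "", fixed = TRUE)[[1L]]
  cons <- a
  differ <- which(a != b)
  for (p in differ) {
    if (a[p] == "N" || b[p] == "N" || a[p] == "-" || b[p] == "-") {
      cons[p] <- "N"
    } else {
      union_set <- sort(unique(c(IUPAC_SETS[[a[p]]], IUPAC_SETS[[b[p]]])))
      cons[p] <- IUPAC_CODES[[paste(union_set, collapse = "")]]
    }
  }
  frac <- length(differ) / length(a)
  structure(list(id = id, calls_a = calls_a, calls_b = calls_b,
                 consensus = paste(cons, collapse = ""),
                 inconsistent_fraction = frac,
                 retained = frac < 1 / 3),
            class = "edited_read")
}

#' @export
print.edited_read <- function(x, ...) {
  cat(sprintf("edited_read '%s': %d bp, %.1f%% inconsistent, %s\n",
              x$id, nchar(x$consensus), 100 * x$inconsistent_fraction,
              if (x$retained) "retained" else "rejected"))
  invisible(x)
}

#' Partition edited reads by the quality filter
#'
#' @param reads list of `edited_read` objects (from [consensus_calls()]).
#' @return A list with `retained` and `discarded` sublists; the two are a
#'   partition of the input.
#' @export
filter_reads <- function(reads) {
  keep <- vapply(reads, function(r) isTRUE(r$retained), TRUE)
  message(sprintf("quality filter: %d of %d reads retained",
                  sum(keep), length(reads)))
  list(retained = reads[keep], discarded = reads[!keep])
}

#' Trim retained reads to the maximal shared clean window
#'
#' Reads share a coordinate system (equal lengths); leading and trailing
#' low-quality runs are marked N. The output window is the intersection of
#' every read's span between its first and last non-N position, so all
#' outputs have equal length and no read contributes a terminal N run.
#'
#' @param reads list of `edited_read` objects, or a [seq_records] frame.
#' @param site_of optional named character vector id -> site label for the
#'   output records.
#' @return A [seq_records] of the trimmed consensus sequences, with
#'   attribute `window` (1-based `c(start, end)`).
#' @export
trim_common_window <- function(reads, site_of = NULL) {
  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- reads$seq; sites <- reads$site
  } else {
    ids <- vapply(reads, `[[`, "", "id")
    seqs <- vapply(reads, `[[`, "", "consensus")
    sites <- rep("", length(ids))
  }
  if (!length(seqs)) stop("no reads to trim", call. = FALSE)
  check_equal_lengths(seqs, "reads")
  m <- seq_chars(seqs)
  first <- apply(m, 1L, function(r) {
    w <- which(r != "N"); if (length(w)) w[1L] else NA_integer_
  })
  last <- apply(m, 1L, function(r) {
    w <- which(r != "N"); if (length(w)) w[length(w)] else NA_integer_
  })
  if (anyNA(first))
    stop(sprintf("empty window: read '%s' is all N", ids[which(is.na(first))[1L]]),
         call. = FALSE)
  start <- max(first); end <- min(last)
  if (start > end) stop("empty window: reads share no clean positions",
                        call. = FALSE)
  if (!is.null(site_of)) sites <- unname(site_of[ids])
  out <- seq_records(ids, substr(seqs, start, end),
                     ifelse(is.na(sites), "", sites))
  attr(out, "window") <- c(start = start, end = end)
  out
}
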