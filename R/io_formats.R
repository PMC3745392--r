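# FASTA and count-table IO, plus the two core containers:
#  * seq_records   -- data.frame(id, site, seq), one aligned sequence per row
#  * count_table   -- haplotype x site integer matrix with optional
#                     auxiliary-dataset counts and old-ID annotations

#' Construct a set of sequence records
#'
#' The basic container for aligned sequences: a data frame with columns
#' `id` (unique label, e.g. accession or sample code), `site` (breeding-site
#' label, empty string for repository records with no sampling site) and
#' `seq` (uppercase sequence over A/C/G/T, IUPAC ambiguity codes, N and `-`).
#'
#' @param id character vector of unique record labels.
#' @param seq character vector of sequences (same length as `id`).
#' @param site character vector of site labels, recycled; `""` when unknown.
#' @return A `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, seq, site = "") {
  id <- as.character(id); seq <- toupper(as.character(seq))
  site <- rep_len(as.character(site), length(id))
  if (length(seq) != length(id))
    stop("id and seq must have the same length", call. = FALSE)
  if (anyDuplicated(id))
    stop(sprintf("duplicate record id '%s'", id[duplicated(id)][1L]),
         call. = FALSE)
  if (any(!nzchar(seq)))
    stop("empty sequence not permitted", call. = FALSE)
  for (i in seq_along(seq)) check_alphabet(seq[i], id[i])
  structure(data.frame(id = id, site = site, seq = seq,
                       stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

#' Read aligned sequences from a FASTA file
#'
#' Headers follow the `id|site` dialect: everything before the first `|`
#' is the record id, everything after it the breeding-site label. Headers
#' without a `|` give records with an empty site.
#'
#' @param path path to a FASTA file.
#' @param site_sep separator between id and site in the header.
#' @return A [seq_records] data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path, site_sep = "|") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(seq_records(character(0), character(0)))
  headers <- names(set)
  if (any(!nzchar(headers)))
    stop(sprintf("%s: malformed FASTA header (empty) at record %d",
                 path, which(!nzchar(headers))[1L]), call. = FALSE)
  pos <- regexpr(site_sep, headers, fixed = TRUE)
  id <- ifelse(pos > 0L, substr(headers, 1L, pos - 1L), headers)
  site <- ifelse(pos > 0L, substring(headers, pos + nchar(site_sep)), "")
  seq_records(id, as.character(set), site)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` returns `x`.
#' Sequences are wrapped at 70 columns.
#'
#' @param records a [seq_records] data frame.
#' @param path output path.
#' @param site_sep header separator, see [read_fasta()].
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, site_sep = "|") {
  headers <- ifelse(nzchar(records$site),
                    paste0(records$id, site_sep, records$site),
                    records$id)
  set <- Biostrings::BStringSet(setNames(as.character(records$seq), headers))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct a haplotype-by-site count table
#'
#' The tabular summary of a haplotype survey: one row per haplotype, one
#' column per sampling site, integer counts of individuals. Two annotation
#' vectors travel with the matrix: `aux`, counts in an auxiliary
#' (unpublished) dataset, and `old_id`, a free-text mapping to repository
#' haplotype ids (`"New"` for haplotypes absent from the repository).
#' Rows with all-zero site counts must have a positive `aux` count
#' (auxiliary-only haplotypes).
#'
#' @param counts non-negative integer matrix with haplotype rownames and
#'   site colnames.
#' @param aux optional non-negative integer vector, one per row.
#' @param old_id optional character vector, one per row.
#' @return A matrix of class `count_table` with `aux`/`old_id` attributes.
#' @export
count_table <- function(counts, aux = NULL, old_id = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    rownames(counts) <- paste0("HT", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("count table needs site column names", call. = FALSE)
  aux <- as.integer(aux %||% rep(0L, nrow(counts)))
  old_id <- as.character(old_id %||% rep("", nrow(counts)))
  stopifnot(length(aux) == nrow(counts), length(old_id) == nrow(counts))
  if (any(rowSums(counts) == 0L & aux == 0L))
    stop("haplotype row with no positive count and no auxiliary count",
         call. = FALSE)
  structure(counts, aux = aux, old_id = old_id,
            class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d haplotypes x %d sites, %d individuals\n",
              nrow(x), ncol(x), sum(x)))
  df <- as.data.frame(unclass(x))
  df$aux <- attr(x, "aux")
  df$old_id <- attr(x, "old_id")
  print(df, ...)
  invisible(x)
}

#' Read a count table from TSV
#'
#' Expects a tab-separated file with a `haplotype` column, one column per
#' site, and optional `aux`, `old_id` and `Total` columns. Lines starting
#' with `#` are comments. A `Total` row and/or column, when present, is
#' verified against the computed sums and then dropped; a mismatch is an
#' error.
#'
#' @param path path to a TSV file.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"haplotype" %in% names(df))
    stop("count table must have a 'haplotype' column", call. = FALSE)
  reserved <- c("haplotype", "aux", "old_id", "Total")
  site_cols <- setdiff(names(df), reserved)
  if (!length(site_cols)) stop("no site columns found", call. = FALSE)

  total_row <- df$haplotype == "Total"
  body <- df[!total_row, , drop = FALSE]
  m <- as.matrix(body[site_cols])
  if (any(is.na(m))) m[is.na(m)] <- 0
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- body$haplotype

  if (any(total_row)) {
    stated <- as.integer(unlist(df[total_row, site_cols][1L, ]))
    if (!identical(stated, as.integer(unname(colSums(m)))))
      stop("Total row disagrees with column sums", call. = FALSE)
  }
  if ("Total" %in% names(df)) {
    stated <- as.integer(body$Total)
    if (!identical(stated, as.integer(unname(rowSums(m)))))
      stop("Total column disagrees with row sums", call. = FALSE)
  }
  aux <- if ("aux" %in% names(body)) {
    a <- body$aux; a[is.na(a)] <- 0L; as.integer(a)
  } else NULL
  old_id <- if ("old_id" %in% names(body)) {
    o <- as.character(body$old_id); o[is.na(o)] <- ""; o
  } else NULL
  count_table(m, aux = aux, old_id = old_id)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]. Emits a `Total` row so that readers can
#' verify the sums.
#'
#' @param table a [count_table].
#' @param path output path.
#' @param comment optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, comment = NULL) {
  df <- data.frame(haplotype = rownames(table), unclass(table),
                   aux = attr(table, "aux"), old_id = attr(table, "old_id"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  tot <- data.frame(haplotype = "Total",
                    as.list(colSums(unclass(table))),
                    aux = sum(attr(table, "aux")), old_id = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- rbind(df, tot)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to a packaged example/reference data file
#'
#' @param file file name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
hapaudit_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "hapaudit")))
  system.file("extdata", file, package = "hapaudit", mustWork = TRUE)
}

#' Packaged Baltic grey seal haplotype distribution (re-edited dataset)
#'
#' The distribution of the 38 grey seal control-region haplotypes across
#' the three Baltic breeding sites (Bay of Bothnia `BB`, Estonia `EST`,
#' Stockholm Archipelago `STA`), with auxiliary-dataset counts and the
#' mapping to the originally deposited repository haplotype ids.
#' Haplotypes 36-38 are auxiliary-only: zero Baltic counts.
#'
#' @return A [count_table] with 38 rows and sites BB/EST/STA
#'   (column totals 39/36/28, grand total 103).
#' @export
reference_distribution <- function() {
  read_count_table(hapaudit_example("grey_seal_reedited_distribution.tsv"))
}

#' Packaged repository duplicate groups
#'
#' The six groups of repository entries that proved to be identical
#' sequences deposited under different haplotype ids.
#'
#' @return A data frame with columns `group` and `members`
#'   (comma-separated repository haplotype ids).
#' @export
reference_duplicate_groups <- function() {
  read.delim(hapaudit_example("grey_seal_repository_duplicates.tsv"),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged synthetic stand-in for the uncorrected ("erroneous") distribution
#'
#' The uncorrected dataset in the grey seal reassessment was rebuilt from
#' repository haplotypes 1-40 and a published distribution table that is not
#' reproduced here; this packaged table is a synthetic stand-in with the
#' same shape: 40 haplotype rows over BB/EST/STA with column totals
#' 40/40/28 (108 individuals).
#'
#' @return A [count_table] with 40 rows.
#' @export
synthetic_erroneous_distribution <- function() {
  read_count_table(hapaudit_example("erroneous_distribution_synthetic.tsv"))
}
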