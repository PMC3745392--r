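# Summary statistics for haplotype surveys: Nei's unbiased haplotype
# diversity with its sampling variance, nucleotide diversity with a
# Tajima-style total variance, segregating sites, base composition, the
# chi-square test on site-unique haplotype proportions, and a t-based
# comparison of two diversity estimates.

#' Nei's unbiased haplotype diversity
#'
#' \deqn{h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)}
#' with sampling variance
#' \deqn{V(h) = \frac{2}{n(n-1)}\Bigl\{2(n-2)\bigl[\sum p_i^3 -
#'   (\sum p_i^2)^2\bigr] + \sum p_i^2 - (\sum p_i^2)^2\Bigr\}}
#' (Nei 1987, eqs. 8.4 and 8.12) and a normal 95% CI
#' `h +/- 1.96 sqrt(V)` truncated to `[0, 1]`.
#'
#' @param counts non-negative integer vector of haplotype counts
#'   (zeros are dropped); `sum(counts) >= 2`.
#' @return A list `h`, `V_h`, `ci` (length-2 numeric).
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  p <- counts / n
  sp2 <- sum(p^2); sp3 <- sum(p^3)
  h <- n / (n - 1) * (1 - sp2)
  V <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  half <- 1.96 * sqrt(V)
  ci <- c(max(0, h - half), min(1, h + half))
  list(h = h, V_h = V, ci = ci)
}

#' Pairwise difference matrix between haplotypes
#'
#' `d[i, j]` counts the positions at which haplotypes `i` and `j` carry
#' different resolved bases; positions where either sequence has an
#' unresolved character (N, ambiguity code, gap) are pairwise-deleted.
#'
#' @param haplotypes a `haplotype_set`, named character vector, or plain
#'   character vector of equal-length sequences.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
pairwise_diff_matrix <- function(haplotypes) {
  seqs <- if (is.data.frame(haplotypes)) haplotypes$seq
          else as.character(haplotypes)
  labels <- if (is.data.frame(haplotypes)) haplotypes$label
            else names(haplotypes)
  check_equal_lengths(seqs, "haplotypes")
  m <- seq_chars(seqs)
  res <- matrix(m %in% BASES, nrow = nrow(m))
  k <- length(seqs)
  d <- matrix(0L, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        use <- res[i, ] & res[j, ]
        d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use])
      }
    }
  }
  dimnames(d) <- list(labels, labels)
  d
}

#' Nucleotide diversity
#'
#' \deqn{\pi = \frac{n}{n-1} \sum_{i \ne j} p_i p_j \frac{d_{ij}}{L}}
#' the unbiased per-site average number of differences between two
#' randomly drawn sequences, which equals the plain mean of
#' `d/L` over all unordered individual pairs. The variance is Tajima's
#' (1983) total variance
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L} +
#'   \frac{2(n^2+n+3)}{9n(n-1)}\pi^2,}
#' which includes the evolutionary (stochastic) term and therefore gives
#' the wide intervals typical of single-locus reports; the pure sampling
#' contribution is returned separately as `V_components`.
#'
#' @param counts haplotype counts aligned with the rows of `d`.
#' @param d pairwise difference matrix from [pairwise_diff_matrix()].
#' @param L sequence length (sites).
#' @return A list `pi`, `V_pi`, `ci` (truncated at 0), `V_components`
#'   (named: `sampling`, `stochastic`).
#' @export
nucleotide_diversity <- function(counts, d, L) {
  counts <- as.numeric(counts)
  if (length(counts) != nrow(d))
    stop("counts do not match the distance matrix dimension", call. = FALSE)
  if (L <= 0) stop("L must be positive", call. = FALSE)
  n <- sum(counts)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  p <- counts / n
  pi_hat <- n / (n - 1) * as.numeric(t(p) %*% (d / L) %*% p)
  v_samp <- (n + 1) / (3 * (n - 1)) * pi_hat / L
  v_stoch <- 2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  V <- v_samp + v_stoch
  half <- 1.96 * sqrt(V)
  list(pi = pi_hat, V_pi = V,
       ci = c(max(0, pi_hat - half), pi_hat + half),
       V_components = c(sampling = v_samp, stochastic = v_stoch))
}

#' Number of segregating (polymorphic) sites
#'
#' Counts alignment columns with at least two distinct resolved bases.
#'
#' @inheritParams pairwise_diff_matrix
#' @return Integer count.
#' @export
segregating_sites <- function(haplotypes) {
  seqs <- if (is.data.frame(haplotypes)) haplotypes$seq
          else as.character(haplotypes)
  check_equal_lengths(seqs, "haplotypes")
  m <- seq_chars(seqs)
  sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% BASES])) >= 2L
  }))
}

#' Base composition of a sequence set
#'
#' Percentages of A, C, G and T over resolved bases only, plus GC content.
#'
#' @param records a [seq_records] frame or character vector of sequences.
#' @return Named numeric vector `A`, `C`, `G`, `T`, `GC` (percent).
#' @export
base_composition <- function(records) {
  seqs <- if (is.data.frame(records)) records$seq else as.character(records)
  if (!length(seqs)) stop("no sequences", call. = FALSE)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  chars <- chars[chars %in% BASES]
  tab <- table(factor(chars, levels = BASES))
  pct <- 100 * as.numeric(tab) / sum(tab)
  c(setNames(pct, BASES), GC = pct[2L] + pct[3L])
}

# Pearson chi-square without continuity correction on a contingency table
pearson_chisq <- function(obs) {
  if (any(obs < 0)) stop("negative cell", call. = FALSE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) stop("zero margin in contingency table", call. = FALSE)
  stat <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = expected)
}

#' Chi-square test on the proportion of site-unique haplotypes
#'
#' Builds the 2 x (number of sites) contingency table of unique versus
#' non-unique haplotypes per site (a haplotype present at several sites
#' contributes a non-unique count to each of them) and applies Pearson's
#' chi-square without continuity correction, df = sites - 1.
#'
#' @param table a [count_table] with at least 2 site columns.
#' @return A list of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`.
#' @export
chi_square_unique <- function(table) {
  if (ncol(table) < 2L) stop("need at least 2 sites", call. = FALSE)
  sh <- sharedness(table)
  if (any(sh$site_hap_counts == 0))
    stop("site with zero haplotypes", call. = FALSE)
  obs <- rbind(unique = sh$unique_counts,
               shared = sh$site_hap_counts - sh$unique_counts)
  out <- pearson_chisq(obs)
  structure(out, class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.2f, df = %d, P = %.3f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare two diversity estimates by a two-tailed t-test
#'
#' \eqn{t = |s_1 - s_2| / \sqrt{se_1^2 + se_2^2}} with a two-tailed
#' p-value from the t distribution on the supplied degrees of freedom.
#' The standard errors are caller-supplied (e.g. `sqrt(V_h)` or
#' `sqrt(V_pi)`).
#'
#' @param stat1,stat2 the two estimates.
#' @param se1,se2 their standard errors (not both zero).
#' @param df degrees of freedom (`>= 1`).
#' @return A list `t`, `p`.
#' @export
compare_diversity <- function(stat1, se1, stat2, se2, df) {
  if (se1 < 0 || se2 < 0) stop("negative standard error", call. = FALSE)
  pooled <- sqrt(se1^2 + se2^2)
  if (pooled == 0) stop("zero pooled standard error", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  t_stat <- abs(stat1 - stat2) / pooled
  list(t = t_stat, p = 2 * pt(t_stat, df, lower.tail = FALSE))
}
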