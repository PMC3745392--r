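# One-level analysis of molecular variance (Excoffier, Smouse & Quattro
# 1992) on haplotype sequences: SSD decomposition over squared pairwise
# differences, variance components with the unequal-sample-size
# coefficient, Phi-ST, and a label-permutation test.

# Squared-distance matrix between individuals: the pairwise difference
# count serves as the squared Euclidean distance (the conventional choice
# for haplotypic data).
individual_distances <- function(records) {
  check_equal_lengths(records$seq)
  f <- factor(records$seq, levels = unique(records$seq))
  dh <- pairwise_diff_matrix(levels(f))
  idx <- as.integer(f)
  dh[idx, idx, drop = FALSE]
}

# SSD decomposition and Phi for a given population assignment.
amova_components <- function(D, pop) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ssd_total <- sum(D) / (2 * N)
  ssd_within <- 0
  n_p <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    n_p[k] <- length(idx)
    ssd_within <- ssd_within + sum(D[idx, idx]) / (2 * n_p[k])
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1L
  df_within <- N - P
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n_prime <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_b <- ms_within
  sigma_a <- (ms_among - ms_within) / n_prime
  denom <- sigma_a + sigma_b
  phi <- if (denom > 0) sigma_a / denom else 0
  list(ssd = c(among = ssd_among, within = ssd_within, total = ssd_total),
       df = c(among = df_among, within = df_within, total = N - 1L),
       ms = c(among = ms_among, within = ms_within),
       n_prime = n_prime, sigma_a = sigma_a, sigma_b = sigma_b, phi = phi)
}

pop_assignment <- function(records, grouping = NULL) {
  site <- records$site
  if (any(!nzchar(site))) stop("records without a site label", call. = FALSE)
  if (is.null(grouping)) return(site)
  missing <- setdiff(unique(site), names(grouping))
  if (length(missing))
    stop(sprintf("grouping omits site '%s'", missing[1L]), call. = FALSE)
  unname(grouping[site])
}

#' One-level AMOVA with Phi-ST
#'
#' Partitions the squared pairwise differences between haplotype sequences
#' into among- and within-population sums of squares, derives variance
#' components using the standard unequal-sample-size coefficient
#' \eqn{n' = (N - \sum n_p^2 / N)/(P-1)}, and reports
#' \eqn{\Phi_{ST} = \sigma_a^2 / (\sigma_a^2 + \sigma_b^2)}. A negative
#' among-population component is retained internally but the reported
#' Phi-ST is clamped at 0, which is why unstructured datasets print as
#' `0.000` rather than small negative values.
#'
#' @param records a [seq_records] with site labels.
#' @param grouping optional named character vector site -> population;
#'   by default every site is its own population.
#' @param label description stored in the result.
#' @return A list of class `amova_result`: `label`, `ssd`, `df`, `ms`,
#'   `n_prime`, `sigma_a`, `sigma_b`, `phi_st`, `phi_st_reported`,
#'   and (after [amova_permutation()]) `p_value`, `n_perm`, `seed`.
#' @export
amova_fst <- function(records, grouping = NULL, label = NULL) {
  pop <- pop_assignment(records, grouping)
  pops <- unique(pop)
  if (length(pops) < 2L) stop("single population", call. = FALSE)
  sizes <- table(pop)
  if (any(sizes < 2L))
    stop(sprintf("population '%s' has fewer than 2 members",
                 names(sizes)[sizes < 2L][1L]), call. = FALSE)
  D <- individual_distances(records)
  comp <- amova_components(D, pop)
  structure(c(list(label = label %||% paste(pops, collapse = " vs ")),
              comp,
              list(phi_st = comp$phi,
                   phi_st_reported = max(comp$phi, 0),
                   p_value = NA_real_, n_perm = 0L, seed = NA_integer_)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: %s\n", x$label))
  tab <- data.frame(df = x$df[c("among", "within")],
                    SSD = x$ssd[c("among", "within")],
                    MS = x$ms)
  print(round(tab, 4))
  cat(sprintf("sigma_a = %.4f, sigma_b = %.4f, Phi_ST = %.3f",
              x$sigma_a, x$sigma_b, x$phi_st_reported))
  if (!is.na(x$p_value))
    cat(sprintf(" (P = %.3f, %d permutations, seed %d)",
                x$p_value, x$n_perm, x$seed))
  cat("\n")
  invisible(x)
}

#' Permutation test for AMOVA Phi-ST
#'
#' Individuals are shuffled among populations holding sample sizes fixed;
#' the p-value is \eqn{(1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(n_{perm}+1)},
#' so it is always positive.
#'
#' @inheritParams amova_fst
#' @param n_perm number of permutations (`>= 1`).
#' @param seed integer seed; results are reproducible given the seed.
#' @return An `amova_result` with `p_value`, `n_perm` and `seed` filled in.
#' @export
amova_permutation <- function(records, grouping = NULL, n_perm = 10000L,
                              seed = 1L, label = NULL) {
  stopifnot(n_perm >= 1L)
  res <- amova_fst(records, grouping, label)
  pop <- pop_assignment(records, grouping)
  D <- individual_distances(records)
  obs <- res$phi_st
  exceed <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      phi_p <- amova_components(D, sample(pop))$phi
      if (phi_p >= obs - 1e-12) count <- count + 1L
    }
    count
  })
  res$p_value <- (1 + exceed) / (n_perm + 1)
  res$n_perm <- as.integer(n_perm)
  res$seed <- as.integer(seed)
  res
}

#' AMOVA over several site poolings
#'
#' Runs one permutation AMOVA per partition of the sites into populations,
#' e.g. to test a pooled pair of breeding sites against the third.
#'
#' @inheritParams amova_permutation
#' @param pools list of partitions; each partition is a list of character
#'   vectors of site labels covering every site in `records`.
#' @return A list of `amova_result`, one per partition.
#' @export
pooled_runs <- function(records, pools, n_perm = 10000L, seed = 1L) {
  sites <- unique(records$site)
  lapply(pools, function(partition) {
    if (!is.list(partition)) partition <- as.list(partition)
    covered <- unlist(partition)
    missing <- setdiff(sites, covered)
    if (length(missing))
      stop(sprintf("partition omits site '%s'", missing[1L]), call. = FALSE)
    if (length(partition) < 2L) stop("single population", call. = FALSE)
    grouping <- unlist(lapply(partition, function(g)
      setNames(rep(paste(g, collapse = "+"), length(g)), g)))
    amova_permutation(records, grouping, n_perm, seed,
                      label = paste(vapply(partition, paste, "",
                                           collapse = "+"),
                                    collapse = " vs "))
  })
}
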