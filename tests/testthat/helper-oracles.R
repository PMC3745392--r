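# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are written as plain loops/enumeration, independent of
# the implementation paths they check.

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

rand_records <- function(n, L = 20, sites = c("BB", "EST", "STA")) {
  seq_records(sprintf("r%03d", seq_len(n)),
              vapply(seq_len(n), function(i) rand_seq(L), ""),
              sample(sites, n, replace = TRUE))
}

# position-by-position difference count with pairwise deletion
oracle_diff <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n <- 0L
  for (p in seq_along(a)) {
    if (a[p] %in% bases && b[p] %in% bases && a[p] != b[p]) n <- n + 1L
  }
  n
}

# mean pairwise difference per site over all individual pairs
oracle_pi <- function(seqs) {
  n <- length(seqs); L <- nchar(seqs[1])
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + oracle_diff(seqs[i], seqs[j]) / L
    np <- np + 1
  }
  tot / np
}

# explicit sums-of-squares AMOVA decomposition (Excoffier one-level),
# double loops throughout
oracle_amova <- function(seqs, pop) {
  N <- length(seqs)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    D[i, j] <- oracle_diff(seqs[i], seqs[j])
  ssd_total <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) ssd_total <- ssd_total + D[i, j]
  ssd_total <- ssd_total / (2 * N)
  pops <- unique(pop)
  ssd_within <- 0
  for (pp in pops) {
    idx <- which(pop == pp)
    s <- 0
    for (i in idx) for (j in idx) s <- s + D[i, j]
    ssd_within <- ssd_within + s / (2 * length(idx))
  }
  P <- length(pops)
  n_p <- sapply(pops, function(pp) sum(pop == pp))
  ms_among <- (ssd_total - ssd_within) / (P - 1)
  ms_within <- ssd_within / (N - P)
  n_prime <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ms_among - ms_within) / n_prime
  sigma_b <- ms_within
  list(ssd_among = ssd_total - ssd_within, ssd_within = ssd_within,
       ssd_total = ssd_total, sigma_a = sigma_a, sigma_b = sigma_b,
       phi = if (sigma_a + sigma_b > 0) sigma_a / (sigma_a + sigma_b) else 0)
}

# union of all minimum spanning trees by exhaustive enumeration
oracle_msn_edges <- function(d) {
  n <- nrow(d)
  if (n == 1) return(data.frame(i = integer(0), j = integer(0)))
  pairs <- t(combn(n, 2))
  # is the edge subset `sel` (row indices into pairs) a spanning tree?
  is_tree <- function(sel) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in sel) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri == rj) return(FALSE)
      parent[ri] <- rj
    }
    TRUE
  }
  subsets <- combn(nrow(pairs), n - 1, simplify = FALSE)
  weights <- vapply(subsets, function(sel)
    if (is_tree(sel)) sum(d[pairs[sel, , drop = FALSE]]) else Inf, 0)
  best <- min(weights)
  in_msn <- unique(unlist(subsets[weights == best]))
  data.frame(i = pairs[in_msn, 1], j = pairs[in_msn, 2])
}

# build a small synthetic world shared by several tests
study_world <- function(seed = 1) simulate_study(seed)

# count_table -> bare integer matrix (drop aux/old_id annotations)
bare_counts <- function(x) {
  m <- unclass(x)
  attr(m, "aux") <- NULL
  attr(m, "old_id") <- NULL
  m
}
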