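# Internal helpers shared across modules.

# Permitted sequence alphabet: the four bases, IUPAC ambiguity codes,
# N and the gap character.
SEQ_ALPHABET <- c("A", "C", "G", "T",
                  "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of bases it covers.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base-set (sorted, collapsed) -> minimal IUPAC code
IUPAC_CODES <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All generators route through this
# so no function touches global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

check_alphabet <- function(seq, id = "?") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% SEQ_ALPHABET)
  if (length(bad)) {
    stop(sprintf("record '%s': illegal character '%s' at position %d",
                 id, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

seq_chars <- function(seqs) {
  # character matrix, one row per sequence (equal lengths assumed)
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

is_resolved <- function(ch) ch %in% BASES

check_equal_lengths <- function(seqs, what = "sequences") {
  if (length(unique(nchar(seqs))) > 1L)
    stop(sprintf("%s must have equal lengths", what), call. = FALSE)
  invisible(TRUE)
}
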