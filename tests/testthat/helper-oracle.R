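# Independent brute-force oracle for global alignment with affine gaps.
# Enumerates every global alignment as a move string over M (pair),
# I (gap in b, consumes a), D (gap in a, consumes b), scores each by
# explicit gap-run accounting, and returns the maximum. Kept free of any
# dynamic programming so it is independent of the aligner it checks.

# All move strings for sequence lengths la, lb (cached per shape).
.move_cache <- new.env(parent = emptyenv())
enumerate_moves <- function(la, lb) {
  key <- paste(la, lb)
  if (!is.null(.move_cache[[key]])) return(.move_cache[[key]])
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return("")
    out <- character(0)
    if (i > 0L && j > 0L) out <- c(out, paste0(rec(i - 1L, j - 1L), "M"))
    if (i > 0L) out <- c(out, paste0(rec(i - 1L, j), "I"))
    if (j > 0L) out <- c(out, paste0(rec(i, j - 1L), "D"))
    out
  }
  res <- rec(la, lb)
  .move_cache[[key]] <- res
  res
}

# Score one move string. Gap runs cost open + extend * len; a run is
# terminal (free under the free-terminal-gap policy) iff it touches the
# first or last alignment column -- the standard ends-free convention, in
# which at most one sequence may leave residues unaligned at each end.
score_moves <- function(moves, a, b, scheme) {
  mv <- strsplit(moves, "", fixed = TRUE)[[1]]
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ia <- cumsum(mv != "D")
  ib <- cumsum(mv != "I")
  subst <- 0
  mpos <- which(mv == "M")
  if (length(mpos))
    subst <- sum(scheme$substitution[cbind(ca[ia[mpos]], cb[ib[mpos]])])
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap_cost <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k] == "M") next
    terminal <- starts[k] == 1L || ends[k] == length(mv)
    if (scheme$terminal_gaps == "free" && terminal) next
    gap_cost <- gap_cost + scheme$gap_open + scheme$gap_extend * r$lengths[k]
  }
  subst - gap_cost
}

brute_force_align_score <- function(a, b, scheme = scoring_scheme()) {
  moves <- enumerate_moves(nchar(a), nchar(b))
  max(vapply(moves, score_moves, 0, a = a, b = b, scheme = scheme,
             USE.NAMES = FALSE))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}
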