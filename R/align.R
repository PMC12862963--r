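#' Optimal global pairwise alignment of two TK-region sequences
#'
#' Needleman-Wunsch alignment with affine gap penalties, delegated to
#' \code{Biostrings::pairwiseAlignment}. With the default scheme terminal
#' gaps are free (overlap-style global alignment). Percent identity is
#' computed over columns where both sequences place a residue; \code{X}
#' never counts as identical.
#'
#' @param a,b character strings of residues, or \code{tk_record} objects.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return An object of class \code{"tk_alignment"}: a list with
#'   \code{aligned_a}, \code{aligned_b} (equal-length gapped strings),
#'   \code{score}, \code{n_identical}, \code{n_aligned_columns},
#'   \code{identity_pct}.
#' @export
#' @examples
#' aln <- tk_align("ACDE", "ACDD")
#' aln$identity_pct  # 75
tk_align <- function(a, b, scheme = scoring_scheme()) {
  a <- as_residues(a)
  b <- as_residues(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align an empty sequence")
  type <- if (scheme$terminal_gaps == "free") "overlap" else "global"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$substitution,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = type)
  full <- full_gapped_strings(a, b, pa)
  alignment_result(full$a, full$b, Biostrings::score(pa))
}

# Overlap-type alignments clip unaligned terminal flanks from the aligned
# strings; re-attach them as free terminal gap columns so that removing
# gaps recovers the input sequences and positions can be mapped.
full_gapped_strings <- function(a, b, pa, i = 1L) {
  ga <- as.character(Biostrings::alignedPattern(pa))[i]
  gb <- as.character(Biostrings::alignedSubject(pa))[i]
  sa <- BiocGenerics::start(Biostrings::pattern(pa))[i]
  ea <- BiocGenerics::end(Biostrings::pattern(pa))[i]
  sb <- BiocGenerics::start(Biostrings::subject(pa))[i]
  eb <- BiocGenerics::end(Biostrings::subject(pa))[i]
  pre_a <- substr(a, 1L, sa - 1L); post_a <- substr(a, ea + 1L, nchar(a))
  pre_b <- substr(b, 1L, sb - 1L); post_b <- substr(b, eb + 1L, nchar(b))
  gp <- function(n) strrep("-", n)
  list(a = paste0(pre_a, gp(nchar(pre_b)), ga, post_a, gp(nchar(post_b))),
       b = paste0(gp(nchar(pre_a)), pre_b, gb, gp(nchar(post_a)), post_b))
}

# Assemble a tk_alignment from two gapped strings and a score.
alignment_result <- function(aligned_a, aligned_b, score) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb & ca != "X"
  n_cols <- sum(both)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = unname(score),
                 n_identical = sum(ident),
                 n_aligned_columns = n_cols,
                 identity_pct = if (n_cols > 0) 100 * sum(ident) / n_cols
                                else NA_real_),
            class = "tk_alignment")
}

#' @export
print.tk_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, identity %.1f%% (%d/%d columns)\n",
              x$score, x$identity_pct, x$n_identical, x$n_aligned_columns))
  invisible(x)
}

as_residues <- function(x) {
  if (inherits(x, "tk_record")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a residue string or tk_record")
}

#' All pairwise alignment scores and identities within a sequence set
#'
#' Aligns every unordered pair (and each sequence against itself) and
#' returns square symmetric matrices of raw scores and percent identities.
#' Alignments are batched per subject through the vectorised
#' \code{pairwiseAlignment} interface.
#'
#' @param set a \code{tk_set}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param identities logical; also compute the identity matrix (slower,
#'   needs the aligned strings).
#' @return list with \code{ids}, \code{score} matrix and (optionally)
#'   \code{identity} matrix.
#' @export
pairwise_scores <- function(set, scheme = scoring_scheme(),
                            identities = FALSE) {
  recs <- set$records
  n <- length(recs)
  if (n < 2L) stop("need at least two sequences")
  ids <- vapply(recs, `[[`, "", "id")
  seqs <- Biostrings::AAStringSet(vapply(recs, `[[`, "", "residues"))
  type <- if (scheme$terminal_gaps == "free") "overlap" else "global"
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  P <- if (identities) matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    pa <- Biostrings::pairwiseAlignment(
      seqs[seq_len(j)], seqs[[j]],
      substitutionMatrix = scheme$substitution,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      type = type)
    sc <- Biostrings::score(pa)
    S[seq_len(j), j] <- sc
    S[j, seq_len(j)] <- sc
    if (identities) {
      # identity only needs the aligned core: clipped terminal flanks
      # contribute no columns where both sequences place a residue
      ga <- as.character(Biostrings::alignedPattern(pa))
      gb <- as.character(Biostrings::alignedSubject(pa))
      for (i in seq_len(j)) {
        p <- alignment_result(ga[i], gb[i], sc[i])$identity_pct
        P[i, j] <- p
        P[j, i] <- p
      }
    }
  }
  out <- list(ids = ids, score = S)
  if (identities) out$identity <- P
  out
}

#' Within- and across-group percent-identity summaries
#'
#' Summarises pairwise sequence identities within each group (mean, sd and
#' range over all unordered pairs) and across groups (all between-group
#' pairs), the quantities reported alongside identity matrices of TK
#' sequence clusters.
#'
#' @param set a \code{tk_set} whose records carry labels.
#' @param group_by name of the grouping label (\code{"isoform"},
#'   \code{"fish_clade"}, \code{"taxon_class"}) or \code{"group"} for the
#'   combined five-way grouping; alternatively a character vector of group
#'   names, one per record.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return list with \code{within} (data.frame: group, n_sequences,
#'   mean_pct, sd_pct, min_pct, max_pct; singleton groups are NA) and
#'   \code{across} (symmetric matrix of mean between-group identities).
#' @export
identity_summary <- function(set, group_by = "group",
                             scheme = scoring_scheme()) {
  recs <- set$records
  groups <- resolve_groups(recs, group_by)
  pw <- pairwise_scores(set, scheme, identities = TRUE)
  P <- pw$identity
  lev <- unique(groups)
  within <- do.call(rbind, lapply(lev, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L)
      return(data.frame(group = g, n_sequences = length(idx),
                        mean_pct = NA_real_, sd_pct = NA_real_,
                        min_pct = NA_real_, max_pct = NA_real_))
    v <- P[idx, idx][upper.tri(P[idx, idx])]
    data.frame(group = g, n_sequences = length(idx),
               mean_pct = mean(v), sd_pct = stats::sd(v),
               min_pct = min(v), max_pct = max(v))
  }))
  across <- matrix(NA_real_, length(lev), length(lev),
                   dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    bi <- which(groups == lev[i]); bj <- which(groups == lev[j])
    if (i == j) {
      if (length(bi) >= 2L)
        across[i, j] <- mean(P[bi, bi][upper.tri(P[bi, bi])])
    } else across[i, j] <- mean(P[bi, bj, drop = FALSE])
  }
  list(within = within, across = across)
}

resolve_groups <- function(recs, group_by) {
  if (length(group_by) == length(recs) && length(recs) > 1L)
    return(as.character(group_by))
  stopifnot(is.character(group_by), length(group_by) == 1L)
  if (group_by == "group")
    vapply(recs, function(r) combined_group(r$labels), "")
  else
    vapply(recs, function(r) {
      v <- r$labels[[group_by]]
      if (is.null(v)) "unknown" else as.character(v)
    }, "")
}

# Five-way group label: mammal, or fish isoform x clade.
combined_group <- function(labels) {
  if (is.null(labels)) return("unknown")
  if (identical(labels$taxon_class, "mammal")) return("mammal")
  iso <- labels$isoform
  cl <- labels$fish_clade
  if (is.null(iso) || is.null(cl) || identical(iso, "none")) return("unknown")
  paste0("fish_", iso, "_", cl)
}
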