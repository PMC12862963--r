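#' Map a query sequence onto the reference coordinate frame
#'
#' Globally aligns the query to the reference sequence and records, for each
#' reference position, the corresponding query position (or NA at gaps).
#' This single-alignment column map replaces a multiple alignment for
#' anchored motif extraction.
#'
#' @param query a \code{tk_record} or residue string.
#' @param ref a \code{\link{tk_reference}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param min_identity floor (percent, over aligned columns) below which
#'   the query is declared unmappable, preventing nonsense motif calls.
#' @param min_columns minimum number of aligned (both non-gap) columns;
#'   with free terminal gaps a spurious short overlap can reach high
#'   identity over a handful of columns, so the floor is paired with this
#'   coverage guard.
#' @return object of class \code{"tk_colmap"}: list with \code{ref_to_query}
#'   (integer vector, one entry per reference position), \code{anchor_covered}
#'   (named logical over anchors) and \code{identity_pct}.
#' @export
map_columns <- function(query, ref, scheme = scoring_scheme(),
                        min_identity = 25, min_columns = 50) {
  stopifnot(inherits(ref, "tk_reference"))
  aln <- tk_align(query, ref$record, scheme)
  if (is.na(aln$identity_pct) || aln$identity_pct < min_identity ||
      aln$n_aligned_columns < min_columns)
    stop("query is unmappable: identity ",
         sprintf("%.1f", aln$identity_pct), "% over ",
         aln$n_aligned_columns, " columns (floor ", min_identity,
         "% over >= ", min_columns, " columns)")
  qa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  ra <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  r2q <- rep(NA_integer_, nchar(ref$record$residues))
  keep <- ra != "-" & qa != "-"
  r2q[rpos[keep]] <- qpos[keep]
  covered <- vapply(ref$anchors, function(p) all(!is.na(r2q[p])), TRUE)
  structure(list(ref_to_query = r2q, anchor_covered = covered,
                 identity_pct = aln$identity_pct),
            class = "tk_colmap")
}

.BULKY <- c("M", "L", "I", "F")
.SMALL <- c("G", "A", "S", "T")
.LARGE <- c("L", "I", "V", "M", "F")

.GLY_LOOP_TEMPLATES <- list(
  GxGxxG = list(pos = c(1L, 3L, 6L), res = list("G", "G", "G")),
  RxGxxG = list(pos = c(1L, 3L, 6L), res = list("R", "G", "G")),
  `Ax[C/S]xxG` = list(pos = c(1L, 3L, 6L), res = list("A", c("C", "S"), "G")))

#' Extract the TK signature motifs from one sequence
#'
#' Anchored fields (theta residue, DFG slot, P+1 residue, position -2
#' fallback, glycine-rich loop window) are read off the mapped reference
#' columns. Pattern fields are found by scanning the query segment spanned
#' by the NL and CRD windows: \code{[N/L]YD} (NL), \code{[R/K]H[R/K]RYY}
#' and \code{R-7x-R} (an R, any 7 residues, an R; first match kept, number
#' of matches reported) (CRD). Position -2 is the residue two positions
#' before the first arginine of the matched R-7x-R, falling back to the
#' anchored column when the pattern is absent. Residue classes: bulky
#' \{M,L,I,F\}, small \{G,A,S,T\}, large \{L,I,V,M,F\} (configurable).
#' Absence of a motif is recorded as \code{"none"}; an uncovered anchor as
#' NA. \code{X} never counts as a motif residue.
#'
#' @param query a \code{tk_record} or residue string.
#' @param ref a \code{\link{tk_reference}}.
#' @param map optional precomputed \code{\link{map_columns}} result.
#' @param scheme scoring scheme used if \code{map} is NULL.
#' @param bulky,small,large residue class sets.
#' @return object of class \code{"tk_signature"}.
#' @export
extract_signature <- function(query, ref, map = NULL,
                              scheme = scoring_scheme(),
                              bulky = .BULKY, small = .SMALL,
                              large = .LARGE) {
  stopifnot(inherits(ref, "tk_reference"))
  if (is.null(map)) map <- map_columns(query, ref, scheme)
  q <- strsplit(as_residues(query), "", fixed = TRUE)[[1]]
  r2q <- map$ref_to_query
  at <- function(ref_pos) {
    qp <- r2q[ref_pos]
    out <- rep(NA_character_, length(ref_pos))
    out[!is.na(qp)] <- q[qp[!is.na(qp)]]
    out
  }
  window_str <- function(ref_pos) {
    qp <- r2q[ref_pos]
    qp <- qp[!is.na(qp)]
    if (!length(qp)) return("")
    paste(q[min(qp):max(qp)], collapse = "")
  }

  gly <- at(ref$anchors$glycine_rich_loop)
  gly_pattern <- paste(ifelse(is.na(gly), "-", gly), collapse = "")
  gly_template <- classify_gly_loop(gly)

  theta <- at(ref$anchors$beta3_theta)
  dfg <- at(ref$anchors$dfg_slot)
  dfg_string <- paste(ifelse(is.na(dfg), "-", dfg), collapse = "")
  dfg_first <- if (is.na(dfg[1])) NA_character_
               else if (dfg[1] %in% c("D", "E")) dfg[1] else "other"
  p1 <- at(ref$anchors$p_plus1_slot)

  nl_seq <- window_str(ref$anchors$nl_window)
  m <- regexpr("[A-WYZ]YD", nl_seq)
  if (m > 0) {
    nl_match <- substr(nl_seq, m, m + 2L)
    yd_present <- TRUE
    yd_prec <- substr(nl_match, 1L, 1L)
    nl_yd <- if (yd_prec %in% c("N", "L")) nl_match else "none"
  } else {
    # YD at the very start of the window has no preceding residue
    yd_present <- grepl("YD", nl_seq, fixed = TRUE)
    yd_prec <- NA_character_
    nl_yd <- "none"
  }

  crd_seq <- window_str(ref$anchors$crd_window)
  a1 <- regexpr("[RK]H[RK]RYY", crd_seq)
  crd_alphaR1 <- if (a1 > 0) substr(crd_seq, a1, a1 + 5L) else "none"

  r7 <- gregexpr("(?=R.{7}R)", crd_seq, perl = TRUE)[[1]]
  minus2 <- NA_character_
  r7xr <- NULL
  n_r7 <- 0L
  if (r7[1] > 0) {
    n_r7 <- length(r7)
    first <- r7[1]
    r7xr <- c(first, first + 8L)  # window-relative positions of the two Rs
    if (first >= 3L) minus2 <- substr(crd_seq, first - 2L, first - 2L)
  }
  if (is.na(minus2)) minus2 <- at(ref$anchors$minus2)

  cls <- function(x, set1, name1, set2, name2) {
    if (is.na(x) || x == "X") NA_character_
    else if (x %in% set1) name1 else if (x %in% set2) name2 else "other"
  }
  id <- if (inherits(query, "tk_record")) query$id else NA_character_
  structure(list(
    id = id,
    gly_loop_pattern = gly_pattern,
    gly_loop_template = gly_template,
    theta_residue = theta,
    theta_class = cls(theta, bulky, "bulky", small, "small"),
    dfg_slot_string = dfg_string,
    dfg_first_residue = dfg_first,
    p_plus1_residue = p1,
    nl_yd = nl_yd,
    yd_present = yd_present,
    yd_preceding = yd_prec,
    crd_alphaR1 = crd_alphaR1,
    r7xr = r7xr,
    r7xr_n_matches = n_r7,
    minus2_residue = minus2,
    minus2_class = cls(minus2, small, "small", large, "large"),
    anchor_covered = map$anchor_covered),
    class = "tk_signature")
}

# Best-matching glycine-rich loop template by fixed-position matches;
# ties resolved in listed order (canonical first).
classify_gly_loop <- function(gly6) {
  if (length(gly6) != 6L || any(is.na(gly6))) return(NA_character_)
  scores <- vapply(.GLY_LOOP_TEMPLATES, function(t)
    sum(mapply(function(p, rs) gly6[p] %in% rs, t$pos, t$res)), 0)
  names(.GLY_LOOP_TEMPLATES)[which.max(scores)]
}

#' @export
print.tk_signature <- function(x, ...) {
  cat("TK signature", if (!is.na(x$id)) paste0("(", x$id, ")"), "\n")
  cat(sprintf("  gly loop %s [%s]  beta3 theta %s (%s)  DFG slot %s\n",
              x$gly_loop_pattern, x$gly_loop_template, x$theta_residue,
              x$theta_class, x$dfg_slot_string))
  cat(sprintf("  P+1 %s  NL [N/L]YD %s  alphaR1 %s  -2 %s (%s)\n",
              x$p_plus1_residue, x$nl_yd, x$crd_alphaR1, x$minus2_residue,
              x$minus2_class))
  invisible(x)
}

.TRACKED_FEATURES <- c("theta_residue", "theta_class", "dfg_first_residue",
                       "p_plus1_residue", "minus2_residue", "minus2_class",
                       "gly_loop_template", "nl_yd", "yd_preceding",
                       "crd_alphaR1")

#' Per-group residue/motif frequency table
#'
#' For each group and tracked signature feature, tabulates the percentage
#' and count of each observed value. Sequences whose feature is unresolved
#' (NA: anchor not covered or residue X) are excluded from that feature's
#' denominator; the exclusion count is reported. Motif absence
#' (\code{"none"}) is a value, not an exclusion.
#'
#' @param signatures list of \code{\link{extract_signature}} results.
#' @param groups character vector, one group label per signature.
#' @param features feature names to tabulate (default all tracked).
#' @return data.frame with columns group, feature, value, n, pct,
#'   n_group, n_unresolved; class \code{"tk_freq_table"}.
#' @export
group_frequencies <- function(signatures, groups,
                              features = .TRACKED_FEATURES) {
  stopifnot(length(signatures) == length(groups))
  groups <- as.character(groups)
  rows <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) next
    for (f in features) {
      vals <- vapply(signatures[idx], function(s) {
        v <- s[[f]]
        if (is.null(v) || length(v) != 1L) NA_character_ else as.character(v)
      }, "")
      resolved <- vals[!is.na(vals)]
      n_unres <- sum(is.na(vals))
      if (!length(resolved)) next
      tab <- table(resolved)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, feature = f, value = names(tab),
        n = as.integer(tab),
        pct = 100 * as.integer(tab) / length(resolved),
        n_group = length(idx), n_unresolved = n_unres,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tk_freq_table", "data.frame")
  out
}

#' beta-3 / CRD position -2 covariation
#'
#' Builds the 2x2 contingency of theta class (bulky vs not) against
#' position -2 class (small vs not) over sequences with both classes
#' resolved, and reports the Haldane-corrected odds ratio and the
#' association coefficient sqrt(chi-squared / n) (the phi coefficient for a
#' 2x2 table, in [0, 1]). The volume-compensation covariation between the
#' beta-3 theta residue and the CRD residue packing against it makes
#' TK-like sequences (bulky theta, small -2) segregate from
#' active-kinase-like sequences (small theta, large -2).
#'
#' @param signatures list of \code{\link{extract_signature}} results.
#' @return object of class \code{"tk_covariation"}: list with \code{counts}
#'   (2x2 matrix), \code{odds_ratio}, \code{association}, \code{n},
#'   \code{undefined} flag.
#' @export
motif_covariation <- function(signatures) {
  th <- vapply(signatures, function(s) s$theta_class %||% NA_character_, "")
  m2 <- vapply(signatures, function(s) s$minus2_class %||% NA_character_, "")
  ok <- !is.na(th) & !is.na(m2)
  if (sum(ok) < 2L)
    stop("need at least two sequences with both motif classes resolved")
  bulky <- factor(th[ok] == "bulky", levels = c(TRUE, FALSE))
  small <- factor(m2[ok] == "small", levels = c(TRUE, FALSE))
  counts <- table(theta_bulky = bulky, minus2_small = small)
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(theta = c("bulky", "not_bulky"),
                                   minus2 = c("small", "not_small")))
  n <- sum(counts)
  undefined <- any(rowSums(counts) == 0L) || any(colSums(counts) == 0L)
  cc <- counts
  if (any(cc == 0L)) cc <- cc + 0.5  # Haldane-Anscombe correction
  or <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  assoc <- if (undefined) NA_real_ else {
    num <- counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1]
    den <- prod(c(rowSums(counts), colSums(counts)))
    chisq <- n * num^2 / den
    sqrt(chisq / n)
  }
  structure(list(counts = counts, odds_ratio = unname(or),
                 association = unname(assoc), n = n, undefined = undefined),
            class = "tk_covariation")
}

#' @export
print.tk_covariation <- function(x, ...) {
  cat("beta3 theta x CRD position -2 covariation (n =", x$n, ")\n")
  print(x$counts)
  cat(sprintf("  odds ratio %.3g, association %.3f%s\n", x$odds_ratio,
              x$association, if (x$undefined) " (undefined margin)" else ""))
  invisible(x)
}
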