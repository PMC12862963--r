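#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues plus the ambiguity code \code{X}. \code{X} is
#' tolerated on input but scores 0 against every residue and never counts as
#' an identity or a motif residue.
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Scoring scheme for global pairwise alignment
#'
#' Bundles a substitution matrix with affine gap penalties and a terminal-gap
#' policy. The default is the BLOSUM62 log-odds table with the \code{X}
#' row/column zeroed (so ambiguity codes are neutral), gap opening 10, gap
#' extension 0.5 and free terminal gaps. A gap run of length L costs
#' \code{gap_open + gap_extend * L}. Free terminal gaps suit domain-region
#' sequences whose trimming differs between database entries.
#'
#' @param substitution symmetric integer substitution matrix with row/column
#'   names covering the amino-acid alphabet; default BLOSUM62 with X zeroed.
#' @param gap_open positive gap opening penalty.
#' @param gap_extend positive gap extension penalty; must not exceed
#'   \code{gap_open}.
#' @param terminal_gaps \code{"free"} (default) or \code{"penalized"}.
#' @return An object of class \code{"tk_scheme"}.
#' @export
#' @examples
#' sc <- scoring_scheme()
#' sc$substitution["M", "M"]
scoring_scheme <- function(substitution = NULL, gap_open = 10,
                           gap_extend = 0.5,
                           terminal_gaps = c("free", "penalized")) {
  terminal_gaps <- match.arg(terminal_gaps)
  if (is.null(substitution)) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    substitution <- data_env$BLOSUM62
    substitution["X", ] <- 0L
    substitution[, "X"] <- 0L
  }
  stopifnot(is.matrix(substitution),
            identical(rownames(substitution), colnames(substitution)))
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop("require gap_open >= gap_extend > 0")
  structure(list(substitution = substitution,
                 gap_open = gap_open,
                 gap_extend = gap_extend,
                 terminal_gaps = terminal_gaps),
            class = "tk_scheme")
}

#' @export
print.tk_scheme <- function(x, ...) {
  cat("Alignment scoring scheme\n")
  cat("  substitution matrix:", nrow(x$substitution), "x",
      ncol(x$substitution), "\n")
  cat(sprintf("  gap open %.3g, gap extend %.3g, terminal gaps %s\n",
              x$gap_open, x$gap_extend, x$terminal_gaps))
  invisible(x)
}
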