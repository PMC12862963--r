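#' Build the pairwise-similarity matrix
#'
#' Computes all pairwise global alignment scores s_ij (including
#' self-scores s_ii) and normalizes them into correlation-like coefficients
#' r_ij = s_ij / sqrt(s_ii * s_jj), with unit diagonal. The r matrix is the
#' input to the spectral similarity-map embedding.
#'
#' @param set a \code{tk_set} with at least 3 sequences.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return object of class \code{"tk_similarity"}: list with \code{ids},
#'   \code{s} (raw scores), \code{r} (normalized coefficients).
#' @export
build_similarity <- function(set, scheme = scoring_scheme()) {
  if (length(set$records) < 3L) stop("need at least 3 sequences")
  pw <- pairwise_scores(set, scheme)
  s <- pw$score
  d <- diag(s)
  if (any(d <= 0))
    stop("non-positive self-score for: ",
         paste(pw$ids[d <= 0], collapse = ", "),
         " (scheme unusable for normalization)")
  r <- s / sqrt(outer(d, d))
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(list(ids = pw$ids, s = s, r = r), class = "tk_similarity")
}

#' @export
print.tk_similarity <- function(x, ...) {
  cat("Pairwise similarity matrix:", length(x$ids), "sequences\n")
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("  r_ij range %.3f .. %.3f\n", min(off), max(off)))
  invisible(x)
}

#' Spectral similarity-map embedding
#'
#' Eigendecomposes the normalized coefficient matrix r and places each
#' sequence at x_i(d) = sqrt(lambda_d) * v_d(i) for the top-k positive
#' eigenvalues, so that dot products x_i . x_j approximate r_ij. Dimensions
#' are ordered by non-increasing eigenvalue: dimension 1 carries the shared
#' signal and later dimensions successively less prominent sequence
#' divergences. Signs are fixed deterministically by making the
#' largest-magnitude coordinate of each dimension positive (anchors may
#' re-orient them later, see \code{\link{classify_sequences}}).
#'
#' An optional quasi-Newton least-squares refinement of
#' sum_\{i<=j\} (x_i . x_j - r_ij)^2 (unit diagonal included) is available;
#' the refined solution is kept only if it does not increase the error.
#'
#' @param sim a \code{\link{build_similarity}} result, or a symmetric
#'   unit-diagonal matrix.
#' @param k number of dimensions to retain (default 4).
#' @param refine logical; run the least-squares refinement.
#' @return object of class \code{"tk_embedding"}: list with
#'   \code{coordinates} (n x k matrix, rownames ids), \code{eigenvalues},
#'   \code{k}, \code{k_requested}, \code{deficient} flag,
#'   \code{reconstruction_error} (sum over i <= j, unit diagonal included).
#' @export
embed_similarity <- function(sim, k = 4, refine = FALSE) {
  if (inherits(sim, "tk_similarity")) {
    r <- sim$r; ids <- sim$ids
  } else {
    r <- sim
    ids <- rownames(r) %||% paste0("s", seq_len(nrow(r)))
  }
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-8) stop("r must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("r must have unit diagonal")
  if (k < 1L) stop("k must be >= 1")
  eg <- eigen(r, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eg$values))
  npos <- sum(eg$values > tol)
  deficient <- npos < k
  if (deficient)
    warning("only ", npos, " positive eigenvalues available (requested k = ",
            k, ")")
  kk <- min(k, npos)
  lam <- eg$values[seq_len(kk)]
  X <- eg$vectors[, seq_len(kk), drop = FALSE] %*% diag(sqrt(lam), kk)
  for (d in seq_len(kk)) {
    i <- which.max(abs(X[, d]))
    if (X[i, d] < 0) X[, d] <- -X[, d]
  }
  err <- recon_error(X, r)
  if (refine) {
    n <- nrow(X)
    obj <- function(v) {
      Xv <- matrix(v, n, kk)
      recon_error(Xv, r)
    }
    opt <- stats::optim(as.vector(X), obj, method = "BFGS",
                        control = list(maxit = 200))
    if (opt$value < err) {
      X <- matrix(opt$par, n, kk)
      err <- opt$value
    }
  }
  rownames(X) <- ids
  colnames(X) <- paste0("dim", seq_len(kk))
  structure(list(coordinates = X, eigenvalues = lam, k = kk,
                 k_requested = k, deficient = deficient,
                 reconstruction_error = err),
            class = "tk_embedding")
}

# Squared reconstruction error over i <= j (unit diagonal included).
recon_error <- function(X, r) {
  G <- tcrossprod(X)
  D <- G - r
  (sum(D^2) + sum(diag(D)^2)) / 2
}

#' @export
print.tk_embedding <- function(x, ...) {
  cat("Similarity-map embedding:", nrow(x$coordinates), "sequences,",
      x$k, "dimensions\n")
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                              collapse = ", "), "\n")
  cat(sprintf("  reconstruction error %.4g\n", x$reconstruction_error))
  invisible(x)
}

#' Classify sequences into isoform/clade clusters from an embedding
#'
#' Uses labelled anchor sequences (e.g. the annotated zebrafish ttna/ttnb
#' entries) to orient the embedding axes and assign every sequence to a
#' cluster. Two methods:
#' \describe{
#'   \item{sign-quadrant}{isoform from the sign of the isoform dimension
#'     (default 2; a below zero, b above), clade from the sign of the clade
#'     dimension (default 3; neoteleostei below zero). Signs are flipped so
#'     every anchor falls on its labelled side; anchors of the same label on
#'     opposite sides raise an ambiguity error. Fish-only.}
#'   \item{nearest-centroid}{each sequence is assigned the label of the
#'     nearest anchor-defined centroid in dimensions 2..k; the default when
#'     mammals are included (five clusters).}
#' }
#'
#' @param emb a \code{\link{embed_similarity}} result.
#' @param anchors data.frame with columns \code{id}, \code{isoform}
#'   (\code{a}/\code{b}/\code{none}) and \code{clade}
#'   (\code{neoteleostei}/\code{non-neoteleostei}/\code{mammal}).
#' @param method \code{"nearest-centroid"} (default) or
#'   \code{"sign-quadrant"}.
#' @param isoform_dim,clade_dim dimensions used by the sign-quadrant
#'   method.
#' @return object of class \code{"tk_clusters"}: list with
#'   \code{assignments} (data.frame id, cluster, isoform, clade),
#'   \code{method}, \code{anchors}, \code{orientation_signs}.
#' @export
classify_sequences <- function(emb, anchors,
                               method = c("nearest-centroid",
                                          "sign-quadrant"),
                               isoform_dim = 2L, clade_dim = 3L) {
  method <- match.arg(method)
  X <- emb$coordinates
  ids <- rownames(X)
  stopifnot(all(c("id", "isoform", "clade") %in% names(anchors)))
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  missing_anch <- setdiff(anchors$id, ids)
  if (length(missing_anch))
    stop("anchor id(s) not in embedding: ",
         paste(missing_anch, collapse = ", "))
  signs <- rep(1, ncol(X))

  if (method == "sign-quadrant") {
    if (max(isoform_dim, clade_dim) > emb$k)
      stop("embedding has only ", emb$k, " dimensions")
    signs[isoform_dim] <- orient_dimension(
      X[anchors$id, isoform_dim], anchors$isoform,
      negative_label = "a", positive_label = "b", what = "isoform")
    signs[clade_dim] <- orient_dimension(
      X[anchors$id, clade_dim], anchors$clade,
      negative_label = "neoteleostei", positive_label = "non-neoteleostei",
      what = "clade")
    Xo <- sweep(X, 2, signs, `*`)
    isoform <- ifelse(Xo[, isoform_dim] < 0, "a", "b")
    clade <- ifelse(Xo[, clade_dim] < 0, "neoteleostei", "non-neoteleostei")
    cluster <- paste0("fish_", isoform, "_", clade)
  } else {
    dims <- 2:emb$k
    if (emb$k < 2L) dims <- 1L
    grp <- ifelse(anchors$clade == "mammal", "mammal",
                  paste0("fish_", anchors$isoform, "_", anchors$clade))
    cent <- do.call(rbind, lapply(split(anchors$id, grp), function(aid)
      colMeans(X[aid, dims, drop = FALSE])))
    d2 <- outer(rowSums(X[, dims, drop = FALSE]^2), rep(1, nrow(cent))) -
      2 * X[, dims, drop = FALSE] %*% t(cent) +
      outer(rep(1, nrow(X)), rowSums(cent^2))
    cluster <- rownames(cent)[max.col(-d2, ties.method = "first")]
    isoform <- ifelse(cluster == "mammal", "none",
                      sub("^fish_([ab])_.*$", "\\1", cluster))
    clade <- ifelse(cluster == "mammal", "mammal",
                    sub("^fish_[ab]_", "", cluster))
  }
  # anchors must recover their own labels
  for (i in seq_len(nrow(anchors))) {
    j <- match(anchors$id[i], ids)
    exp_cl <- if (anchors$clade[i] == "mammal") "mammal"
              else paste0("fish_", anchors$isoform[i], "_", anchors$clade[i])
    if (method == "nearest-centroid" && cluster[j] != exp_cl)
      stop("anchor '", anchors$id[i], "' not recovered by its own centroid")
  }
  structure(list(assignments = data.frame(id = ids, cluster = cluster,
                                          isoform = isoform, clade = clade,
                                          stringsAsFactors = FALSE),
                 method = method, anchors = anchors,
                 orientation_signs = signs),
            class = "tk_clusters")
}

# Sign (+1/-1) putting every anchor of negative_label below zero and of
# positive_label above; error when anchors of one label straddle zero.
orient_dimension <- function(coords, labels, negative_label, positive_label,
                             what) {
  keep <- labels %in% c(negative_label, positive_label)
  coords <- coords[keep]; labels <- labels[keep]
  if (!length(coords))
    stop("no anchors labelled for ", what, " orientation")
  want_neg <- labels == negative_label
  s_ok <- all(coords[want_neg] < 0) && all(coords[!want_neg] > 0)
  s_fl <- all(coords[want_neg] > 0) && all(coords[!want_neg] < 0)
  if (s_ok) 1
  else if (s_fl) -1
  else stop("dimension does not separate ", what,
            " labels: same-label anchors fall on opposite sides")
}

#' @export
print.tk_clusters <- function(x, ...) {
  cat("Cluster assignment (", x$method, "):\n", sep = "")
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Write embedding coordinates and cluster calls as TSV
#'
#' @param emb a \code{tk_embedding}.
#' @param clusters optional \code{tk_clusters} to merge in.
#' @param path output TSV.
#' @export
write_embedding_tsv <- function(emb, path, clusters = NULL) {
  df <- data.frame(id = rownames(emb$coordinates), emb$coordinates,
                   stringsAsFactors = FALSE)
  if (!is.null(clusters))
    df <- merge(df, clusters$assignments, by = "id", sort = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
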