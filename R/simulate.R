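.SIM_GROUPS <- c("mammal", "fish_a_neoteleostei", "fish_a_non-neoteleostei",
                 "fish_b_neoteleostei", "fish_b_non-neoteleostei")

# Default per-group motif tables: named list group -> anchor -> named
# probability vector over implanted strings. Anchors absent from a table
# keep the conserved reference residues. Probabilities follow the observed
# per-cluster frequencies of the TK signature loci: the theta residue of
# the beta-3 motif (methionine 98.5% in mammals, 98.9%/100% in
# neoteleostei a/b, 40%/77.4% in non-neoteleostei a/b, remainder split
# L:I:F = 8.7:0.6:2.6), the ExG first residue (E except 17.6%/6.7% D in
# fish a), the P+1 tyrosine (96.4% mammals, 28.6%/46.7% fish a, absent in
# b), position -2 (76.8% A, 15.2% S/T, 4.8% G, 1.5% V, rarely E/Q), the
# glycine-rich loop template (GxGxxG in mammals and isoform b, RxGxxG in
# non-neoteleostei a, Ax[C/S]xxG in neoteleostei a) and the [N/L]YD motif
# (N-preceded 73.8%).
default_motif_tables <- function() {
  theta_rest <- c(L = 8.7, I = 0.6, F = 2.6) / 11.9
  theta <- function(pM) c(M = pM, theta_rest * (1 - pM))
  minus2 <- c(A = 76.8, S = 7.6, T = 7.6, G = 4.8, V = 1.5,
              E = 0.4, Q = 0.4)
  minus2 <- minus2 / sum(minus2)
  nl <- c(NYD = 0.738, LYD = 0.262)
  a1 <- c(RHRRYY = 0.8, KHRRYY = 0.2)
  gly_b <- c(GAGSSG = 1)
  base <- function(pM, dfgD, pY, gly, dfg_x) list(
    beta3_theta = theta(pM),
    dfg_slot = stats::setNames(c(dfgD, 1 - dfgD),
                               paste0(c("D", "E"), dfg_x, "G")),
    p_plus1_slot = c(Y = pY, A = 1 - pY),
    minus2 = minus2,
    glycine_rich_loop = gly,
    yd_motif_ext = nl,
    alphaR1_motif = a1)
  list(
    mammal = base(0.985, 0, 0.964, gly_b, "F"),
    `fish_a_neoteleostei` = base(0.989, 0.176, 0.286,
                                 c(AACSSG = 0.5, AASSSG = 0.5), "L"),
    `fish_a_non-neoteleostei` = base(0.400, 0.067, 0.467,
                                     c(RAGSSG = 1), "L"),
    `fish_b_neoteleostei` = base(1.000, 0, 0, gly_b, "L"),
    `fish_b_non-neoteleostei` = base(0.774, 0, 0, gly_b, "L"))
}

#' Configuration for the sequence-family simulator
#'
#' The generator emulates a five-group TK family (mammal, plus fish
#' isoforms a/b in the neoteleostei and non-neoteleostei clades) in which
#' the isoform split is deeper than the clade split, with group-specific
#' motif residue frequencies implanted at the annotated anchor columns of
#' the medaka TKb reference frame.
#'
#' @param seed integer seed; fully determines the output.
#' @param root_length ancestor length (default 355, the TK region span).
#' @param rates per-branch substitution rates: \code{root_divergence}
#'   (reference frame to family root), \code{class_split} (root to
#'   mammal/fish), \code{isoform_split} (fish to isoform a/b),
#'   \code{clade_split} (isoform to clade), \code{tip} (group ancestor to
#'   individual). The isoform-split rate is strictly larger than the
#'   clade-split rate by default, mirroring the observation that TK
#'   isoforms within an organism differ more than the same isoform across
#'   fish groups. Substitutions act on non-anchor positions; anchor columns
#'   are controlled by the motif tables.
#' @param n_per_group sequences per group (default 10).
#' @param motif_tables per-group anchor implant tables; see
#'   \code{default_motif_tables} in the package source.
#' @param truncation_fraction fraction of sequences truncated mid-kinase
#'   (for partial-sequence curation tests).
#' @param indel_rate optional per-site insertion/deletion rate applied to
#'   non-anchor positions of each emitted sequence (default 0: anchored
#'   columns stay aligned); used to stress column mapping.
#' @return object of class \code{"tk_sim_config"}.
#' @export
sim_config <- function(seed = 1L, root_length = 355L,
                       rates = list(root_divergence = 0.35,
                                    class_split = 0.25,
                                    isoform_split = 0.15,
                                    clade_split = 0.06,
                                    tip = 0.03),
                       n_per_group = 10L,
                       motif_tables = default_motif_tables(),
                       truncation_fraction = 0,
                       indel_rate = 0) {
  stopifnot(all(unlist(rates) >= 0), truncation_fraction >= 0,
            truncation_fraction <= 1, n_per_group >= 1L,
            indel_rate >= 0, indel_rate <= 0.5)
  for (g in names(motif_tables)) for (a in names(motif_tables[[g]])) {
    p <- motif_tables[[g]][[a]]
    if (abs(sum(p) - 1) > 1e-6)
      stop("motif table ", g, "/", a, " probabilities must sum to 1")
  }
  structure(list(seed = as.integer(seed), root_length = root_length,
                 rates = rates, n_per_group = as.integer(n_per_group),
                 motif_tables = motif_tables,
                 truncation_fraction = truncation_fraction,
                 indel_rate = indel_rate),
            class = "tk_sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a five-group TK sequence family with known truth
#'
#' Starts from the annotated reference frame, diverges the non-anchor
#' background at the root rate, evolves the root along the fixed
#' species/isoform/clade tree with per-site substitution at the branch
#' rates, overwrites anchor columns from each group's motif table, and
#' emits labelled records. Keeping the family within recognizable
#' divergence of the reference mirrors the vertebrate TK data, where all
#' family members remain alignable to one annotated frame. Windows around the NL
#' and CRD motifs are kept free of residues that could create spurious
#' pattern matches, so implanted motif frequencies are exactly recoverable.
#' Deterministic under the config seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{set} (a \code{tk_set}; headers carry truth
#'   labels) and \code{truth} (data.frame: id, group, labels, implanted
#'   anchor values, truncated flag).
#' @export
simulate_families <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "tk_sim_config"))
  ref <- ref_medakaTKb()
  anch <- ref$anchors
  refres <- strsplit(ref$record$residues, "", fixed = TRUE)[[1]]
  L <- cfg$root_length
  if (L != length(refres))
    stop("root_length must match the reference frame (", length(refres), ")")
  aa <- setdiff(AA_ALPHABET, "X")
  anchor_pos <- sort(unique(unlist(anch[setdiff(names(anch),
                                                c("nl_window",
                                                  "crd_window"))])))
  yd_ext <- c(min(anch$yd_motif) - 1L, anch$yd_motif)  # preceding residue
  anchor_pos <- sort(unique(c(anchor_pos, yd_ext)))
  nl_free <- setdiff(anch$nl_window, anchor_pos)
  crd_free <- setdiff(anch$crd_window, anchor_pos)

  scrub <- function(s) {
    bad_nl <- nl_free[s[nl_free] %in% c("N", "L", "Y", "D")]
    if (length(bad_nl))
      s[bad_nl] <- sample(setdiff(aa, c("N", "L", "Y", "D")),
                          length(bad_nl), TRUE)
    bad_crd <- crd_free[s[crd_free] %in% c("R", "K", "H")]
    if (length(bad_crd))
      s[bad_crd] <- sample(setdiff(aa, c("R", "K", "H")),
                           length(bad_crd), TRUE)
    s
  }
  free <- setdiff(seq_len(L), anchor_pos)
  mutate <- function(s, rate) {
    hit <- free[stats::runif(length(free)) < rate]
    if (length(hit)) s[hit] <- sample(aa, length(hit), TRUE)
    scrub(s)
  }
  implant <- function(s, tab) {
    draws <- list()
    for (a in names(tab)) {
      pos <- switch(a, yd_motif_ext = yd_ext,
                    anch[[a]] %||% stop("motif table references an ",
                                        "undefined anchor: ", a))
      p <- tab[[a]]
      pick <- sample(names(p), 1L, prob = p)
      if (nchar(pick) != length(pos))
        stop("implant '", pick, "' does not fit anchor '", a, "' (",
             length(pos), " positions)")
      s[pos] <- strsplit(pick, "", fixed = TRUE)[[1]]
      draws[[a]] <- pick
    }
    list(seq = s, draws = draws)
  }

  with_seed(cfg$seed, {
    r <- cfg$rates
    root <- mutate(refres, r$root_divergence %||% 0.35)
    anc <- list(
      mammal = mutate(root, r$class_split),
      fish = mutate(root, r$class_split))
    anc$fish_a <- mutate(anc$fish, r$isoform_split)
    anc$fish_b <- mutate(anc$fish, r$isoform_split)
    # One substitution set per clade, applied to both gene copies: the
    # clade signature is shared across isoforms (in the real vector map a
    # single dimension separates fish groups for both isoforms at once).
    clade_offset <- function(rate) {
      pos <- free[stats::runif(length(free)) < rate]
      list(pos = pos, res = sample(aa, length(pos), TRUE))
    }
    offs <- list(neoteleostei = clade_offset(r$clade_split),
                 `non-neoteleostei` = clade_offset(r$clade_split))
    apply_offset <- function(s, off) {
      s[off$pos] <- off$res
      scrub(s)
    }
    ganc <- list(
      mammal = anc$mammal,
      `fish_a_neoteleostei` = apply_offset(anc$fish_a, offs[[1]]),
      `fish_a_non-neoteleostei` = apply_offset(anc$fish_a, offs[[2]]),
      `fish_b_neoteleostei` = apply_offset(anc$fish_b, offs[[1]]),
      `fish_b_non-neoteleostei` = apply_offset(anc$fish_b, offs[[2]]))

    records <- list(); truth <- list()
    for (g in .SIM_GROUPS) {
      tab <- cfg$motif_tables[[g]]
      if (is.null(tab)) stop("no motif table for group ", g)
      for (i in seq_len(cfg$n_per_group)) {
        s <- mutate(ganc[[g]], r$tip)
        imp <- implant(s, tab)
        seq_out <- imp$seq
        if (cfg$indel_rate > 0) {
          # indels at non-anchor sites only: delete the residue or insert
          # a random residue after it (equal odds)
          hit <- free[stats::runif(length(free)) < cfg$indel_rate]
          if (length(hit)) {
            pieces <- as.list(seq_out)
            for (p in hit) {
              if (stats::runif(1) < 0.5) pieces[[p]] <- character(0)
              else pieces[[p]] <- c(pieces[[p]], sample(aa, 1))
            }
            seq_out <- unlist(pieces)
          }
        }
        id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "", g), i)
        labels <- if (g == "mammal")
          list(taxon_class = "mammal", fish_clade = "none", isoform = "none")
        else list(taxon_class = "fish",
                  fish_clade = sub("^fish_[ab]_", "", g),
                  isoform = sub("^fish_([ab])_.*$", "\\1", g))
        records[[length(records) + 1L]] <-
          seq_record(id, paste(seq_out, collapse = ""), labels = labels)
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, group = g,
          taxon_class = labels$taxon_class, fish_clade = labels$fish_clade,
          isoform = labels$isoform,
          theta = substr(imp$draws$beta3_theta, 1, 1),
          dfg_slot = imp$draws$dfg_slot,
          p_plus1 = imp$draws$p_plus1_slot,
          minus2 = imp$draws$minus2,
          gly_loop = imp$draws$glycine_rich_loop,
          nl_yd = imp$draws$yd_motif_ext,
          alphaR1 = imp$draws$alphaR1_motif,
          truncated = FALSE, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    if (cfg$truncation_fraction > 0) {
      n_trunc <- round(cfg$truncation_fraction * nrow(truth))
      idx <- sample(nrow(truth), n_trunc)
      cut_at <- anch$catalytic_aspartate - 10L  # mid-kinase truncation
      for (j in idx) {
        rec <- records[[j]]
        records[[j]] <- seq_record(rec$id,
                                   substr(rec$residues, 1L, cut_at),
                                   labels = rec$labels)
        truth$truncated[j] <- TRUE
      }
    }
    list(set = sequence_set(records,
                            provenance = sprintf("simulated (seed %d)",
                                                 cfg$seed)),
         truth = truth)
  })
}

#' Simulate a rigid-body structure pair with noise
#'
#' Generates a random-walk Calpha trace (3.8 Angstrom steps), applies a
#' random rigid transform plus isotropic Gaussian coordinate noise, and
#' reports the expected post-superposition RMSD
#' sigma * sqrt(3 * (1 - 2/n)) (the 2/n term accounts for the six fitted
#' rigid-body parameters).
#'
#' @param seed integer seed.
#' @param n_points number of Calpha points (>= 4).
#' @param noise_sigma per-coordinate Gaussian noise sd in Angstrom (>= 0).
#' @param transform optional list(U = rotation, t = translation); random
#'   when NULL.
#' @return list with \code{a}, \code{b} (\code{tk_structure} models),
#'   \code{expected_rmsd}, \code{U_true}, \code{t_true}.
#' @export
simulate_structure_pair <- function(seed = 1L, n_points = 100L,
                                    noise_sigma = 0.5, transform = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_points < 4L) stop("need n_points >= 4")
  with_seed(seed, {
    steps <- matrix(stats::rnorm(3 * (n_points - 1L)), ncol = 3)
    steps <- 3.8 * steps / sqrt(rowSums(steps^2))
    A <- rbind(0, apply(steps, 2, cumsum))
    if (is.null(transform)) {
      M <- matrix(stats::rnorm(9), 3, 3)
      qr_ <- qr(M)
      U <- qr.Q(qr_)
      if (det(U) < 0) U[, 1] <- -U[, 1]
      tvec <- stats::rnorm(3, sd = 20)
    } else {
      U <- transform$U; tvec <- transform$t
    }
    B <- A %*% t(U) + matrix(tvec, n_points, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n_points, sd = noise_sigma), ncol = 3)
    as_model <- function(X) structure_model(data.frame(
      chain = "A", resno = seq_len(n_points), insert = "", resid = "ALA",
      elety = "CA", x = X[, 1], y = X[, 2], z = X[, 3], o = 1,
      is_polymer = TRUE, stringsAsFactors = FALSE))
    list(a = as_model(A), b = as_model(B),
         expected_rmsd = noise_sigma * sqrt(3 * (1 - 2 / n_points)),
         U_true = U, t_true = tvec)
  })
}
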