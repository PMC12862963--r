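# Synthetic reference sequences. These are stand-ins constructed in code:
# random backgrounds with every annotated anchor residue/motif implanted at
# the literature positions of each numbering frame. They are NOT the
# biological sequences (which are database-deposited and not shipped here);
# they carry the coordinate frames and anchor layout only.

.MEDTKB_SEQ <- paste0(
  "KHMPIFFHWVNYDGTGGQRGIMRHERSRQRFMTDPLLVHHMLECNGAGSSGYVRPLFELQ",
  "RADDKMAKERQKREMNFPVWGCEMYLLGDQYDYWNMRLSFGTAIYKIQTRMAIRTSNMDI",
  "WDKLCSQPLMATCMNQGLQNRNRLSALWQNWASISWHADNRWSVIVYSRRAVHCNSRMEL",
  "GQMMYYTRCINYESQTSYGRKAPCCAMTMIAPARSSRKGWLTVLWPCLSTTILYHMQTHV",
  "KQQMRHKVTDNWWVHQPNFTWFQMWCHEIQQQFAVSFFEPDRYQHKVHVPMRTPMCWGCI",
  "MDYAWLDWITRHRRYYCQMYMFDQAENACRMGMLCSERAWCTPVATMQYSMGCGA")

.HUMANTK_SEQ <- paste0(
  "GPQFFSMGHNYDRASFMTDPLLYEHKLESNGAGSSGYVRPLFWLHRAIDWMAKERSKCEE",
  "DFPVWGCEAGLLNDQIDSWNMQLSFVTAEHQCQHRMPIPTSMPDIWDIKCIQPHKHTPQD",
  "QGEQNRSCLLMIVMVWASIRKHGDHRFSVIVYSRRMVPLTHPMEFGQWMYYSRAYNYTSQ",
  "TKYKAKYTCEYMTTIIPARKSRGGWETVLVWDLSEFILEWGATSRKSQMIHKSTDSPWLH",
  "QPRTAWFQCNKHEICVEFAVERATPYLYAHKPHQRMRTILCWKCIMDYTWLDLIMRHRRY",
  "YCAEYDFDEADNACRMNMLCSNRCAGTPWAMMQYYSGAGCVQ")

#' Construct a reference annotation for motif extraction
#'
#' A reference annotation couples a reference sequence with named anchor
#' positions (in the reference's local numbering) for the TK signature
#' loci: the glycine-rich loop window, the theta position and catalytic
#' lysine of the beta-3 motif, the alpha-C glutamate, the catalytic
#' aspartate, the DFG slot (ExG in most TKs), the P+1 slot, the NL and CRD
#' windows, the catalytic (C-) and regulatory (R-) spine residues, the YD
#' motif and its kinase-side contacts, the R-7x-R arginines, position -2,
#' and the hinge acidic pair.
#'
#' @param record a \code{\link{seq_record}} holding the reference sequence.
#' @param anchors named list of integer positions (windows as integer
#'   vectors); see \code{\link{ref_medakaTKb}} for the expected names.
#' @param kinase_anchors names of the anchors that define the "full kinase
#'   region" for partial-sequence curation (glycine-rich loop through P+1).
#' @return object of class \code{"tk_reference"}.
#' @export
tk_reference <- function(record, anchors, kinase_anchors) {
  stopifnot(inherits(record, "tk_record"), is.list(anchors))
  len <- nchar(record$residues)
  for (nm in names(anchors)) {
    p <- anchors[[nm]]
    if (any(p < 1L | p > len))
      stop("anchor '", nm, "' falls outside the reference (length ", len, ")")
  }
  if (!all(kinase_anchors %in% names(anchors)))
    stop("kinase_anchors must name entries of anchors")
  structure(list(record = record, anchors = anchors,
                 kinase_anchors = kinase_anchors),
            class = "tk_reference")
}

#' @export
print.tk_reference <- function(x, ...) {
  cat("TK reference annotation:", x$record$id, "(",
      nchar(x$record$residues), "residues,", length(x$anchors), "anchors )\n")
  invisible(x)
}

# Anchor names that mark the kinase domain span (gly-rich loop to P+1 loop).
.KINASE_ANCHORS <- c("glycine_rich_loop", "beta3_theta", "beta3_lysine",
                     "alphaC_glutamate", "catalytic_aspartate", "dfg_slot",
                     "p_plus1_slot")

#' Medaka TKb reference annotation (default)
#'
#' Local numbering where residue 1 corresponds to M27887 of the full-length
#' medaka ttnb titin entry. Anchors: NL window 1-33 with the YD motif at
#' 12-13 (preceded by N11); E43 on strand beta-1; glycine-rich loop 46-51;
#' MAK motif with theta M66 and catalytic K68; alpha-C glutamate E83;
#' R-spine L87, L98, H157, L180; hinge S116 with acidic pair D119/D122;
#' catalytic aspartate D159; C-spine V53, M66, I120, I165, V166, Y167,
#' L224, L228; ELG in the DFG slot at 179-181; P+1 slot A202; CRD window
#' 300-355 with the alpha-R1 motif RHRRYY at 311-316, position -2 A328,
#' R-7x-R arginines R330/R338 and S336.
#'
#' The shipped sequence is synthetic (anchor residues implanted on a random
#' background); only the coordinate frame and anchor layout are meaningful.
#'
#' @return a \code{\link{tk_reference}}.
#' @export
ref_medakaTKb <- function() {
  rec <- seq_record("medTKb_synthetic_ref", .MEDTKB_SEQ,
                    description = paste("synthetic medaka TKb-frame",
                                        "reference offset=27887"),
                    labels = list(taxon_class = "fish",
                                  fish_clade = "neoteleostei", isoform = "b"),
                    local_numbering_offset = 27887L)
  tk_reference(rec, anchors = list(
    nl_window = 1:33,
    yd_motif = 12:13,
    yd_contacts = c(43L, 116L, 170L),
    glycine_rich_loop = 46:51,
    beta3_theta = 66L,
    beta3_lysine = 68L,
    alphaC_glutamate = 83L,
    r_spine = c(87L, 98L, 157L, 180L),
    c_spine = c(53L, 66L, 120L, 165L, 166L, 167L, 224L, 228L),
    hinge_acids = c(119L, 122L),
    catalytic_aspartate = 159L,
    dfg_slot = 179:181,
    p_plus1_slot = 202L,
    crd_window = 300:355,
    alphaR1_motif = 311:316,
    minus2 = 328L,
    r7xr_first = 330L,
    r7xr_second = 338L),
    kinase_anchors = .KINASE_ANCHORS)
}

#' Human TK reference annotation
#'
#' Numbering frame of the human TK crystal structures, offset by -15 from
#' the medaka TKb frame over the kinase domain (so the catalytic aspartate
#' is D144, the P+1 tyrosine Y187, the relay residues R146/Q167/Y170 and
#' the second R-7x-R arginine R323). The sequence shipped here is synthetic
#' (see \code{\link{ref_medakaTKb}}).
#'
#' @return a \code{\link{tk_reference}}.
#' @export
ref_humanTK <- function() {
  rec <- seq_record("humanTK_synthetic_ref", .HUMANTK_SEQ,
                    description = paste("synthetic human TK-frame",
                                        "reference offset=32150"),
                    labels = list(taxon_class = "mammal",
                                  fish_clade = "none", isoform = "none"),
                    local_numbering_offset = 32150L)
  tk_reference(rec, anchors = list(
    nl_window = 1:18,
    yd_motif = 11:12,
    yd_contacts = c(28L, 101L, 155L),
    glycine_rich_loop = 31:36,
    beta3_theta = 51L,
    beta3_lysine = 53L,
    alphaC_glutamate = 68L,
    r_spine = c(72L, 83L, 142L, 165L),
    c_spine = c(38L, 51L, 105L, 150L, 151L, 152L, 209L, 213L),
    hinge_acids = c(104L, 107L),
    catalytic_aspartate = 144L,
    dfg_slot = 164:166,
    p_plus1_slot = 187L,
    crd_window = 285:342,
    alphaR1_motif = 296:301,
    minus2 = 313L,
    r7xr_first = 315L,
    r7xr_second = 323L),
    kinase_anchors = .KINASE_ANCHORS)
}
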