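#' Construct a TK sequence record
#'
#' A record holds an accession-like id, a free-text description, the residue
#' string (upper case, 20 standard letters plus X) and optional group labels.
#' \code{local_numbering_offset} records the parent-protein position of
#' residue 1, so that local construct numbering (e.g. the medaka TKb frame
#' where residue 1 corresponds to M27887 of the full titin entry) can be
#' translated back.
#'
#' @param id accession-like identifier.
#' @param residues residue string.
#' @param description free text.
#' @param labels optional list with any of \code{taxon_class}
#'   (\code{mammal}/\code{fish}/\code{other}), \code{fish_clade}
#'   (\code{neoteleostei}/\code{non-neoteleostei}/\code{none}),
#'   \code{isoform} (\code{a}/\code{b}/\code{none}).
#' @param local_numbering_offset parent-protein position of residue 1.
#' @return object of class \code{"tk_record"}.
#' @export
seq_record <- function(id, residues, description = "", labels = NULL,
                       local_numbering_offset = 1L) {
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("record '", id, "' has an empty sequence")
  bad <- setdiff(strsplit(residues, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (length(bad))
    stop("record '", id, "' contains illegal residue character(s): ",
         paste(unique(bad), collapse = ", "))
  if (!is.null(labels)) labels <- validate_labels(labels, id)
  structure(list(id = as.character(id), description = description,
                 residues = residues, labels = labels,
                 local_numbering_offset = as.integer(local_numbering_offset)),
            class = "tk_record")
}

validate_labels <- function(labels, id) {
  ok <- list(taxon_class = c("mammal", "fish", "other"),
             fish_clade = c("neoteleostei", "non-neoteleostei", "none"),
             isoform = c("a", "b", "none"))
  for (k in names(labels)) {
    if (!k %in% names(ok)) next
    if (!labels[[k]] %in% ok[[k]])
      stop("record '", id, "': label ", k, "='", labels[[k]], "' not one of ",
           paste(ok[[k]], collapse = "/"))
  }
  labels
}

#' Construct an ordered set of TK sequence records
#'
#' @param records list of \code{\link{seq_record}} objects.
#' @param provenance free-text description of where the set came from.
#' @return object of class \code{"tk_set"}.
#' @export
sequence_set <- function(records, provenance = "") {
  stopifnot(all(vapply(records, inherits, TRUE, "tk_record")))
  structure(list(records = records, provenance = provenance),
            class = "tk_set")
}

#' @export
print.tk_set <- function(x, ...) {
  cat("TK sequence set:", length(x$records), "records\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.tk_set <- function(x) length(x$records)

set_ids <- function(set) vapply(set$records, `[[`, "", "id")

#' Read a FASTA file of TK-region sequences
#'
#' Headers are parsed into an id (first whitespace-delimited token) and a
#' description. Group labels may be carried as \code{key=value} tokens in
#' the description (\code{isoform=}, \code{clade=}/\code{fish_clade=},
#' \code{class=}/\code{taxon_class=}, \code{offset=}); alternatively a
#' sidecar TSV (columns \code{id}, then any of \code{taxon_class},
#' \code{fish_clade}, \code{isoform}) supplies them, taking precedence.
#'
#' @param path FASTA file.
#' @param labels_tsv optional sidecar TSV path mapping id to labels.
#' @return a \code{\link{sequence_set}}.
#' @export
read_tk_fasta <- function(path, labels_tsv = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  fa <- Biostrings::readBStringSet(path)
  headers <- names(fa)
  seqs <- as.character(fa)
  sidecar <- NULL
  if (!is.null(labels_tsv)) {
    sidecar <- utils::read.delim(labels_tsv, stringsAsFactors = FALSE)
    if (!"id" %in% names(sidecar)) stop("labels TSV needs an 'id' column")
  }
  records <- lapply(seq_along(seqs), function(i) {
    toks <- strsplit(headers[i], "\\s+")[[1]]
    id <- toks[1]
    desc <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    lab <- parse_header_labels(desc)
    off <- lab$offset %||% 1L
    lab$offset <- NULL
    if (!is.null(sidecar)) {
      row <- sidecar[sidecar$id == id, , drop = FALSE]
      if (nrow(row) == 1L)
        for (k in intersect(c("taxon_class", "fish_clade", "isoform"),
                            names(row)))
          lab[[k]] <- as.character(row[[k]])
    }
    if (length(lab) == 0L) lab <- NULL
    seq_record(id, seqs[i], description = desc, labels = lab,
               local_numbering_offset = off)
  })
  sequence_set(records, provenance = paste("read from", path))
}

parse_header_labels <- function(desc) {
  lab <- list()
  toks <- regmatches(desc, gregexpr("[A-Za-z_]+=[^ ]+", desc))[[1]]
  for (t in toks) {
    kv <- strsplit(t, "=", fixed = TRUE)[[1]]
    key <- switch(kv[1],
                  clade = , fish_clade = "fish_clade",
                  class = , taxon_class = "taxon_class",
                  isoform = "isoform",
                  offset = "offset",
                  NA_character_)
    if (is.na(key)) next
    lab[[key]] <- if (key == "offset") as.integer(kv[2]) else kv[2]
  }
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sequence set to FASTA
#'
#' Labels are emitted as \code{key=value} tokens in the description so that
#' \code{\link{read_tk_fasta}} round-trips them.
#'
#' @param set a \code{tk_set}.
#' @param path output file.
#' @export
write_tk_fasta <- function(set, path) {
  lines <- unlist(lapply(set$records, function(r) {
    tags <- character(0)
    if (!is.null(r$labels)) {
      if (!is.null(r$labels$taxon_class))
        tags <- c(tags, paste0("class=", r$labels$taxon_class))
      if (!is.null(r$labels$fish_clade))
        tags <- c(tags, paste0("clade=", r$labels$fish_clade))
      if (!is.null(r$labels$isoform))
        tags <- c(tags, paste0("isoform=", r$labels$isoform))
    }
    if (r$local_numbering_offset != 1L)
      tags <- c(tags, paste0("offset=", r$local_numbering_offset))
    hdr <- paste0(">", r$id,
                  if (length(tags)) paste0(" ", paste(tags, collapse = " "))
                  else "")
    c(hdr, r$residues)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Curate a TK sequence set
#'
#' Applies, in order, the curation rules used to assemble comparable TK
#' region sets: (1) drop records whose description contains any excluded
#' keyword (case-insensitive; e.g. \code{"myosin light chain kinase"},
#' \code{"LOW_QUALITY"}); (2) drop exact duplicate residue strings, keeping
#' the first occurrence; (3) drop partial sequences, i.e. records whose
#' alignment to the annotated reference fails to cover every kinase-domain
#' anchor column (glycine-rich loop through P+1 loop).
#'
#' @param set a \code{tk_set}.
#' @param exclude_keywords character vector of description keywords to
#'   exclude.
#' @param reference a \code{\link{tk_reference}} annotation used for the
#'   partial-sequence test; \code{NULL} skips that step.
#' @param scheme scoring scheme for the reference mapping.
#' @return list with \code{set} (curated \code{tk_set}) and \code{report}
#'   (class \code{"tk_curation_report"}: n_input, n_removed_keyword,
#'   n_removed_duplicate, n_removed_partial, n_kept, removed_ids).
#' @export
curate_sequences <- function(set,
                             exclude_keywords = c("myosin light chain kinase",
                                                  "LOW_QUALITY"),
                             reference = NULL,
                             scheme = scoring_scheme()) {
  if (length(set$records) == 0L) stop("cannot curate an empty sequence set")
  recs <- set$records
  n_input <- length(recs)
  removed <- list(keyword = character(0), duplicate = character(0),
                  partial = character(0))

  if (length(exclude_keywords)) {
    hit <- vapply(recs, function(r) {
      any(vapply(exclude_keywords, grepl, TRUE, x = r$description,
                 ignore.case = TRUE, fixed = FALSE))
    }, TRUE)
    removed$keyword <- vapply(recs[hit], `[[`, "", "id")
    recs <- recs[!hit]
  }

  seqs <- vapply(recs, `[[`, "", "residues")
  dup <- duplicated(seqs)
  removed$duplicate <- vapply(recs[dup], `[[`, "", "id")
  recs <- recs[!dup]

  if (!is.null(reference)) {
    if (!inherits(reference, "tk_reference") ||
        length(reference$kinase_anchors) == 0L)
      stop("reference annotation has no kinase-domain anchors")
    covered <- vapply(recs, function(r) {
      cm <- tryCatch(map_columns(r, reference, scheme),
                     error = function(e) NULL)
      !is.null(cm) && all(cm$anchor_covered[reference$kinase_anchors])
    }, TRUE)
    removed$partial <- vapply(recs[!covered], `[[`, "", "id")
    recs <- recs[covered]
  }

  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("curated set still contains duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  report <- structure(list(n_input = n_input,
                           n_removed_keyword = length(removed$keyword),
                           n_removed_duplicate = length(removed$duplicate),
                           n_removed_partial = length(removed$partial),
                           n_kept = length(recs),
                           removed_ids = removed),
                      class = "tk_curation_report")
  list(set = sequence_set(recs, provenance = paste0(set$provenance,
                                                    " | curated")),
       report = report)
}

#' @export
print.tk_curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat("  input:    ", x$n_input, "\n")
  cat("  keyword:  -", x$n_removed_keyword, "\n")
  cat("  duplicate:-", x$n_removed_duplicate, "\n")
  cat("  partial:  -", x$n_removed_partial, "\n")
  cat("  kept:     ", x$n_kept, "\n")
  invisible(x)
}

#' Write a curation report as TSV or JSON
#'
#' @param report a \code{tk_curation_report}.
#' @param path output file; format chosen by extension (\code{.json} or
#'   anything else for TSV).
#' @export
write_curation_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  } else {
    df <- data.frame(metric = c("n_input", "n_removed_keyword",
                                "n_removed_duplicate", "n_removed_partial",
                                "n_kept"),
                     value = c(report$n_input, report$n_removed_keyword,
                               report$n_removed_duplicate,
                               report$n_removed_partial, report$n_kept))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
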