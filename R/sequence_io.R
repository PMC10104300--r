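# Sequence sets, subfamily grouping, and reference projection.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J")
GAP <- "-"

#' Read a protein FASTA file into a sequence set
#'
#' Reads unaligned or aligned protein FASTA. The first whitespace-delimited
#' token of each header is the record id; the remainder is kept as the
#' description (the annotation text used for subfamily grouping). Residues
#' are upper-cased and the alternative gap character \code{.} is normalised
#' to \code{-}.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class \code{seq_set} with columns \code{id},
#'   \code{description} and \code{residues}, one row per entry, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0) stop("FASTA file contains no sequences: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  residues <- toupper(as.character(set))
  residues <- gsub(".", "-", residues, fixed = TRUE)
  if (any(nchar(residues) == 0)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(residues) == 0], collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(c(AA20, AMBIGUOUS), collapse = ""), "*-]"),
               residues)
  if (any(bad)) {
    stop("unexpected characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  }
  seq_set(ids, desc, residues)
}

#' Construct a sequence set
#'
#' @param id Character vector of unique, non-empty record ids.
#' @param description Character vector of annotations (recycled if length 1).
#' @param residues Character vector of residue strings.
#' @return A \code{seq_set} data frame.
#' @export
seq_set <- function(id, description = "", residues = character()) {
  stopifnot(length(id) == length(residues))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  out <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(id)),
                    residues = as.character(residues),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Write a sequence set to FASTA
#'
#' @param x A \code{seq_set}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  hdr <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Assign sequences to subfamily groups from their annotations
#'
#' Records whose description matches any drop pattern (case-insensitive
#' substring, e.g. "hypothetical", "putative") are excluded first. The
#' remaining records are assigned to the first rule whose pattern occurs in
#' their description. Records matching no rule are reported in the
#' \code{unmatched} element, never silently dropped.
#'
#' @param records A \code{seq_set}.
#' @param rules Named list: group label -> character vector of description
#'   substrings (ordered; first match wins).
#' @param drop_patterns Character vector of substrings that exclude a record.
#' @return List with \code{groups} (named list of id vectors), \code{dropped}
#'   (ids removed by drop patterns) and \code{unmatched} (ids matching no rule).
#' @export
assign_groups <- function(records, rules, drop_patterns = character()) {
  stopifnot(inherits(records, "seq_set"))
  if (length(rules) == 0) stop("at least one grouping rule is required")
  labels <- names(rules)
  if (is.null(labels) || any(!nzchar(labels))) stop("rules must be a named list")
  if (anyDuplicated(labels)) stop("duplicate group labels: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))

  desc <- tolower(records$description)
  dropped <- rep(FALSE, nrow(records))
  for (pat in drop_patterns) {
    dropped <- dropped | grepl(tolower(pat), desc, fixed = TRUE)
  }
  groups <- stats::setNames(vector("list", length(labels)), labels)
  assigned <- rep(NA_character_, nrow(records))
  for (lab in labels) {
    pats <- tolower(rules[[lab]])
    hit <- rep(FALSE, nrow(records))
    for (pat in pats) hit <- hit | grepl(pat, desc, fixed = TRUE)
    take <- hit & !dropped & is.na(assigned)
    assigned[take] <- lab
  }
  for (lab in labels) {
    groups[[lab]] <- records$id[!is.na(assigned) & assigned == lab]
    if (length(groups[[lab]]) == 0) {
      warning("group '", lab, "' is empty after matching")
    }
  }
  list(groups = groups,
       dropped = records$id[dropped],
       unmatched = records$id[!dropped & is.na(assigned)])
}

#' Build an alignment character matrix from an aligned sequence set
#'
#' @param records A \code{seq_set} whose residues all have equal length.
#' @return Character matrix, rows named by id, one column per alignment column.
#' @export
alignment_matrix <- function(records) {
  stopifnot(inherits(records, "seq_set"))
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  }
  m <- do.call(rbind, strsplit(records$residues, ""))
  rownames(m) <- records$id
  m
}

#' Project an alignment onto a reference sequence's coordinate system
#'
#' Removes every column in which the reference row holds a gap, and numbers
#' the surviving columns 1..L along the ungapped reference, so that column i
#' of the projection corresponds to reference residue i (1-based, matching
#' residue numbers such as Arg120 or Ala247). Other rows keep whatever
#' character (residue or gap) they held in the retained columns.
#'
#' @param aln Character matrix with row names (from \code{alignment_matrix}),
#'   or a \code{seq_set} of aligned sequences.
#' @param reference_id Row id of the reference sequence.
#' @param row_groups Optional named character vector mapping row ids to group
#'   labels, carried along for grouped analyses.
#' @return A \code{proj_aln}: list with \code{reference_id},
#'   \code{site_numbers}, \code{source_columns} (original column index of each
#'   kept site), \code{ali} (character matrix) and \code{row_groups}.
#' @export
project_to_reference <- function(aln, reference_id, row_groups = NULL) {
  if (inherits(aln, "seq_set")) aln <- alignment_matrix(aln)
  stopifnot(is.matrix(aln), is.character(aln))
  if (is.null(rownames(aln))) stop("alignment matrix must have row names (ids)")
  if (!reference_id %in% rownames(aln)) {
    stop("reference id '", reference_id, "' not present in alignment")
  }
  ref <- aln[reference_id, ]
  keep <- ref != GAP
  if (!any(keep)) stop("reference row '", reference_id, "' contains only gaps")
  proj <- aln[, keep, drop = FALSE]
  if (!is.null(row_groups)) {
    row_groups <- row_groups[intersect(names(row_groups), rownames(aln))]
  }
  structure(list(reference_id = reference_id,
                 site_numbers = seq_len(sum(keep)),
                 source_columns = which(keep),
                 ali = proj,
                 row_groups = row_groups),
            class = "proj_aln")
}

#' @export
print.proj_aln <- function(x, ...) {
  cat("Projected alignment: ", nrow(x$ali), " sequences x ",
      length(x$site_numbers), " reference sites (reference ",
      x$reference_id, ")\n", sep = "")
  if (!is.null(x$row_groups)) {
    tab <- table(x$row_groups)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a projected alignment as aligned FASTA plus a site map
#'
#' @param proj A \code{proj_aln}.
#' @param path Output FASTA path.
#' @param map_path Optional TSV path for the site_number -> source alignment
#'   column mapping.
#' @return \code{path}, invisibly.
#' @export
write_projection <- function(proj, path, map_path = NULL) {
  stopifnot(inherits(proj, "proj_aln"))
  recs <- seq_set(rownames(proj$ali),
                  residues = apply(proj$ali, 1, paste, collapse = ""))
  write_fasta(recs, path)
  if (!is.null(map_path)) {
    utils::write.table(
      data.frame(site_number = proj$site_numbers,
                 source_column = proj$source_columns),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Rows of a projection belonging to a group label (or explicit id vector).
resolve_rows <- function(proj, rows) {
  ids <- rownames(proj$ali)
  if (is.null(rows)) return(ids)
  if (length(rows) == 1 && !is.null(proj$row_groups) &&
      rows %in% proj$row_groups && !(rows %in% ids)) {
    return(names(proj$row_groups)[proj$row_groups == rows])
  }
  missing <- setdiff(rows, ids)
  if (length(missing) > 0) {
    stop("row id(s) not in alignment: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  rows
}
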