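# In-frame stop-codon (pseudogene) scanning of aligned candidate genes.

#' Read a protein alignment from aligned FASTA
#'
#' All sequences must have equal (gapped) width; gaps are `-`, stop codons
#' are rendered `*`.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- as.character(Biostrings::readAAStringSet(path))
  if (length(unique(nchar(aln))) > 1L) {
    stop("sequences in '", path, "' do not share one alignment width",
         call. = FALSE)
  }
  aln
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
}

# Reference coordinate of each alignment column: number of non-gap
# reference residues up to and including the column (left-anchored, so
# insertion columns inherit the position of the residue to their left).
.ref_positions <- function(ref_chars) {
  cumsum(ref_chars != "-")
}

#' Find candidate-specific insertions in a protein alignment
#'
#' An insertion is a maximal run of alignment columns in which the
#' candidate carries a residue while at least `gap_frac` of the reference
#' sequences have gaps. Segments are anchored to the coordinate system of
#' `ref_id` (the reference position immediately left of the run).
#'
#' @param aln Named character vector of aligned sequences
#'   ([read_alignment()]): the candidate plus one or more references.
#' @param candidate_id Name of the candidate sequence in `aln`.
#' @param gap_frac Minimum fraction of references gapped for a column to be
#'   an insertion column (default 0.8).
#' @param ref_id Reference whose ungapped coordinates anchor the output;
#'   default: first non-candidate sequence.
#' @return Data.frame with one row per insertion: `col_start`, `col_end`
#'   (alignment columns, 1-based inclusive), `ref_anchor` (reference
#'   position preceding the insertion; 0 = before the first residue) and
#'   `length` (columns), sorted by `col_start`.
#' @export
find_insertions <- function(aln, candidate_id, gap_frac = 0.8,
                            ref_id = NULL) {
  if (!candidate_id %in% names(aln)) {
    stop("candidate '", candidate_id, "' not found in the alignment",
         call. = FALSE)
  }
  refs <- setdiff(names(aln), candidate_id)
  if (!length(refs)) stop("alignment has no reference sequences",
                          call. = FALSE)
  if (is.null(ref_id)) ref_id <- refs[1L]
  m <- .aln_matrix(aln[c(candidate_id, refs)])
  cand <- m[1L, ]
  refm <- m[-1L, , drop = FALSE]
  gapf <- colMeans(refm == "-")
  ins_col <- cand != "-" & gapf >= gap_frac
  refpos <- .ref_positions(.aln_matrix(aln[ref_id])[1L, ])
  r <- rle(ins_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    col_start = starts[keep], col_end = ends[keep],
    ref_anchor = ifelse(starts[keep] > 1L, refpos[starts[keep] - 1L], 0L),
    length = r$lengths[keep]
  )
}

#' Scan a candidate for in-frame stop codons within its structural domain
#'
#' Counts every `*` in the aligned candidate whose column falls inside the
#' structural-domain span (given in reference coordinates) and splits the
#' counts into stops inside vs outside candidate-specific insertions.
#' Stops inside a conserved sub-span are tallied separately. The verdict
#' is `intact` (no in-domain stop), `pseudogene_insertion_only` (every
#' in-domain stop lies in an insertion), `pseudogene_conserved_disrupted`
#' (some stop outside insertions falls in the conserved span), or
#' `pseudogene_outside_insertions` (stops outside insertions but none in
#' the conserved span; not one of the three published patterns, included
#' for completeness).
#'
#' @param aln Named character vector of aligned sequences.
#' @param candidate_id Name of the candidate sequence.
#' @param domain_span Length-2 integer vector: 1-based inclusive interval
#'   of the structural domain in reference coordinates.
#' @param conserved_span Optional length-2 interval (reference
#'   coordinates) of a highly conserved region inside the domain.
#' @param insertions Insertion segments ([find_insertions()] output); when
#'   `NULL` they are computed with `gap_frac`.
#' @param gap_frac Passed to [find_insertions()] when needed.
#' @param ref_id Reference anchoring the coordinate system (default: first
#'   non-candidate sequence).
#' @param nt_seq Optional ungapped coding nucleotide sequence of the
#'   candidate (frame +1); when given, its translation is checked against
#'   the ungapped aligned candidate.
#' @return Object of class `pseudogene_report`: list with `candidate_id`,
#'   `n_stops_total`, `n_stops_in_insertions`, `n_stops_outside_insertions`,
#'   `n_stops_in_conserved`, `insertion_segments`, `verdict` and `stops`
#'   (per-stop data.frame: alignment column, reference position,
#'   in_insertion, in_conserved).
#' @export
scan_stops <- function(aln, candidate_id, domain_span,
                       conserved_span = NULL, insertions = NULL,
                       gap_frac = 0.8, ref_id = NULL, nt_seq = NULL) {
  if (!candidate_id %in% names(aln)) {
    stop("candidate '", candidate_id, "' not found in the alignment",
         call. = FALSE)
  }
  stopifnot(length(domain_span) == 2L, domain_span[1L] <= domain_span[2L])
  refs <- setdiff(names(aln), candidate_id)
  if (is.null(ref_id)) ref_id <- refs[1L]
  if (!is.null(conserved_span)) {
    stopifnot(length(conserved_span) == 2L,
              conserved_span[1L] >= domain_span[1L],
              conserved_span[2L] <= domain_span[2L])
  }
  cand <- .aln_matrix(aln[candidate_id])[1L, ]
  if (!is.null(nt_seq)) {
    ungapped <- paste0(cand[cand != "-"], collapse = "")
    tr <- paste0(.translate_codons(substring(
      toupper(nt_seq), seq(1L, nchar(nt_seq) - 2L, by = 3L),
      seq(3L, nchar(nt_seq), by = 3L))), collapse = "")
    if (!identical(tr, ungapped)) {
      stop("translation of nt_seq does not match the ungapped aligned ",
           "candidate", call. = FALSE)
    }
  }
  if (is.null(insertions)) {
    insertions <- find_insertions(aln, candidate_id, gap_frac, ref_id)
  }
  refpos <- .ref_positions(.aln_matrix(aln[ref_id])[1L, ])
  stop_cols <- which(cand == "*")
  pos <- refpos[stop_cols]
  in_domain <- pos >= domain_span[1L] & pos <= domain_span[2L]
  stop_cols <- stop_cols[in_domain]
  pos <- pos[in_domain]
  in_ins <- vapply(stop_cols, function(j) {
    any(j >= insertions$col_start & j <= insertions$col_end)
  }, logical(1L))
  in_cons <- if (is.null(conserved_span)) rep(FALSE, length(pos)) else
    pos >= conserved_span[1L] & pos <= conserved_span[2L]
  total <- length(stop_cols)
  n_in <- sum(in_ins)
  n_out <- total - n_in
  verdict <- if (total == 0L) "intact"
  else if (n_out == 0L) "pseudogene_insertion_only"
  else if (any(in_cons & !in_ins)) "pseudogene_conserved_disrupted"
  else "pseudogene_outside_insertions"
  structure(list(
    candidate_id = candidate_id,
    n_stops_total = total,
    n_stops_in_insertions = n_in,
    n_stops_outside_insertions = n_out,
    n_stops_in_conserved = sum(in_cons),
    insertion_segments = insertions,
    verdict = verdict,
    stops = data.frame(column = stop_cols, ref_pos = pos,
                       in_insertion = in_ins, in_conserved = in_cons)
  ), class = "pseudogene_report")
}

#' @export
print.pseudogene_report <- function(x, ...) {
  cat(sprintf("%s: %d stop codon(s) in domain (%d in insertions, %d outside",
              x$candidate_id, x$n_stops_total, x$n_stops_in_insertions,
              x$n_stops_outside_insertions))
  cat(sprintf(", %d in conserved region) -> %s\n",
              x$n_stops_in_conserved, x$verdict))
  if (nrow(x$insertion_segments)) {
    for (i in seq_len(nrow(x$insertion_segments))) {
      s <- x$insertion_segments[i, ]
      n <- sum(x$stops$in_insertion &
                 x$stops$column >= s$col_start &
                 x$stops$column <= s$col_end)
      cat(sprintf("  insertion after ref position %d (%d columns): %d stop(s)\n",
                  s$ref_anchor, s$length, n))
    }
  }
  invisible(x)
}

#' Write a pseudogene report as TSV
#'
#' @param report A `pseudogene_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudogene_report <- function(report, path) {
  df <- data.frame(candidate_id = report$candidate_id,
                   n_stops_total = report$n_stops_total,
                   n_stops_in_insertions = report$n_stops_in_insertions,
                   n_stops_outside_insertions =
                     report$n_stops_outside_insertions,
                   n_stops_in_conserved = report$n_stops_in_conserved,
                   n_insertions = nrow(report$insertion_segments),
                   verdict = report$verdict,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
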