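# Sequence I/O, GC content and six-frame ORF extraction.

#' Read a nucleotide FASTA file into a DNAStringSet
#'
#' Strict multi-record FASTA reader for assembly contigs. The identifier is
#' the header token before the first whitespace. Sequences are stored
#' upper-case. Duplicate identifiers, records with no sequence, and text
#' before the first header are errors (with line numbers), since silent
#' recovery would corrupt downstream per-contig bookkeeping.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A named [Biostrings::DNAStringSet], one element per record, in
#'   file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(path))
  is_hdr <- startsWith(lines, ">")
  has_text <- nzchar(trimws(lines))
  if (!any(is_hdr)) {
    stop("not FASTA: no '>' header found in '", path, "'", call. = FALSE)
  }
  first_hdr <- which(is_hdr)[1L]
  stray <- which(has_text & !is_hdr)
  stray <- stray[stray < first_hdr]
  if (length(stray)) {
    stop("malformed FASTA at line ", stray[1L],
         ": text before first '>' header", call. = FALSE)
  }
  hdr_lines <- which(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  if (any(!nzchar(ids))) {
    bad <- hdr_lines[!nzchar(ids)][1L]
    stop("malformed FASTA at line ", bad, ": empty record id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id '", dup[1L], "' in '", path, "'",
         call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  keep <- !is_hdr & has_text
  parts <- split(gsub("[[:space:]]", "", lines[keep]), rec[keep])
  seqs <- character(length(ids))
  seqs[as.integer(names(parts))] <- vapply(parts, paste0, "", collapse = "")
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop("malformed FASTA at line ", hdr_lines[empty[1L]],
         ": record '", ids[empty[1L]], "' has no sequence", call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `DNAStringSet`/`AAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

.as_seq_chr <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
    if (is.null(names(out))) {
      names(out) <- if (length(out) == 1L) "seq1" else
        paste0("seq", seq_along(out))
    }
  } else {
    stop("expected a DNAStringSet or character vector of sequences",
         call. = FALSE)
  }
  out
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguity codes (N etc.) are excluded
#' from both numerator and denominator. A sequence with no unambiguous base
#' yields `NA` (undefined), never 0: downstream GC-based routing must treat
#' such contigs through its ambiguous path.
#'
#' @param x A `DNAStringSet` or character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' gc_content(c("GGCC", "ATAT", "ATGCN", "NNN"))
#' @export
gc_content <- function(x) {
  s <- .as_seq_chr(x)
  xx <- Biostrings::DNAStringSet(s)
  f <- Biostrings::letterFrequency(xx, letters = c("A", "C", "G", "T"))
  denom <- rowSums(f)
  gc <- (f[, "G"] + f[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  stats::setNames(as.numeric(gc), names(s))
}

# codon -> amino acid; any codon containing a non-ACGT character is 'X'
# (ambiguity never reads as a stop, so 'X' cannot terminate an ORF).
.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ORFs for one contig; see extract_orfs() for the conventions.
.orfs_one <- function(id, s, min_len_aa, require_start_codon) {
  L <- nchar(s)
  out <- vector("list", 6L)
  k <- 0L
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    str <- if (frame > 0L) s else .revcomp(s)
    off <- abs(frame) - 1L
    n_cod <- (L - off) %/% 3L
    if (n_cod < 1L) next
    starts <- off + 3L * (seq_len(n_cod) - 1L) + 1L
    aa <- .translate_codons(substring(str, starts, starts + 2L))
    r <- rle(aa != "*")
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts_i[j]
      b <- ends_i[j]
      if (require_start_codon) {
        m <- which(aa[a:b] == "M")
        if (!length(m)) next
        a <- a + m[1L] - 1L
      }
      if (b - a + 1L < min_len_aa) next
      s0 <- off + 3L * (a - 1L)     # 0-based on translated strand
      e0 <- off + 3L * b
      if (frame > 0L) {
        fwd <- c(s0, e0)
      } else {
        fwd <- c(L - e0, L - s0)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        contig_id = id, frame = frame, start = fwd[1L], end = fwd[2L],
        aa_len = b - a + 1L,
        aa_seq = paste0(aa[a:b], collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

#' Extract open reading frames in all six frames
#'
#' An ORF is a maximal stop-free run of codons in one of the six reading
#' frames (stop-to-stop; segments truncated by the contig edge are kept).
#' With `require_start_codon = TRUE` each segment is trimmed to begin at its
#' first methionine and dropped if it has none. Segments shorter than
#' `min_len_aa` amino acids (default 70, the conventional floor for
#' transcriptome ORF screens) are discarded after any trimming.
#'
#' Coordinates are 0-based half-open on the forward strand of the contig for
#' every frame, so `substring(contig, start + 1, end)` always slices the
#' genomic interval; for negative frames the slice must be
#' reverse-complemented before translation.
#'
#' @param x A `DNAStringSet` or named character vector of contigs.
#' @param min_len_aa Minimum ORF length in amino acids (>= 1).
#' @param require_start_codon Anchor ORFs at the first ATG of each segment.
#' @return A data.frame with columns `contig_id`, `frame` (one of
#'   +1,+2,+3,-1,-2,-3), `start`, `end`, `aa_len`, `aa_seq`, sorted by
#'   (contig_id, start, frame). Zero rows when nothing passes the floor.
#' @export
extract_orfs <- function(x, min_len_aa = 70L, require_start_codon = FALSE) {
  stopifnot(is.numeric(min_len_aa), min_len_aa >= 1)
  seqs <- .as_seq_chr(x)
  res <- mapply(.orfs_one, names(seqs), seqs,
                MoreArgs = list(min_len_aa = min_len_aa,
                                require_start_codon = require_start_codon),
                SIMPLIFY = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(contig_id = character(), frame = integer(),
                      start = integer(), end = integer(),
                      aa_len = integer(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$contig_id, out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write extracted ORFs as protein FASTA and/or TSV
#'
#' FASTA headers follow `contigID|frame|start-end`; the TSV carries the
#' coordinate table without sequences.
#'
#' @param orfs Output of [extract_orfs()].
#' @param fasta Optional path for amino-acid FASTA.
#' @param tsv Optional path for the coordinate TSV.
#' @return Invisibly, the paths written.
#' @export
write_orfs <- function(orfs, fasta = NULL, tsv = NULL) {
  written <- character()
  if (!is.null(fasta)) {
    aa <- Biostrings::AAStringSet(orfs$aa_seq)
    names(aa) <- sprintf("%s|%+d|%d-%d", orfs$contig_id, orfs$frame,
                         orfs$start, orfs$end)
    Biostrings::writeXStringSet(aa, fasta, width = 60L)
    written <- c(written, fasta)
  }
  if (!is.null(tsv)) {
    utils::write.table(
      orfs[, c("contig_id", "frame", "start", "end", "aa_len")],
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  invisible(written)
}
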