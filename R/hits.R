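# Tabular similarity-search and domain-scan input.

.hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
               "mismatches", "gap_opens", "q_start", "q_end",
               "s_start", "s_end", "e_value", "bit_score")
.hit_num <- .hit_cols[3:12]

#' Read a 12-column tabular hit file
#'
#' Parses the standard 12-column tab-separated alignment-hit dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, bit score).
#' `#`-prefixed comment lines and blank lines are skipped. E-values in
#' scientific notation are parsed; a literal `0.0` e-value is preserved as
#' exact zero (fold-rule arithmetic floors it later, see
#' [classify_contigs()]).
#'
#' @param path Path to a tab-separated hit table.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`, rows in file order.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  lines <- sub("\r$", "", readLines(path))
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  if (!length(lineno)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)),
      .hit_cols), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("line ", lineno[bad], ": expected 12 tab-separated columns, found ",
         nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("line ", lineno[bad], ": non-numeric value '", m[bad, j],
           "' in column ", j, " (", .hit_cols[j], ")", call. = FALSE)
    }
    out[[.hit_cols[j]]] <- v
  }
  int_cols <- c("aln_len", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  out[int_cols] <- lapply(out[int_cols], as.integer)
  out
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits A data.frame as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(.hit_cols %in% names(hits)))
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_len, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   sprintf("%.3e", hits$e_value), hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

#' Best hit per query from one database
#'
#' Reduces a hit table (all rows from searches against a single database) to
#' at most one row per query: the hit with the minimum e-value, ties broken
#' by higher bit score, then lexicographically smallest subject id. The
#' result is therefore invariant to input row order.
#'
#' @param hits A hit-table data.frame ([read_hit_table()] columns).
#' @param queries Optional character vector of query ids; the result then has
#'   exactly one row per requested query, with `NA` fields for queries that
#'   have no hits.
#' @return A data.frame of best hits (one row per query).
#' @export
best_hits <- function(hits, queries = NULL) {
  o <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  b <- h[!duplicated(h$query_id), , drop = FALSE]
  if (!is.null(queries)) {
    b <- b[match(queries, b$query_id), , drop = FALSE]
    b$query_id <- queries
  }
  rownames(b) <- NULL
  b
}

#' Read a per-sequence domain-scan table (tblout dialect)
#'
#' Whitespace-delimited per-sequence output of a profile domain scan:
#' column 1 is the domain (target) name, column 2 its accession, column 3
#' the scanned protein (query) name and column 5 the full-sequence e-value.
#' `#` comment lines are skipped.
#'
#' @param path Path to a tblout-style file.
#' @return A data.frame with columns `protein_id`, `domain_acc`,
#'   `domain_name`, `e_value`, rows in file order.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  lines <- sub("\r$", "", readLines(path))
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  if (!length(lineno)) {
    return(data.frame(protein_id = character(), domain_acc = character(),
                      domain_name = character(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[lineno]), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)[1L]
    stop("line ", lineno[bad],
         ": expected at least 5 whitespace-delimited fields, found ",
         nf[bad], call. = FALSE)
  }
  ev <- suppressWarnings(
    as.numeric(vapply(fields, `[`, "", 5L)))
  if (anyNA(ev)) {
    bad <- which(is.na(ev))[1L]
    stop("line ", lineno[bad], ": non-numeric e-value field", call. = FALSE)
  }
  data.frame(
    protein_id = vapply(fields, `[`, "", 3L),
    domain_acc = vapply(fields, `[`, "", 2L),
    domain_name = vapply(fields, `[`, "", 1L),
    e_value = ev,
    stringsAsFactors = FALSE
  )
}

#' Write domain hits in the tblout-style layout accepted by
#' [read_domain_table()]
#'
#' @param hits Data.frame with columns `protein_id`, `domain_acc`,
#'   `domain_name`, `e_value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  header <- c("# target name  accession  query name  accession  E-value",
              "#------------- ---------- ----------- ---------- -------")
  acc <- if (is.null(hits$domain_acc)) rep("-", nrow(hits)) else
    hits$domain_acc
  lines <- sprintf("%s %s %s - %s", hits$domain_name, acc,
                   hits$protein_id, sprintf("%.2e", hits$e_value))
  writeLines(c(header, lines), path)
  invisible(path)
}
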