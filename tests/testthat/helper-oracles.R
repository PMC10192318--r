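# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything character by character and share
# no code path with the package internals.

.oracle_codon_map <- local({
  m <- Biostrings::GENETIC_CODE
  function(codon) {
    if (grepl("[^ACGT]", codon)) return("X")
    unname(m[[codon]])
  }
})

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Six-frame stop-to-stop ORF finder, one codon at a time.
oracle_orfs <- function(id, s, min_len_aa = 70, require_start = FALSE) {
  s <- toupper(s)
  L <- nchar(s)
  rows <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    str <- if (frame > 0) s else oracle_revcomp(s)
    off <- abs(frame) - 1
    aa <- character(0)
    i <- off + 1
    while (i + 2 <= L) {
      aa <- c(aa, .oracle_codon_map(substr(str, i, i + 2)))
      i <- i + 3
    }
    if (!length(aa)) next
    # split on stops
    seg_start <- 1
    for (j in seq_len(length(aa) + 1)) {
      if (j <= length(aa) && aa[j] != "*") next
      a <- seg_start; b <- j - 1
      seg_start <- j + 1
      if (b < a) next
      if (require_start) {
        m <- which(aa[a:b] == "M")
        if (!length(m)) next
        a <- a + m[1] - 1
      }
      if (b - a + 1 < min_len_aa) next
      s0 <- off + 3 * (a - 1); e0 <- off + 3 * b
      if (frame > 0) { st <- s0; en <- e0 } else { st <- L - e0; en <- L - s0 }
      rows[[length(rows) + 1]] <- data.frame(
        contig_id = id, frame = frame, start = st, end = en,
        aa_len = b - a + 1, aa_seq = paste(aa[a:b], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), frame = integer(),
                      start = integer(), end = integer(),
                      aa_len = integer(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$start, out$frame), ]
  rownames(out) <- NULL
  out
}

oracle_host_decision <- function(pident, evalue, identity = 85,
                                 ethr = 1e-75) {
  if (is.na(evalue)) return("keep")
  if (pident > identity && evalue < ethr) "exclude" else "keep"
}

oracle_classify <- function(et, bt, ec, bc, efold = 100, bfold = 1.5,
                            floor = 1e-180) {
  has_t <- !is.na(et); has_c <- !is.na(ec)
  if (!has_t && !has_c) return("not_clear")
  if (has_t && !has_c) return("target")
  if (!has_t && has_c) return("contamination")
  etf <- max(et, floor); ecf <- max(ec, floor)
  if (etf <= ecf / efold && bt >= bfold * bc) return("target")
  if (ecf <= etf / efold && bc >= bfold * bt) return("contamination")
  "not_clear"
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

write_tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}
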