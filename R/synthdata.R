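# Synthetic mixed assemblies, hit tables and pseudogene fixtures with
# ground truth, for end-to-end validation of the decontamination and
# pseudogene-scanning machinery.

#' Simulate a two-population mixed assembly
#'
#' Draws per-contig GC from a low-GC parasite mode and a high-GC
#' contaminant mode (defaults Normal(0.28, 0.03) and Normal(0.55, 0.04),
#' matching the bimodal GC scatter the decontamination procedure assumes)
#' and realizes each contig by independent per-base sampling at its drawn
#' GC. Lengths are log-normal around `len_median`.
#'
#' @param n_target,n_contam Numbers of parasite and contaminant contigs
#'   (their sum must be positive).
#' @param gc_target_mean,gc_target_sd,gc_contam_mean,gc_contam_sd GC mode
#'   parameters.
#' @param len_median Median contig length (bp).
#' @param len_sdlog Log-scale standard deviation of lengths.
#' @param min_len Minimum contig length (bp).
#' @param seed Integer seed; mandatory, so every simulated assembly is
#'   reproducible.
#' @param out_dir Optional directory: writes `assembly.fasta`, a sidecar
#'   `truth.tsv`, and a `manifest.tsv` echoing paths and seed.
#' @return Object of class `sim_assembly`: list with `contigs` (named
#'   `DNAStringSet`) and `truth` (data.frame: contig_id, origin, gc_drawn,
#'   gc_realized, length).
#' @export
simulate_assembly <- function(n_target, n_contam,
                              gc_target_mean = 0.28, gc_target_sd = 0.03,
                              gc_contam_mean = 0.55, gc_contam_sd = 0.04,
                              len_median = 1000, len_sdlog = 0.45,
                              min_len = 300L, seed, out_dir = NULL) {
  n <- n_target + n_contam
  if (n == 0L) stop("n_target + n_contam must be positive", call. = FALSE)
  stopifnot(gc_target_sd > 0, gc_contam_sd > 0)
  set.seed(seed)
  origin <- rep(c("target", "contaminant"), c(n_target, n_contam))
  ids <- sprintf("%s_%05d", ifelse(origin == "target", "tg", "ct"),
                 seq_len(n))
  mu <- ifelse(origin == "target", gc_target_mean, gc_contam_mean)
  sd <- ifelse(origin == "target", gc_target_sd, gc_contam_sd)
  gc_drawn <- pmin(0.95, pmax(0.05, stats::rnorm(n, mu, sd)))
  len <- pmax(min_len, round(stats::rlnorm(n, log(len_median), len_sdlog)))
  # exact composition at the drawn GC (random arrangement), so realized GC
  # tracks the draw to within rounding even for short contigs
  seqs <- vapply(seq_len(n), function(i) {
    ngc <- round(gc_drawn[i] * len[i])
    ng <- ngc %/% 2L
    na_ <- (len[i] - ngc) %/% 2L
    bases <- c(rep("G", ng), rep("C", ngc - ng),
               rep("A", na_), rep("T", len[i] - ngc - na_))
    paste0(sample(bases), collapse = "")
  }, "")
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- ids
  truth <- data.frame(contig_id = ids, origin = origin,
                      gc_drawn = round(gc_drawn, 4L),
                      gc_realized = round(gc_content(seqs), 4L),
                      length = len, stringsAsFactors = FALSE)
  out <- structure(list(contigs = contigs, truth = truth, seed = seed),
                   class = "sim_assembly")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(contigs, file.path(out_dir, "assembly.fasta"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("file\tseed",
                 paste0("assembly.fasta\t", seed),
                 paste0("truth.tsv\t", seed)),
               file.path(out_dir, "manifest.tsv"))
  }
  out
}

# One representative codon per amino acid, for reverse translation of
# synthetic protein sequences ('*' -> TAA).
.codon_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  tapply(names(gc), gc, `[`, 1L)
}

#' Simulate best-hit tables against two databases
#'
#' For each hit-bearing contig, draws an own-database best hit (e-value
#' exponent uniform on a strong range; bit score a monotone map of the
#' exponent) and a cross-database hit weakened by the separation knobs:
#' the cross e-value is `evalue_separation` times larger (with
#' log10-normal jitter) and the cross bit score `bitscore_separation`
#' times smaller (with multiplicative noise). `evalue_separation = Inf`
#' suppresses cross-database hits entirely; `evalue_separation = 1` with
#' `bitscore_separation = 1` produces no usable signal, so fold-rule
#' classification should collapse to `not_clear`.
#'
#' @param truth Truth table from [simulate_assembly()] (columns
#'   `contig_id`, `origin`, `length`).
#' @param evalue_separation Fold weakening of the cross-database e-value.
#' @param bitscore_separation Fold weakening of the cross-database bit
#'   score.
#' @param p_no_hit Probability a contig has no hit in either table.
#' @param evalue_jitter_sd SD of the log10 jitter on the cross e-value.
#' @param bitscore_noise_sd SD of the log-normal noise on the cross bit
#'   score.
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `target_hits.tsv` and
#'   `contam_hits.tsv` in the 12-column dialect.
#' @return List of class `sim_hits` with elements `target` and `contam`
#'   (12-column hit data.frames) and `has_hit` (named logical per contig).
#' @export
simulate_hits <- function(truth, evalue_separation = 1e4,
                          bitscore_separation = 2, p_no_hit = 0.1,
                          evalue_jitter_sd = 0.5, bitscore_noise_sd = 0.05,
                          seed, out_dir = NULL) {
  stopifnot(p_no_hit >= 0, p_no_hit <= 1, evalue_separation >= 1,
            bitscore_separation >= 1)
  set.seed(seed)
  n <- nrow(truth)
  has_hit <- stats::runif(n) >= p_no_hit
  expo_own <- stats::runif(n, -150, -30)
  bits_own <- round(-2.5 * expo_own + 30, 1L)
  expo_cross <- expo_own + log10(evalue_separation) +
    stats::rnorm(n, 0, evalue_jitter_sd)
  bits_cross <- round(bits_own / (bitscore_separation *
                                    exp(stats::rnorm(n, 0, bitscore_noise_sd))), 1L)
  pid_own <- round(stats::runif(n, 82, 99), 1L)
  pid_cross <- round(stats::runif(n, 55, 85), 1L)
  aln <- pmin(truth$length %/% 3L, 500L)

  row_for <- function(i, db, own) {
    ev <- if (own) 10^expo_own[i] else min(10, 10^expo_cross[i])
    bs <- if (own) bits_own[i] else max(20, bits_cross[i])
    pid <- if (own) pid_own[i] else pid_cross[i]
    data.frame(query_id = truth$contig_id[i],
               subject_id = sprintf("%s_subj_%05d", db, i),
               pct_identity = pid, aln_len = aln[i],
               mismatches = as.integer(round(aln[i] * (100 - pid) / 100)),
               gap_opens = 0L,
               q_start = 1L, q_end = aln[i], s_start = 1L, s_end = aln[i],
               e_value = ev, bit_score = bs, stringsAsFactors = FALSE)
  }
  t_rows <- list(); c_rows <- list()
  for (i in seq_len(n)) {
    if (!has_hit[i]) next
    own_is_target <- truth$origin[i] == "target"
    t_rows[[length(t_rows) + 1L]] <-
      if (own_is_target) row_for(i, "dbT", TRUE)
      else if (is.finite(evalue_separation)) row_for(i, "dbT", FALSE)
    c_rows[[length(c_rows) + 1L]] <-
      if (!own_is_target) row_for(i, "dbC", TRUE)
      else if (is.finite(evalue_separation)) row_for(i, "dbC", FALSE)
  }
  empty_hits <- function() {
    out <- data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE)
    for (nm in c("pct_identity", "aln_len", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end", "e_value",
                 "bit_score")) out[[nm]] <- numeric()
    out
  }
  bind <- function(rows) {
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) do.call(rbind, rows) else empty_hits()
  }
  res <- structure(list(target = bind(t_rows), contam = bind(c_rows),
                        has_hit = stats::setNames(has_hit,
                                                  truth$contig_id),
                        seed = seed),
                   class = "sim_hits")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hit_table(res$target, file.path(out_dir, "target_hits.tsv"))
    write_hit_table(res$contam, file.path(out_dir, "contam_hits.tsv"))
  }
  res
}

#' Simulate an aligned pseudogene fixture with known truth
#'
#' Builds a reference protein (plus mutated reference copies), then a
#' candidate equal to the reference with planted candidate-specific
#' insertions (columns where all references are gapped) and planted
#' in-frame stop codons, either inside insertions or at chosen reference
#' positions. Also emits the candidate's coding nucleotide sequence
#' (reverse-translated, stops as TAA) and the ground-truth stop counts
#' and verdict, computed from the construction itself.
#'
#' @param n_refs Number of reference sequences.
#' @param ref_len Reference length (aa).
#' @param domain_span,conserved_span 1-based inclusive reference intervals
#'   of the structural domain and its conserved core.
#' @param insertions List of `c(anchor=, len=, stops=)` vectors: an
#'   insertion of `len` columns after reference position `anchor`, with
#'   `stops` stop codons planted inside it.
#' @param stops_outside Integer vector of reference positions at which the
#'   candidate carries a stop codon (outside insertions).
#' @param sub_rate Per-site substitution rate applied to reference copies.
#' @param seed Integer seed.
#' @return List of class `sim_pseudogene`: `aln` (named character,
#'   candidate first), `candidate_id`, `nt_seq`, `domain_span`,
#'   `conserved_span` and `truth` (list: n_stops_total,
#'   n_stops_in_insertions, n_stops_outside_insertions, verdict).
#' @export
simulate_pseudogene_fixture <- function(n_refs = 4L, ref_len = 110L,
                                        domain_span = c(10L, 100L),
                                        conserved_span = c(26L, 94L),
                                        insertions = list(),
                                        stops_outside = integer(),
                                        sub_rate = 0.08, seed) {
  set.seed(seed)
  aa20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  ref <- sample(aa20, ref_len, replace = TRUE)
  refs <- lapply(seq_len(n_refs), function(i) {
    mut <- stats::runif(ref_len) < sub_rate
    out <- ref
    out[mut] <- sample(aa20, sum(mut), replace = TRUE)
    out
  })
  cand <- ref
  if (length(stops_outside)) {
    stopifnot(all(stops_outside >= 1L), all(stops_outside <= ref_len))
    cand[stops_outside] <- "*"
  }
  anchors <- vapply(insertions, function(x) as.integer(x[["anchor"]]), 1L)
  stopifnot(!is.unsorted(anchors, strictly = TRUE) || length(anchors) <= 1L)

  cand_cols <- as.list(cand)
  ref_cols <- lapply(seq_len(ref_len),
                     function(j) vapply(refs, `[`, "", j))
  ins_cols <- integer()   # alignment columns that belong to insertions
  out_cand <- character(); out_refs <- vector("list", 0L)
  col <- 0L
  planted_in <- 0L
  for (p in 0:ref_len) {
    if (p >= 1L) {
      col <- col + 1L
      out_cand[col] <- cand_cols[[p]]
      out_refs[[col]] <- ref_cols[[p]]
    }
    hit <- which(anchors == p)
    for (h in hit) {
      len <- as.integer(insertions[[h]][["len"]])
      nstop <- as.integer(insertions[[h]][["stops"]])
      stopifnot(nstop <= len)
      block <- sample(aa20, len, replace = TRUE)
      if (nstop > 0L) {
        block[sort(sample.int(len, nstop))] <- "*"
      }
      for (b in block) {
        col <- col + 1L
        out_cand[col] <- b
        out_refs[[col]] <- rep("-", n_refs)
        ins_cols <- c(ins_cols, col)
      }
      if (p >= domain_span[1L] && p <= domain_span[2L]) {
        planted_in <- planted_in + nstop
      }
    }
  }
  aln <- c(paste0(out_cand, collapse = ""),
           vapply(seq_len(n_refs), function(i) {
             paste0(vapply(out_refs, `[`, "", i), collapse = "")
           }, ""))
  names(aln) <- c("candidate", paste0("ref", seq_len(n_refs)))

  codon <- .codon_for_aa()
  ungapped <- out_cand[out_cand != "-"]
  nt_seq <- paste0(ifelse(ungapped == "*", "TAA", codon[ungapped]),
                   collapse = "")

  n_out <- sum(stops_outside >= domain_span[1L] &
                 stops_outside <= domain_span[2L])
  total <- planted_in + n_out
  conserved_hit <- any(stops_outside >= conserved_span[1L] &
                         stops_outside <= conserved_span[2L])
  verdict <- if (total == 0L) "intact"
  else if (n_out == 0L) "pseudogene_insertion_only"
  else if (conserved_hit) "pseudogene_conserved_disrupted"
  else "pseudogene_outside_insertions"

  structure(list(aln = aln, candidate_id = "candidate", nt_seq = nt_seq,
                 domain_span = as.integer(domain_span),
                 conserved_span = as.integer(conserved_span),
                 truth = list(n_stops_total = total,
                              n_stops_in_insertions = planted_in,
                              n_stops_outside_insertions = n_out,
                              verdict = verdict),
                 seed = seed),
            class = "sim_pseudogene")
}
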