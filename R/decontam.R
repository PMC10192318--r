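# Decontamination of mixed assemblies: host-genome exclusion, dual-database
# three-way classification, and GC-content rescue of ambiguous contigs.

#' Host-genome contig exclusion
#'
#' A contig is excluded when its best hit against the host genome shows
#' strictly more than `identity_threshold` percent identity AND an e-value
#' strictly below `evalue_threshold` (defaults 85 and 1e-75). Both
#' comparisons are strict: a best hit at exactly 85% identity is kept.
#' Contigs without a host hit are kept.
#'
#' @param best A best-hit data.frame ([best_hits()]) for the host database;
#'   rows with `NA` fields mean "no hit".
#' @param identity_threshold Percent identity threshold (strict `>`).
#' @param evalue_threshold E-value threshold (strict `<`).
#' @return A data.frame with columns `query_id`, `decision`
#'   (`"keep"`/`"exclude"`), `pct_identity`, `e_value`.
#' @export
host_filter <- function(best, identity_threshold = 85, evalue_threshold = 1e-75) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 100,
            evalue_threshold > 0)
  hit <- !is.na(best$e_value)
  excl <- hit & best$pct_identity > identity_threshold &
    best$e_value < evalue_threshold
  data.frame(query_id = best$query_id,
             decision = ifelse(excl, "exclude", "keep"),
             pct_identity = best$pct_identity,
             e_value = best$e_value,
             stringsAsFactors = FALSE)
}

#' Three-way contig classification from dual-database best hits
#'
#' Implements the fold rule on per-query best hits against a target-clade
#' database and a contaminant database: a contig is labelled `target` when
#' the target best hit's e-value is at least `evalue_fold` times smaller
#' AND its bit score at least `bitscore_fold` times larger than the
#' contaminant best hit's ("at least" is inclusive); `contamination` when
#' the mirrored conditions hold; otherwise `not_clear`. Exact-zero e-values
#' are floored at `evalue_floor` before ratios are formed, keeping zero as
#' strongest-possible evidence while leaving the fold arithmetic defined.
#'
#' Single-sided evidence (a hit in exactly one database) is decided toward
#' that database; contigs with no hit in either database receive
#' `no_hit_label` (default `not_clear`, which routes them to GC rescue).
#'
#' @param target_best,contam_best Best-hit data.frames for the two databases
#'   ([best_hits()]), aligned on the same query universe (`NA` rows = no
#'   hit). Queries present in only one frame are treated as no-hit in the
#'   other.
#' @param evalue_fold E-value fold requirement (> 1, default 100).
#' @param bitscore_fold Bit-score fold requirement (> 1, default 1.5).
#' @param evalue_floor Replacement for exact-zero e-values (default 1e-180).
#' @param no_hit_label Label for queries with no hits at all.
#' @return A data.frame with columns `query_id`, `label` (`target` /
#'   `contamination` / `not_clear`), `rule` (which rule fired), and the
#'   evidence columns `e_target`, `bits_target`, `e_contam`, `bits_contam`.
#' @export
classify_contigs <- function(target_best, contam_best,
                             evalue_fold = 100, bitscore_fold = 1.5,
                             evalue_floor = 1e-180,
                             no_hit_label = "not_clear") {
  stopifnot(evalue_fold > 1, bitscore_fold > 1, evalue_floor > 0)
  ids <- union(target_best$query_id, contam_best$query_id)
  ti <- match(ids, target_best$query_id)
  ci <- match(ids, contam_best$query_id)
  et <- target_best$e_value[ti]
  bt <- target_best$bit_score[ti]
  ec <- contam_best$e_value[ci]
  bc <- contam_best$bit_score[ci]
  etf <- pmax(et, evalue_floor)
  ecf <- pmax(ec, evalue_floor)
  has_t <- !is.na(et)
  has_c <- !is.na(ec)

  label <- rep("not_clear", length(ids))
  rule <- rep("fold_rule_not_clear", length(ids))

  both <- has_t & has_c
  tgt <- both & etf <= ecf / evalue_fold & bt >= bitscore_fold * bc
  con <- both & ecf <= etf / evalue_fold & bc >= bitscore_fold * bt
  label[tgt] <- "target"; rule[tgt] <- "fold_rule_target"
  label[con] <- "contamination"; rule[con] <- "fold_rule_contamination"

  only_t <- has_t & !has_c
  only_c <- has_c & !has_t
  label[only_t] <- "target"; rule[only_t] <- "single_db_target"
  label[only_c] <- "contamination"; rule[only_c] <- "single_db_contamination"

  none <- !has_t & !has_c
  label[none] <- no_hit_label; rule[none] <- "no_hits"

  data.frame(query_id = ids, label = label, rule = rule,
             e_target = et, bits_target = bt,
             e_contam = ec, bits_contam = bc,
             stringsAsFactors = FALSE)
}

#' GC-content rescue of ambiguous contigs
#'
#' Routes `not_clear` contigs by GC fraction: `gc <= cutoff` goes to
#' `target` (the parasite mode is the low-GC one), `gc > cutoff` to
#' `contamination`. The boundary is inclusive on the low side. Contigs with
#' undefined GC (no unambiguous base) cannot be routed by this rule and
#' default to `undefined_to` (conservative `"contamination"`) with a
#' warning.
#'
#' @param gc Numeric vector of GC fractions (`NA` = undefined).
#' @param cutoff GC cutoff in (0, 1); e.g. the published presets in
#'   [gc_cutoff_presets()], or a value from [estimate_gc_cutoff()].
#' @param undefined_to Label for undefined-GC contigs.
#' @return Character vector of labels (`target`/`contamination`).
#' @export
gc_partition <- function(gc, cutoff, undefined_to = "contamination") {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff < 1)
  out <- ifelse(gc <= cutoff, "target", "contamination")
  if (anyNA(gc)) {
    warning(sum(is.na(gc)), " contig(s) with undefined GC routed to '",
            undefined_to, "'", call. = FALSE)
    out[is.na(gc)] <- undefined_to
  }
  out
}

#' Published GC-cutoff presets
#'
#' The cutoffs used for the malacosporean transcriptome assemblies:
#' 39.03% for *Buddenbrockia plumatellae*, 40.80% for the
#' *Tetracapsuloides bryosalmonae* assembly from fish kidney, and 36.92%
#' for *T. bryosalmonae* from the bryozoan host.
#'
#' @return Named numeric vector of GC fractions.
#' @export
gc_cutoff_presets <- function() {
  c(b_plumatellae = 0.3903,
    t_bryosalmonae_fish = 0.4080,
    t_bryosalmonae_bryozoan = 0.3692)
}

#' Estimate a GC cutoff from a bimodal GC distribution
#'
#' Kernel-density valley search: the empirical GC density is estimated on
#' `[0, 1]` and the cutoff is placed at the density minimum between the two
#' tallest modes. This automates the manual choice of a boundary between a
#' low-GC parasite mode and a high-GC contaminant mode on a GC scatter.
#' Entirely deterministic.
#'
#' @param gc Numeric vector of GC fractions; needs at least 20 defined
#'   values.
#' @param valley_range The valley must fall inside this interval (default
#'   `c(0.15, 0.70)`); otherwise, or if the density is unimodal, an error
#'   asks for an explicit cutoff.
#' @param bw,n Kernel bandwidth rule and grid size passed to
#'   [stats::density()].
#' @param min_peak_frac Modes below this fraction of the tallest mode are
#'   ignored as noise.
#' @return The cutoff (GC fraction), with attributes `method` and `peaks`.
#' @export
estimate_gc_cutoff <- function(gc, valley_range = c(0.15, 0.70),
                               bw = "nrd0", n = 1024L,
                               min_peak_frac = 0.05) {
  gc <- gc[!is.na(gc)]
  if (length(gc) < 20L) {
    stop("need at least 20 defined GC values to estimate a cutoff; ",
         "supply an explicit cutoff instead", call. = FALSE)
  }
  d <- stats::density(gc, bw = bw, n = n, from = 0, to = 1)
  y <- d$y
  dy <- diff(y)
  peaks <- which(diff(sign(dy)) == -2L) + 1L
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y[peaks])]
  if (length(peaks) < 2L) {
    stop("GC distribution appears unimodal in (", valley_range[1L], ", ",
         valley_range[2L], "); supply an explicit cutoff", call. = FALSE)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  cutoff <- d$x[between[which.min(y[between])]]
  if (cutoff <= valley_range[1L] || cutoff >= valley_range[2L]) {
    stop("no density valley inside (", valley_range[1L], ", ",
         valley_range[2L], "); supply an explicit cutoff", call. = FALSE)
  }
  structure(cutoff, method = "kde_valley", bw = d$bw,
            peaks = d$x[peaks])
}

#' Run the full decontamination pipeline on an assembly
#'
#' Orchestrates, per contig: (1) optional host-genome exclusion
#' ([host_filter()]); (2) three-way classification from dual-database best
#' hits ([classify_contigs()]); (3) GC rescue of the `not_clear` group
#' ([gc_partition()]), with the cutoff either given, taken from
#' [gc_cutoff_presets()] by name, or estimated from the `not_clear` GC
#' distribution ([estimate_gc_cutoff()]) when `gc_cutoff = "auto"`.
#'
#' @param assembly A `DNAStringSet`, named character vector, or path to a
#'   FASTA file of contigs.
#' @param target_hits,contam_hits Hit tables (data.frames or paths) against
#'   the target-clade and contaminant databases.
#' @param host_hits Optional hit table against the host genome.
#' @param identity_threshold,evalue_threshold Host-filter thresholds.
#' @param evalue_fold,bitscore_fold,evalue_floor Classifier parameters.
#' @param gc_cutoff Numeric cutoff in (0,1), a preset name, or `"auto"`.
#' @param no_hit_label Label for hitless contigs before GC rescue.
#' @param out_dir Optional directory; when given, writes `target.fasta`,
#'   `classification.tsv` (with a parameter header), and `gc_length.tsv`.
#' @return An object of class `decontam_run`: a list with `report` (per
#'   contig: id, length, gc, initial label, final label, rule, evidence),
#'   `counts`, `gc_cutoff_used`, `params`, and `unknown_queries`.
#' @export
run_decontam <- function(assembly, target_hits, contam_hits,
                         host_hits = NULL,
                         identity_threshold = 85, evalue_threshold = 1e-75,
                         evalue_fold = 100, bitscore_fold = 1.5,
                         evalue_floor = 1e-180,
                         gc_cutoff = "auto",
                         no_hit_label = "not_clear",
                         out_dir = NULL) {
  if (is.character(assembly) && length(assembly) == 1L &&
      file.exists(assembly)) {
    assembly <- read_fasta(assembly)
  }
  contigs <- .as_seq_chr(assembly)
  ids <- names(contigs)
  if (anyDuplicated(ids)) stop("duplicate contig ids in assembly",
                               call. = FALSE)
  load_hits <- function(h) {
    if (is.character(h) && length(h) == 1L) read_hit_table(h) else h
  }
  target_hits <- load_hits(target_hits)
  contam_hits <- load_hits(contam_hits)
  host_hits <- if (!is.null(host_hits)) load_hits(host_hits)

  unknown <- setdiff(
    unique(c(target_hits$query_id, contam_hits$query_id,
             host_hits$query_id)), ids)
  if (length(unknown)) {
    warning(length(unknown),
            " hit-table query id(s) not present in the assembly (e.g. '",
            unknown[1L], "')", call. = FALSE)
  }

  gc <- gc_content(contigs)
  len <- nchar(contigs)
  report <- data.frame(contig_id = ids, length = len, gc = round(gc, 4L),
                       stringsAsFactors = FALSE)

  # stage 1: host exclusion
  excluded <- character()
  if (!is.null(host_hits)) {
    hb <- best_hits(host_hits, queries = ids)
    hf <- host_filter(hb, identity_threshold, evalue_threshold)
    excluded <- hf$query_id[hf$decision == "exclude"]
  }
  remaining <- setdiff(ids, excluded)

  # stage 2: dual-database classification
  tb <- best_hits(target_hits, queries = remaining)
  cb <- best_hits(contam_hits, queries = remaining)
  cls <- classify_contigs(tb, cb, evalue_fold, bitscore_fold, evalue_floor,
                          no_hit_label)
  cls <- cls[match(remaining, cls$query_id), , drop = FALSE]

  # stage 3: GC rescue of the not_clear group
  nc <- cls$query_id[cls$label == "not_clear"]
  cutoff_used <- NA_real_
  if (length(nc)) {
    if (identical(gc_cutoff, "auto")) {
      cutoff_used <- as.numeric(estimate_gc_cutoff(gc[nc]))
    } else if (is.character(gc_cutoff)) {
      presets <- gc_cutoff_presets()
      if (!gc_cutoff %in% names(presets)) {
        stop("unknown GC-cutoff preset '", gc_cutoff, "'; available: ",
             paste(names(presets), collapse = ", "), call. = FALSE)
      }
      cutoff_used <- presets[[gc_cutoff]]
    } else {
      cutoff_used <- as.numeric(gc_cutoff)
    }
    rescue <- gc_partition(gc[nc], cutoff_used)
  }

  idx <- match(ids, cls$query_id)
  report$initial_label <- ifelse(ids %in% excluded, "host_excluded",
                                 cls$label[idx])
  report$label <- report$initial_label
  report$rule <- ifelse(ids %in% excluded, "host_filter", cls$rule[idx])
  if (length(nc)) {
    j <- match(nc, ids)
    report$label[j] <- rescue
    report$rule[j] <- paste0("gc_rescue_", rescue)
  }
  report$e_target <- cls$e_target[idx]
  report$bits_target <- cls$bits_target[idx]
  report$e_contam <- cls$e_contam[idx]
  report$bits_contam <- cls$bits_contam[idx]

  counts <- c(table(factor(report$label,
                           levels = c("target", "contamination",
                                      "host_excluded", "not_clear"))))
  stopifnot(sum(counts) == length(ids))

  params <- list(identity_threshold = identity_threshold,
                 evalue_threshold = evalue_threshold,
                 evalue_fold = evalue_fold, bitscore_fold = bitscore_fold,
                 evalue_floor = evalue_floor, gc_cutoff = gc_cutoff,
                 no_hit_label = no_hit_label)
  res <- structure(list(report = report, counts = counts,
                        gc_cutoff_used = cutoff_used, params = params,
                        unknown_queries = unknown),
                   class = "decontam_run")
  if (!is.null(out_dir)) .write_decontam(res, contigs, out_dir)
  res
}

.write_decontam <- function(res, contigs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- res$report$contig_id[res$report$label == "target"]
  write_fasta(Biostrings::DNAStringSet(contigs[keep]),
              file.path(out_dir, "target.fasta"))
  hdr <- c(sprintf("# %s = %s", names(res$params),
                   vapply(res$params, function(x) paste(format(x),
                                                        collapse = ","), "")),
           sprintf("# gc_cutoff_used = %s", format(res$gc_cutoff_used)))
  path <- file.path(out_dir, "classification.tsv")
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    res$report, path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  utils::write.table(
    res$report[, c("contig_id", "length", "gc", "label")],
    file.path(out_dir, "gc_length.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.decontam_run <- function(x, ...) {
  cat("Decontamination run:", sum(x$counts), "contigs\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-14s %d\n", nm, x$counts[[nm]]))
  }
  if (!is.na(x$gc_cutoff_used)) {
    cat(sprintf("  GC cutoff used: %.4f\n", x$gc_cutoff_used))
  }
  invisible(x)
}
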