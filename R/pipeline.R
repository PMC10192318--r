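# Declarative end-to-end pipeline: config validation, orchestration,
# run manifest.

# section -> key -> list(default, type, required, is_path)
.config_schema <- function() {
  key <- function(default = NULL, type = "character", required = FALSE,
                  is_path = FALSE) {
    list(default = default, type = type, required = required,
         is_path = is_path)
  }
  list(
    input = list(
      assembly = key(required = TRUE, is_path = TRUE),
      target_hits = key(required = TRUE, is_path = TRUE),
      contam_hits = key(required = TRUE, is_path = TRUE),
      host_hits = key(is_path = TRUE),
      catalogue = key(is_path = TRUE),
      alignment = key(is_path = TRUE),
      out_dir = key(required = TRUE)
    ),
    host_filter = list(
      identity = key(85, "numeric"),
      evalue = key(1e-75, "numeric")
    ),
    classify = list(
      evalue_fold = key(100, "numeric"),
      bitscore_fold = key(1.5, "numeric"),
      evalue_floor = key(1e-180, "numeric")
    ),
    gc = list(
      cutoff = key("auto")   # numeric string, preset name, or "auto"
    ),
    orf = list(
      min_len_aa = key(70, "numeric"),
      require_start_codon = key(FALSE, "logical")
    ),
    pseudoscan = list(
      candidate_id = key(),
      domain_start = key(type = "numeric"),
      domain_end = key(type = "numeric"),
      conserved_start = key(type = "numeric"),
      conserved_end = key(type = "numeric"),
      gap_frac = key(0.8, "numeric")
    ),
    run = list(
      seed = key(1, "numeric")
    )
  )
}

.parse_ini <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*[#;]", lines)]
  section <- NA_character_
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section)) {
        stop("config line outside any [section]: '", ln, "'", call. = FALSE)
      }
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1L])]] <- trimws(kv[2L])
    } else {
      stop("unparseable config line: '", ln, "'", call. = FALSE)
    }
  }
  out
}

#' Validate a pipeline configuration file
#'
#' Reads a flat INI-style config (`[section]` headers, `key = value`
#' lines, `#` comments), checks it against the full parameter schema, and
#' returns a fully defaulted configuration. All problems — unknown
#' sections or keys (with a nearest-key suggestion), missing required
#' keys, type errors, missing input files — are aggregated into a single
#' error report rather than failing one at a time.
#'
#' @param path Path to the config file.
#' @return Object of class `run_config`: nested list
#'   `config$<section>$<key>` with defaults filled in.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'",
                               call. = FALSE)
  raw <- .parse_ini(path)
  schema <- .config_schema()
  errs <- character()
  cfg <- lapply(schema, function(sec) lapply(sec, `[[`, "default"))

  for (sec in names(raw)) {
    if (!sec %in% names(schema)) {
      errs <- c(errs, paste0("unknown section [", sec, "]"))
      next
    }
    for (k in names(raw[[sec]])) {
      if (!k %in% names(schema[[sec]])) {
        sug <- utils::adist(k, names(schema[[sec]]))
        hint <- names(schema[[sec]])[which.min(sug)]
        errs <- c(errs, paste0("unknown key '", k, "' in [", sec,
                               "]; did you mean '", hint, "'?"))
        next
      }
      v <- raw[[sec]][[k]]
      spec <- schema[[sec]][[k]]
      if (spec$type == "numeric" ||
          (sec == "gc" && k == "cutoff" && v != "auto" &&
           !v %in% names(gc_cutoff_presets()))) {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) {
          errs <- c(errs, paste0("[", sec, "] ", k, ": expected a number, ",
                                 "got '", v, "'"))
          next
        }
        v <- num
      } else if (spec$type == "logical") {
        lv <- toupper(v) %in% c("TRUE", "YES", "1")
        if (!toupper(v) %in% c("TRUE", "YES", "1", "FALSE", "NO", "0")) {
          errs <- c(errs, paste0("[", sec, "] ", k,
                                 ": expected true/false, got '", v, "'"))
          next
        }
        v <- lv
      }
      cfg[[sec]][[k]] <- v
    }
  }
  for (sec in names(schema)) {
    for (k in names(schema[[sec]])) {
      spec <- schema[[sec]][[k]]
      val <- cfg[[sec]][[k]]
      if (spec$required && is.null(val)) {
        errs <- c(errs, paste0("missing required key '", k, "' in [",
                               sec, "]"))
      }
      if (spec$is_path && !is.null(val) && !file.exists(val)) {
        errs <- c(errs, paste0("[", sec, "] ", k, ": file not found: '",
                               val, "'"))
      }
    }
  }
  if (length(errs)) {
    stop("invalid config '", path, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline from a validated configuration
#'
#' Stages: decontamination ([run_decontam()]) of the assembly; six-frame
#' ORF extraction ([extract_orfs()]) on the retained (target) contigs;
#' optionally, presence-matrix and loss-gradient construction from a
#' catalogue TSV; optionally, pseudogene scanning of an aligned candidate.
#' Every stage writes plain files under the run directory, and a manifest
#' records input checksums, parameters and per-stage record counts.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   config file.
#' @return Invisibly, a list with `manifest` (data.frame) and the per-stage
#'   results. Fails with the stage name on any stage error.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$input$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list()
  note <- function(file, n) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file,
      md5 = unname(tools::md5sum(file)),
      n_records = n, stringsAsFactors = FALSE)
  }
  for (f in c("assembly", "target_hits", "contam_hits", "host_hits",
              "catalogue", "alignment")) {
    p <- config$input[[f]]
    if (!is.null(p)) note(p, NA_integer_)
  }

  assembly <- stage("read_assembly", read_fasta(config$input$assembly))
  if (!length(assembly)) stop("stage 'read_assembly' failed: empty assembly",
                              call. = FALSE)

  dec <- stage("decontam", run_decontam(
    assembly,
    target_hits = config$input$target_hits,
    contam_hits = config$input$contam_hits,
    host_hits = config$input$host_hits,
    identity_threshold = config$host_filter$identity,
    evalue_threshold = config$host_filter$evalue,
    evalue_fold = config$classify$evalue_fold,
    bitscore_fold = config$classify$bitscore_fold,
    evalue_floor = config$classify$evalue_floor,
    gc_cutoff = config$gc$cutoff,
    out_dir = out_dir))
  note(file.path(out_dir, "classification.tsv"), nrow(dec$report))

  kept <- dec$report$contig_id[dec$report$label == "target"]
  orfs <- stage("orfs", extract_orfs(
    assembly[kept],
    min_len_aa = config$orf$min_len_aa,
    require_start_codon = config$orf$require_start_codon))
  write_orfs(orfs, fasta = file.path(out_dir, "orfs.fasta"),
             tsv = file.path(out_dir, "orfs.tsv"))
  note(file.path(out_dir, "orfs.tsv"), nrow(orfs))

  mat <- grad <- NULL
  if (!is.null(config$input$catalogue)) {
    cat_ <- stage("catalogue", catalogue_from_table(config$input$catalogue))
    mat <- stage("matrix", build_matrix(cat_))
    # summarise along the parasitism gradient when those taxa are present;
    # otherwise fall back to the catalogue's own taxon order
    grad_order <- if (all(parasitism_gradient() %in% mat$taxa))
      parasitism_gradient() else mat$taxa
    grad <- stage("gradient", loss_gradient(mat, order = grad_order))
    write_matrix(mat, cells_tsv = file.path(out_dir, "presence_matrix.tsv"),
                 counts_tsv = file.path(out_dir, "presence_counts.tsv"))
    utils::write.table(
      data.frame(taxon = grad$order, retention = grad$retention,
                 non_increasing = grad$non_increasing),
      file.path(out_dir, "loss_gradient.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(out_dir, "presence_matrix.tsv"), length(mat$taxa))
  }

  ps <- NULL
  if (!is.null(config$input$alignment)) {
    pc <- config$pseudoscan
    if (is.null(pc$candidate_id) || is.null(pc$domain_start) ||
        is.null(pc$domain_end)) {
      stop("stage 'pseudoscan' failed: candidate_id, domain_start and ",
           "domain_end are required when an alignment is given",
           call. = FALSE)
    }
    cons <- if (!is.null(pc$conserved_start) && !is.null(pc$conserved_end))
      c(pc$conserved_start, pc$conserved_end)
    ps <- stage("pseudoscan", scan_stops(
      read_alignment(config$input$alignment), pc$candidate_id,
      domain_span = c(pc$domain_start, pc$domain_end),
      conserved_span = cons, gap_frac = pc$gap_frac))
    write_pseudogene_report(ps, file.path(out_dir, "pseudogene_report.tsv"))
    note(file.path(out_dir, "pseudogene_report.tsv"), ps$n_stops_total)
  }

  manifest <- do.call(rbind, manifest)
  params <- data.frame(
    key = c("seed", "identity", "evalue", "evalue_fold", "bitscore_fold",
            "evalue_floor", "gc_cutoff", "min_len_aa"),
    value = c(config$run$seed, config$host_filter$identity,
              config$host_filter$evalue, config$classify$evalue_fold,
              config$classify$bitscore_fold, config$classify$evalue_floor,
              format(config$gc$cutoff), config$orf$min_len_aa),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(params, file.path(out_dir, "params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, decontam = dec, orfs = orfs,
                 matrix = mat, gradient = grad, pseudoscan = ps))
}
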