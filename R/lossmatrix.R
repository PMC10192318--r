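# Taxon x apoptotic-actor presence/absence matrix and loss-gradient summary.

#' The ten apoptotic actor categories
#'
#' Canonical category identifiers used throughout the catalogue and matrix
#' functions: caspases, multidomain Bcl-2 family, BH3-only proteins, death
#' receptors, adaptor proteins (FADD/TRADD-like), inhibitors of apoptosis,
#' APAF-1, p53, cytochrome C, and calpains.
#'
#' @return Character vector of the ten category names, in pathway order.
#' @export
actor_categories <- function() {
  c("caspase", "bcl2_multidomain", "bh3_only", "death_receptor",
    "adaptor_protein", "iap", "apaf1", "p53", "cytochrome_c", "calpain")
}

#' Parasitism gradient order
#'
#' Taxa ordered from free-living to most reduced parasite; the retention of
#' apoptotic actor categories is expected to be non-increasing along it.
#'
#' @return Character vector of the four gradient taxa.
#' @export
parasitism_gradient <- function() {
  c("Free-living Cnidaria", "Polypodium", "Malacosporea", "Myxosporea")
}

.actor_statuses <- c("intact", "pseudogene", "absent_marker")

#' Build an actor catalogue from a table
#'
#' Validates a long-format catalogue of apoptotic-actor homologs: one row
#' per (taxon, category, protein). `status` distinguishes intact genes,
#' pseudogenes (in-frame stop codons), and explicit absence markers (rows
#' that document a looked-for-but-missing gene; they never count as
#' present). Optional columns: `species` (per-species expansion of a taxon
#' group) and `flags` (comma-separated free-form marks such as
#' `initiator_card` or `classical`).
#'
#' @param x A data.frame or a path to a TSV with columns `taxon`,
#'   `category`, `protein_id`, `status` (optionally `species`, `flags`).
#' @param taxon_order Optional ordered character vector of taxa; defaults to
#'   order of first appearance. Every catalogue taxon must appear in it.
#' @return An object of class `actor_catalogue`: list with `entries`
#'   (validated data.frame) and `taxon_order`.
#' @export
catalogue_from_table <- function(x, taxon_order = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE, fill = TRUE)
  }
  need <- c("taxon", "category", "protein_id", "status")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("catalogue table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$species)) x$species <- x$taxon
  if (is.null(x$flags)) x$flags <- rep("", nrow(x))
  x$flags[is.na(x$flags)] <- ""
  if (nrow(x)) {
    bad <- setdiff(unique(x$category), actor_categories())
    if (length(bad)) {
      stop("unknown actor category '", bad[1L], "'; allowed: ",
           paste(actor_categories(), collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(unique(x$status), .actor_statuses)
    if (length(bad)) {
      stop("unknown status '", bad[1L], "'; allowed: ",
           paste(.actor_statuses, collapse = ", "), call. = FALSE)
    }
    key <- paste(x$taxon, x$category, x$protein_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- x[duplicated(key), , drop = FALSE][1L, ]
      stop("duplicate catalogue entry (", d$taxon, ", ", d$category, ", ",
           d$protein_id, ")", call. = FALSE)
    }
  }
  if (is.null(taxon_order)) taxon_order <- unique(x$taxon)
  extra <- setdiff(unique(x$taxon), taxon_order)
  if (length(extra)) {
    stop("taxa missing from taxon_order: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = x[, c("taxon", "species", "category",
                                 "protein_id", "status", "flags")],
                 taxon_order = taxon_order),
            class = "actor_catalogue")
}

#' The packaged apoptotic-actor catalogue for Cnidaria and outgroups
#'
#' Transcription of the published presence table of the main apoptotic
#' actors across Myxosporea, Malacosporea, *Polypodium hydriforme*,
#' free-living Cnidaria (*Hydra vulgaris*), *Caenorhabditis elegans* and
#' *Homo sapiens*, with pseudogene and absence annotations for the
#' myxosporean cytochrome C genes. The calpain row for *Polypodium*
#' follows the four-calpain reading (Calp-5, Calp-7 and two classical
#' calpains) supported by the text and the domain-structure figure.
#'
#' @return An `actor_catalogue` whose `taxon_order` starts with the
#'   parasitism gradient ([parasitism_gradient()]) followed by the two
#'   non-cnidarian outgroups.
#' @export
table1_catalogue <- function() {
  path <- system.file("extdata", "table1_actors.tsv", package = "myxoloss",
                      mustWork = TRUE)
  catalogue_from_table(
    path,
    taxon_order = c(parasitism_gradient(),
                    "Caenorhabditis elegans", "Homo sapiens"))
}

#' Default domain-to-category assignment rules
#'
#' Shipped, editable mapping from structural domain names to actor
#' categories. A protein joins a category when all of the category's
#' `required` domains are present; each named flag is set when its own
#' domain set is additionally complete (e.g. a caspase with a CARD domain
#' is flagged as an intrinsic-pathway initiator; a calpain with both
#' peptidase domains and an EF-hand is flagged classical). These rules are
#' a deliberately mechanical stand-in for expert domain-architecture
#' curation.
#'
#' @return Named list: per category, a list with `required` (character
#'   vector of domain names) and `flags` (named list of domain vectors).
#' @export
default_category_map <- function() {
  list(
    caspase = list(required = "Caspase_P20",
                   flags = list(initiator_card = "CARD",
                                initiator_ded = "DED")),
    bcl2_multidomain = list(required = "Bcl-2",
                            flags = list(bh4 = "BH4")),
    bh3_only = list(required = "BH3", flags = list()),
    death_receptor = list(required = c("TNFR_c6", "Death"), flags = list()),
    adaptor_protein = list(required = c("DED", "Death"), flags = list()),
    iap = list(required = "BIR", flags = list()),
    apaf1 = list(required = c("NB-ARC", "WD40"), flags = list()),
    p53 = list(required = "P53", flags = list()),
    cytochrome_c = list(required = "Cytochrom_C", flags = list()),
    calpain = list(required = "Peptidase_C2",
                   flags = list(classical = c("Peptidase_C2", "Calpain_III",
                                              "EF-hand")))
  )
}

#' Build an actor catalogue from domain-scan hits
#'
#' Assigns each scanned protein to actor categories from its domain
#' content: a protein joins a category when every required domain of that
#' category ([default_category_map()]) is hit at `e_value <= evalue_max`.
#'
#' @param domain_hits Data.frame as from [read_domain_table()], plus a
#'   `taxon` column (or supply `taxa`, a named vector protein_id -> taxon).
#' @param category_map Assignment rules; see [default_category_map()].
#' @param evalue_max Maximum full-sequence e-value for a domain to count.
#' @param taxa Optional named character vector mapping protein ids to taxa.
#' @param taxon_order Passed to [catalogue_from_table()].
#' @return An `actor_catalogue` of `intact` entries.
#' @export
catalogue_from_domains <- function(domain_hits,
                                   category_map = default_category_map(),
                                   evalue_max = 1e-5, taxa = NULL,
                                   taxon_order = NULL) {
  if (!length(category_map)) stop("empty category_map", call. = FALSE)
  if (is.null(domain_hits$taxon)) {
    if (is.null(taxa)) {
      stop("domain_hits needs a 'taxon' column or a 'taxa' mapping",
           call. = FALSE)
    }
    domain_hits$taxon <- unname(taxa[domain_hits$protein_id])
  }
  h <- domain_hits[domain_hits$e_value <= evalue_max, , drop = FALSE]
  rows <- list()
  for (pid in unique(h$protein_id)) {
    sub <- h[h$protein_id == pid, , drop = FALSE]
    doms <- unique(sub$domain_name)
    for (cat in names(category_map)) {
      rule <- category_map[[cat]]
      if (!all(rule$required %in% doms)) next
      fl <- names(Filter(function(d) all(d %in% doms), rule$flags))
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = sub$taxon[1L], species = sub$taxon[1L], category = cat,
        protein_id = pid, status = "intact",
        flags = paste(fl, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(), species = character(),
               category = character(), protein_id = character(),
               status = character(), flags = character(),
               stringsAsFactors = FALSE)
  catalogue_from_table(entries, taxon_order = taxon_order)
}

#' Reduce a catalogue to a presence/absence matrix
#'
#' Cells count intact entries per (taxon, category); a cell is "present"
#' when at least one intact entry supports it. Pseudogene entries are
#' tallied in a parallel `pseudo` matrix and, by default, do not make a
#' cell present (`count_pseudogenes = TRUE` flips that, reproducing the
#' reading in which pseudogenic cytochrome C still occupies its cell).
#' Absence markers never count. Per-taxon retention is the number of
#' present categories.
#'
#' @param catalogue An `actor_catalogue`.
#' @param count_pseudogenes Count pseudogene entries as present.
#' @param categories Column order; defaults to [actor_categories()].
#' @return An object of class `presence_matrix`: list with `taxa`,
#'   `categories`, `cells` (logical matrix), `counts`, `pseudo`, and
#'   `retention` (named integer vector).
#' @export
build_matrix <- function(catalogue, count_pseudogenes = FALSE,
                         categories = actor_categories()) {
  stopifnot(inherits(catalogue, "actor_catalogue"))
  e <- catalogue$entries
  if (!nrow(e)) stop("empty catalogue", call. = FALSE)
  taxa <- catalogue$taxon_order
  tab <- function(status) {
    sub <- e[e$status %in% status, , drop = FALSE]
    m <- table(factor(sub$taxon, levels = taxa),
               factor(sub$category, levels = categories))
    matrix(as.integer(m), nrow = length(taxa),
           dimnames = list(taxa, categories))
  }
  counts <- tab("intact")
  pseudo <- tab("pseudogene")
  eff <- if (count_pseudogenes) counts + pseudo else counts
  cells <- eff >= 1L
  structure(list(taxa = taxa, categories = categories, cells = cells,
                 counts = counts, pseudo = pseudo,
                 retention = rowSums(cells)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence matrix (o = present, . = absent, p = pseudogene only):\n")
  sym <- ifelse(x$cells, "o", ifelse(x$pseudo >= 1L, "p", "."))
  w <- max(nchar(x$taxa))
  cat(sprintf("%*s  %s\n", w, "", paste(substr(x$categories, 1, 4),
                                        collapse = " ")))
  for (i in seq_along(x$taxa)) {
    cat(sprintf("%*s  %s   retention=%d\n", w, x$taxa[i],
                paste(format(sym[i, ], width = 4), collapse = " "),
                x$retention[i]))
  }
  invisible(x)
}

#' Loss gradient along an ordered taxon sequence
#'
#' Summarises the presence matrix along a taxon order (default: the
#' matrix's own order, typically the parasitism gradient): per-taxon
#' retention counts, a verdict on whether retention is non-increasing
#' along the order, and the categories newly lost at each step.
#'
#' @param matrix A `presence_matrix`.
#' @param order Optional character vector of taxa (subset allowed, e.g.
#'   [parasitism_gradient()] to drop outgroups).
#' @return Object of class `loss_gradient`: list with `order`, `retention`,
#'   `non_increasing`, and `first_loss` (per step, categories present in
#'   the previous taxon but absent from the current one).
#' @export
loss_gradient <- function(matrix, order = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (is.null(order)) order <- matrix$taxa
  miss <- setdiff(order, matrix$taxa)
  if (length(miss)) {
    stop("taxa not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells <- matrix$cells[order, , drop = FALSE]
  ret <- rowSums(cells)
  first_loss <- list()
  if (length(order) > 1L) {
    for (i in 2:length(order)) {
      lost <- matrix$categories[cells[i - 1L, ] & !cells[i, ]]
      first_loss[[paste(order[i - 1L], "->", order[i])]] <- lost
    }
  }
  structure(list(order = order, retention = ret,
                 non_increasing = all(diff(ret) <= 0),
                 first_loss = first_loss),
            class = "loss_gradient")
}

#' @export
print.loss_gradient <- function(x, ...) {
  cat("Loss gradient:",
      paste(sprintf("%s=%d", x$order, x$retention), collapse = " >= "),
      "\n  non-increasing:", x$non_increasing, "\n")
  for (nm in names(x$first_loss)) {
    if (length(x$first_loss[[nm]])) {
      cat("  lost at", nm, ":", paste(x$first_loss[[nm]], collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}

#' Write a presence matrix as TSV files
#'
#' @param matrix A `presence_matrix`.
#' @param cells_tsv,counts_tsv Optional output paths for the 0/1 matrix and
#'   the parallel intact-entry counts.
#' @return Invisibly, the paths written.
#' @export
write_matrix <- function(matrix, cells_tsv = NULL, counts_tsv = NULL) {
  written <- character()
  dump <- function(m, path) {
    df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  if (!is.null(cells_tsv)) {
    written <- c(written, dump(matrix$cells * 1L, cells_tsv))
  }
  if (!is.null(counts_tsv)) {
    written <- c(written, dump(matrix$counts, counts_tsv))
  }
  invisible(written)
}
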