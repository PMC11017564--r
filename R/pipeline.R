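# Pipeline surface: the package's end-to-end entry points, tying detection,
# genotyping, variation and reporting together over directories of genomes.

#' Scan genomes for gamma-PGA genes and build architectures
#'
#' Reads every GenBank file, detects the panel genes and builds one cluster
#' architecture per genome. Unreadable files are reported and skipped; the
#' call fails only when nothing could be read.
#'
#' @param paths Character vector of GenBank files, or a single directory
#'   (scanned for `.gb`/`.gbk`/`.genbank` files).
#' @param panel Reference panel.
#' @param scheme A [scoring_scheme()].
#' @param min_identity,min_coverage Detection thresholds, see
#'   [find_gene_hits()].
#' @param out_dir Optional output directory: writes `hits.tsv` and one
#'   `<genome>.architecture.json` per genome.
#' @return List with `hits` (tibble over all genomes), `architectures`
#'   (named list), and `errors` (tibble of skipped files).
#' @export
scan_genomes <- function(paths, panel, scheme = scoring_scheme(),
                         min_identity = 0.30, min_coverage = 0.50,
                         out_dir = NULL) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
  }
  if (length(paths) == 0) stop("no inputs: no GenBank files to scan")
  hits <- list(); archs <- list(); errs <- list()
  for (p in sort(paths)) {
    rec <- tryCatch(read_genbank(p), error = function(e) e)
    if (inherits(rec, "error")) {
      errs[[length(errs) + 1]] <- tibble(file = p,
                                         error = conditionMessage(rec))
      next
    }
    h <- find_gene_hits(rec, panel, scheme, min_identity, min_coverage)
    hits[[length(hits) + 1]] <- h
    archs[[rec$id]] <- build_architecture(h, rec)
  }
  if (length(archs) == 0) {
    stop("no inputs could be read; first error: ",
         if (length(errs) > 0) errs[[1]]$error else "none")
  }
  hits <- dplyr::bind_rows(hits)
  errors <- if (length(errs) > 0) dplyr::bind_rows(errs)
            else tibble(file = character(), error = character())
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (gid in names(archs)) {
      architecture_json(archs[[gid]],
                        file.path(out_dir, paste0(gid, ".architecture.json")))
    }
  }
  list(hits = hits, architectures = archs, errors = errors)
}

#' Genotype scanned genomes
#'
#' @param scan A [scan_genomes()] result (or a named list of
#'   architectures).
#' @param rules Rule set or `"default"`.
#' @param out_dir Optional directory for `assignments.tsv` and
#'   `genotype_summary.tsv`.
#' @return List with `assignments` (tibble) and `summary` (tibble).
#' @export
genotype_genomes <- function(scan, rules = "default", out_dir = NULL) {
  if (is.character(rules)) rules <- load_rules(rules)
  archs <- if (!is.null(scan$architectures)) scan$architectures else scan
  assignments <- purrr::map_dfr(archs[sort(names(archs))],
                                assign_genotype, rules = rules)
  summary <- summarize_genotypes(assignments)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    flat <- assignments[, c("genome_id", "genotype", "subtype", "n_genes")]
    utils::write.table(flat, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "genotype_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(assignments = assignments, summary = summary)
}

#' Per-protein variation summary across scanned genomes
#'
#' For one panel protein, collects the matching CDS translation from every
#' genome, calls substitutions against the panel reference, and tabulates
#' panel frequencies and the pairwise identity range. Genomes lacking the
#' protein are excluded from the denominator.
#'
#' @param seqs Named character vector strain -> protein sequence (strains
#'   lacking the protein are simply absent, so the denominator is
#'   per-protein).
#' @param gene Panel gene name.
#' @param panel Reference panel.
#' @param scheme A [scoring_scheme()].
#' @return List with `events` (long tibble), `frequencies`
#'   ([substitution_frequencies()] table), `identity_range` and
#'   `n_strains`.
#' @export
catalog_variation <- function(seqs, gene, panel, scheme = scoring_scheme()) {
  panel <- as_panel(panel)
  seqs <- unlist(seqs)
  if (length(seqs) == 0) stop("no strain sequences supplied for ", gene)
  reference <- panel[[gene]]
  events <- purrr::imap_dfr(seqs, function(s, nm) {
    ev <- call_substitutions(reference, s, scheme)
    if (nrow(ev) == 0) return(tibble())
    ev$strain <- nm
    ev$protein <- gene
    ev
  })
  freq <- substitution_frequencies(
    if (nrow(events) > 0) events else tibble(strain = character(),
                                             notation = character()),
    panel_size = length(seqs), protein = gene
  )
  rng <- if (length(seqs) >= 2) attr(identity_matrix(seqs, scheme), "range")
         else c(min = 1, max = 1)
  list(events = events, frequencies = freq, identity_range = rng,
       n_strains = length(seqs))
}

#' Consolidated analysis report
#'
#' Assembles the stage outputs into one JSON-serializable document with
#' five sections: genotype summary, per-protein mutation tables, identity
#' ranges, trees (Newick) and the assay table. Missing upstream stages are
#' marked `"missing"`; with `strict = TRUE` a missing section is an error.
#'
#' @param genotypes [genotype_genomes()] result, or NULL.
#' @param variation Named list of [catalog_variation()] results, or NULL.
#' @param trees Named list of `phylo` trees, or NULL.
#' @param assay [pga_yield_table()] tibble, or NULL.
#' @param out_file Optional JSON output path.
#' @param strict Error on missing sections.
#' @return The report list, invisibly when written to `out_file`.
#' @export
build_report <- function(genotypes = NULL, variation = NULL, trees = NULL,
                         assay = NULL, out_file = NULL, strict = FALSE) {
  missing_marker <- "missing"
  sections <- list(
    genotype_summary = if (is.null(genotypes)) missing_marker
                       else genotypes$summary,
    mutation_tables = if (is.null(variation)) missing_marker
                      else lapply(variation, function(v) v$frequencies),
    identity_ranges = if (is.null(variation)) missing_marker
                      else lapply(variation, function(v)
                        as.list(v$identity_range)),
    trees = if (is.null(trees)) missing_marker
            else lapply(trees, function(t) ape::write.tree(t)),
    assay = if (is.null(assay)) missing_marker else assay
  )
  if (strict) {
    miss <- names(sections)[vapply(sections, identical, logical(1),
                                   missing_marker)]
    if (length(miss) > 0) {
      stop("missing report sections: ", paste(miss, collapse = ", "))
    }
  }
  if (!is.null(out_file)) {
    writeLines(jsonlite::toJSON(sections, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA, pretty = TRUE),
               out_file)
    return(invisible(sections))
  }
  sections
}
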