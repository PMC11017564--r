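#' Pairwise protein alignment with affine gaps
#'
#' Aligns two amino-acid sequences with the Gotoh three-state recurrence
#' (match, gap-in-b, gap-in-a). Traceback is deterministic with tie-break
#' priority diagonal > up > left, so results are bit-stable across runs.
#'
#' Identity is computed over the aligned region (terminal overhangs excluded
#' in global mode): identical residue columns divided by aligned columns,
#' where internal gap columns count in the denominator but never the
#' numerator. Set `identity_denominator = "ungapped"` to divide by
#' residue-residue columns only.
#'
#' @param a,b Amino-acid strings (20 canonical residues plus X).
#' @param scheme A [scoring_scheme()].
#' @param identity_denominator `"gapped"` (default) or `"ungapped"`.
#' @return A `pga_alignment`: list with `aligned_a`, `aligned_b`, `score`,
#'   `identity`, `coverage_a`, `coverage_b`, `mode`.
#' @examples
#' al <- align_pair("ACDE", "ACDA", scoring_scheme())
#' al$identity  # 0.75
#' @export
align_pair <- function(a, b, scheme = scoring_scheme(),
                       identity_denominator = c("gapped", "ungapped")) {
  identity_denominator <- match.arg(identity_denominator)
  stopifnot(inherits(scheme, "pga_scheme"))
  check_sequence(a, scheme$alphabet, "a")
  check_sequence(b, scheme$alphabet, "b")
  res <- gotoh_align_cpp(a, b, scheme$matrix, scheme$alphabet,
                         scheme$gap_open, scheme$gap_extend,
                         scheme$mode == "local")
  ca <- strsplit(res$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(res$aligned_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) {
    ident <- 0
    region <- logical(length(ca))
  } else {
    lo <- min(which(both)); hi <- max(which(both))
    region <- seq_along(ca) >= lo & seq_along(ca) <= hi
    idn <- sum(ca == cb & both & region)
    den <- if (identity_denominator == "gapped") sum(region) else sum(both & region)
    ident <- idn / den
  }
  structure(
    list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
         score = res$score, identity = ident,
         coverage_a = sum(both) / nchar(a),
         coverage_b = sum(both) / nchar(b),
         mode = scheme$mode),
    class = "pga_alignment"
  )
}

#' @export
print.pga_alignment <- function(x, ...) {
  cat(sprintf("<pga_alignment> score %g, identity %.4f (%s)\n",
              x$score, x$identity, x$mode))
  w <- 60
  n <- nchar(x$aligned_a)
  for (i in seq(1, n, by = w)) {
    cat(substr(x$aligned_a, i, min(i + w - 1, n)), "\n")
    cat(substr(x$aligned_b, i, min(i + w - 1, n)), "\n\n")
  }
  invisible(x)
}

#' Exhaustive alignment score by brute-force enumeration
#'
#' Depth-first enumeration of every gapped alignment of `a` and `b` under the
#' same affine gap model as [align_pair()], without dynamic programming or
#' memoisation. Exponential in sequence length; intended as an independent
#' oracle for short sequences in tests.
#'
#' @inheritParams align_pair
#' @return The optimal alignment score as a number.
#' @export
enumerate_alignment_score <- function(a, b, scheme = scoring_scheme()) {
  check_sequence(a, scheme$alphabet, "a")
  check_sequence(b, scheme$alphabet, "b")
  enumerate_align_score_cpp(a, b, scheme$matrix, scheme$alphabet,
                            scheme$gap_open, scheme$gap_extend)
}

#' Detect gamma-PGA genes in a genome by panel homology
#'
#' Aligns every translated CDS of `record` against each reference-panel
#' protein and reports, per panel gene, the best-scoring CDS passing both the
#' identity and the coverage threshold. Each CDS may serve at most one gene
#' (assignment is greedy by score, ties broken by genome order), mirroring a
#' presence-and-homology gene screen.
#'
#' @param record A [genome_record()].
#' @param panel A reference panel: named character vector of proteins (names
#'   are gene labels; `pgsE` is accepted as an alias of `ywtC`), e.g. from
#'   [generate_reference_panel()] or [read_protein_fasta()].
#' @param scheme A [scoring_scheme()]; global mode recommended for
#'   identity reporting.
#' @param min_identity Presence threshold on alignment identity (default
#'   0.30, low enough to separate the phage-derived hydrolase paralogs from
#'   random matches while tolerating cross-species divergence).
#' @param min_coverage Minimum fraction of the panel protein covered by
#'   residue-residue columns (default 0.50, so truncated or partial CDS do
#'   not count as presence).
#' @return A tibble with one row per detected gene: `genome_id`, `gene`,
#'   `locus_tag`, `start`, `end`, `strand`, `identity`, `coverage`, `score`,
#'   sorted by genome position.
#' @export
find_gene_hits <- function(record, panel, scheme = scoring_scheme(),
                           min_identity = 0.30, min_coverage = 0.50) {
  stopifnot(inherits(record, "pga_genome"))
  panel <- as_panel(panel)
  feats <- record$features
  feats <- feats[!is.na(feats$translation) & nzchar(feats$translation), , drop = FALSE]
  empty <- tibble(genome_id = character(), gene = character(),
                  locus_tag = character(), start = integer(), end = integer(),
                  strand = character(), identity = double(),
                  coverage = double(), score = double())
  if (nrow(feats) == 0 || length(panel) == 0) return(empty)

  cand <- list()
  for (g in names(panel)) {
    ref <- panel[[g]]
    for (k in seq_len(nrow(feats))) {
      al <- align_pair(ref, feats$translation[k], scheme)
      cov <- al$coverage_a  # fraction of the panel reference covered
      if (al$identity >= min_identity && cov >= min_coverage) {
        cand[[length(cand) + 1]] <- tibble(
          gene = g, k = k, identity = al$identity, coverage = cov,
          score = al$score
        )
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- dplyr::bind_rows(cand)
  # greedy: best score first, ties by genome order of the CDS
  cand <- cand[order(-cand$score, feats$start[cand$k]), , drop = FALSE]
  taken_gene <- character(0)
  taken_cds <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gene[i] %in% taken_gene || cand$k[i] %in% taken_cds) next
    keep[i] <- TRUE
    taken_gene <- c(taken_gene, cand$gene[i])
    taken_cds <- c(taken_cds, cand$k[i])
  }
  cand <- cand[keep, , drop = FALSE]
  out <- tibble(
    genome_id = record$id,
    gene = cand$gene,
    locus_tag = feats$locus_tag[cand$k],
    start = feats$start[cand$k],
    end = feats$end[cand$k],
    strand = feats$strand[cand$k],
    identity = cand$identity,
    coverage = cand$coverage,
    score = cand$score
  )
  out[order(out$start), , drop = FALSE]
}

#' Identity range across a set of alignments or identities
#'
#' @param panel_hits A list of `pga_alignment` objects, or a numeric vector
#'   of identities.
#' @return Named numeric vector `c(min = , max = )`.
#' @export
percent_identity_range <- function(panel_hits) {
  if (length(panel_hits) == 0) stop("empty set: no identities to range over")
  ids <- if (is.numeric(panel_hits)) panel_hits
         else vapply(panel_hits, function(x) x$identity, numeric(1))
  c(min = min(ids), max = max(ids))
}

as_panel <- function(panel) {
  if (inherits(panel, "pga_panel")) panel <- unclass(panel)
  if (is.list(panel)) panel <- unlist(panel)
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("panel must be a named character vector of proteins")
  }
  names(panel) <- normalize_gene_name(names(panel))
  if (anyDuplicated(names(panel))) stop("panel gene names must be unique")
  if (any(!nzchar(panel))) stop("panel sequences must be non-empty")
  panel
}
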