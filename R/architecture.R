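#' Build the cluster architecture of a genome's gene hits
#'
#' Orders detected gamma-PGA genes along the genome and records the layout
#' used for genotyping: gene order, strand pattern, lengths, and intergenic
#' spacings for every adjacent pair plus the diagnostic pgdS-ywtC pair.
#' Spacing is the end-to-start gap (negative when genes overlap).
#'
#' @param hits Gene-hit tibble from [find_gene_hits()] (one genome).
#' @param record Optional [genome_record()] the hits refer to; used for the
#'   genome id when `hits` is empty.
#' @return Object of class `pga_architecture`.
#' @export
build_architecture <- function(hits, record = NULL) {
  if (anyDuplicated(hits$gene)) {
    stop("duplicate gene names in hits: ",
         paste(unique(hits$gene[duplicated(hits$gene)]), collapse = ", "))
  }
  genome_id <- if (nrow(hits) > 0) hits$genome_id[1] else record$id %||% NA_character_
  genes <- hits[order(hits$start),
                c("gene", "start", "end", "strand"), drop = FALSE]
  genes$length <- genes$end - genes$start
  spacings <- tibble(gene_a = character(), gene_b = character(),
                     gap = integer(), kind = character())
  if (nrow(genes) >= 2) {
    a <- genes$gene[-nrow(genes)]
    b <- genes$gene[-1]
    gap <- genes$start[-1] - genes$end[-nrow(genes)]
    spacings <- tibble(gene_a = a, gene_b = b, gap = as.integer(gap),
                       kind = "adjacent")
  }
  if (all(c("pgdS", "ywtC") %in% genes$gene)) {
    d <- gap_between(genes, "pgdS", "ywtC")
    spacings <- dplyr::bind_rows(
      spacings,
      tibble(gene_a = "pgdS", gene_b = "ywtC", gap = as.integer(d),
             kind = "diagnostic")
    )
  }
  structure(
    list(genome_id = genome_id, genes = genes,
         present = genes$gene,
         strand_pattern = paste(genes$strand, collapse = ""),
         spacings = spacings),
    class = "pga_architecture"
  )
}

gap_between <- function(genes, a, b) {
  ia <- match(a, genes$gene); ib <- match(b, genes$gene)
  up <- if (genes$start[ia] <= genes$start[ib]) ia else ib
  dn <- if (up == ia) ib else ia
  genes$start[dn] - genes$end[up]
}

#' Signed intergenic distance between two genes of an architecture
#'
#' Distance is `start(downstream) - end(upstream)` with upstream/downstream
#' determined by genome position; overlapping genes give a negative value.
#' Set `convention = "start"` for start-to-start distances instead.
#'
#' @param arch A [build_architecture()] result.
#' @param a,b Gene names.
#' @param convention `"gap"` (end-to-start, default) or `"start"`
#'   (start-to-start).
#' @return Signed distance in bp.
#' @export
intergenic_distance <- function(arch, a, b, convention = c("gap", "start")) {
  convention <- match.arg(convention)
  genes <- arch$genes
  for (g in c(a, b)) {
    if (!g %in% genes$gene) stop("gene not present in architecture: ", g)
  }
  if (convention == "gap") {
    gap_between(genes, a, b)
  } else {
    abs(genes$start[match(b, genes$gene)] - genes$start[match(a, genes$gene)])
  }
}

#' @export
print.pga_architecture <- function(x, ...) {
  cat(sprintf("<pga_architecture> %s: %d genes [%s] strands %s\n",
              x$genome_id, nrow(x$genes),
              paste(x$genes$gene, collapse = " "), x$strand_pattern))
  invisible(x)
}

#' @export
as_tibble.pga_architecture <- function(x, ...) {
  out <- x$genes
  out$genome_id <- x$genome_id
  out[, c("genome_id", "gene", "start", "end", "strand", "length")]
}

#' Serialize an architecture to JSON
#'
#' @param arch A `pga_architecture`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
architecture_json <- function(arch, path = NULL) {
  obj <- list(
    genome_id = arch$genome_id,
    genes = arch$genes,
    strand_pattern = arch$strand_pattern,
    spacings = arch$spacings
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Gene-arrow diagram of a cluster architecture
#'
#' Draws each detected gene as an arrow along a scaled genome axis, one row
#' per genome; the in-package replacement for web-based cluster-illustration
#' tools.
#'
#' @param object A `pga_architecture` or list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pga_architecture <- function(object, ...) {
  archs <- if (inherits(object, "pga_architecture")) list(object) else object
  df <- purrr::map_dfr(archs, as_tibble)
  df$y <- match(df$genome_id, unique(df$genome_id))
  df$xend <- ifelse(df$strand == "+", df$end, df$start)
  df$x <- ifelse(df$strand == "+", df$start, df$end)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y, colour = .data$gene),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm"),
                             type = "closed"),
      linewidth = 2.5
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$y + 0.25,
                   label = .data$gene),
      size = 2.8
    ) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(df$genome_id)),
      labels = unique(df$genome_id)
    ) +
    ggplot2::labs(x = "genome position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
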