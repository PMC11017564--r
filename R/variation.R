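#' Call amino-acid substitutions against a reference protein
#'
#' Globally aligns `query` to `reference` and reports every mismatch column
#' as a reference-anchored substitution in D74N-style notation (reference
#' residue, 1-based reference position, query residue). Insertions and
#' deletions are reported separately in the `indels` attribute, never as
#' substitutions, so notations aggregate cleanly across strains.
#'
#' @param reference Reference protein (no gaps).
#' @param query Query protein.
#' @param scheme A [scoring_scheme()].
#' @return Tibble with columns `position`, `ref`, `alt`, `notation`; the
#'   indel table (`type` = insertion/deletion, `position` = 1-based
#'   reference anchor, `seq`) is attached as attribute `"indels"`.
#' @examples
#' subs <- call_substitutions("MKDLV", "MKNLV")
#' subs$notation  # "D3N"
#' @export
call_substitutions <- function(reference, query, scheme = scoring_scheme()) {
  if (grepl("-", reference, fixed = TRUE)) {
    stop("reference must not contain gap characters")
  }
  al <- align_pair(reference, query, scheme)
  ra <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  qa <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  pos <- cumsum(ra != "-")  # reference coordinate per column
  mism <- ra != "-" & qa != "-" & ra != qa
  subs <- tibble(
    position = as.integer(pos[mism]),
    ref = ra[mism],
    alt = qa[mism],
    notation = paste0(ra[mism], pos[mism], qa[mism])
  )
  # indels: maximal runs of gap columns
  indels <- list()
  r <- rle(ifelse(ra == "-", "ins", ifelse(qa == "-", "del", "m")))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (u in seq_along(r$values)) {
    if (r$values[u] == "m") next
    cols <- idx_start[u]:idx_end[u]
    if (r$values[u] == "ins") {
      indels[[length(indels) + 1]] <- tibble(
        type = "insertion",
        position = as.integer(pos[idx_start[u]]),  # after this ref residue
        seq = paste(qa[cols], collapse = "")
      )
    } else {
      indels[[length(indels) + 1]] <- tibble(
        type = "deletion",
        position = as.integer(pos[idx_start[u]]),  # first deleted ref residue
        seq = paste(ra[cols], collapse = "")
      )
    }
  }
  indel_tbl <- if (length(indels) > 0) dplyr::bind_rows(indels)
               else tibble(type = character(), position = integer(),
                           seq = character())
  attr(subs, "indels") <- indel_tbl
  subs
}

#' Reconstruct a query protein from called events
#'
#' Applies substitutions and indels called by [call_substitutions()] back to
#' the reference; the result equals the original query exactly (event
#' reversibility).
#'
#' @param reference Reference protein.
#' @param events Substitution tibble from [call_substitutions()] (its
#'   `"indels"` attribute is used unless `indels` is given).
#' @param indels Optional indel tibble.
#' @return The reconstructed query string.
#' @export
reconstruct_query <- function(reference, events, indels = NULL) {
  indels <- indels %||% attr(events, "indels") %||%
    tibble(type = character(), position = integer(), seq = character())
  res <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(events))) {
    p <- events$position[k]
    if (res[p] != events$ref[k]) {
      stop(sprintf("event %s does not match the reference at position %d",
                   events$notation[k], p))
    }
    res[p] <- events$alt[k]
  }
  # deletions: blank out reference residues; insertions: append after anchor
  ins <- setNames(rep("", length(res) + 1L), NULL)  # slot i = after residue i-1
  for (k in seq_len(nrow(indels))) {
    if (indels$type[k] == "deletion") {
      cols <- indels$position[k]:(indels$position[k] + nchar(indels$seq[k]) - 1L)
      res[cols] <- ""
    } else {
      slot <- indels$position[k] + 1L
      ins[slot] <- paste0(ins[slot], indels$seq[k])
    }
  }
  paste0(paste0(ins[seq_along(res)], res, collapse = ""),
         ins[length(res) + 1L])
}

#' Tabulate substitution frequencies across a strain panel
#'
#' Counts how many strains carry each identical notation and divides by the
#' panel size. Strains whose protein is missing should already be excluded
#' from `panel_size` (per-protein denominators differ across a genome panel).
#'
#' @param per_strain_events Either a named list of substitution tibbles (one
#'   per strain) or a long tibble with columns `strain` and `notation`
#'   (optionally `protein`).
#' @param panel_size Number of strains in the panel (>= 1).
#' @param protein Optional protein label recorded in the output; when the
#'   input carries a `protein` column it must be single-valued.
#' @return Tibble `notation`, `position`, `count`, `frequency`, `percent`
#'   (formatted to 2 decimals), sorted by descending frequency then
#'   position; attributes `panel_size` and `protein`.
#' @export
substitution_frequencies <- function(per_strain_events, panel_size,
                                     protein = NULL) {
  if (panel_size < 1) stop("panel_size must be >= 1")
  if (is.data.frame(per_strain_events)) {
    long <- per_strain_events
  } else {
    long <- dplyr::bind_rows(per_strain_events, .id = "strain")
  }
  if ("protein" %in% names(long) && nrow(long) > 0) {
    prots <- unique(long$protein)
    if (length(prots) > 1) {
      stop("inconsistent protein labels in events: ",
           paste(prots, collapse = ", "))
    }
    protein <- protein %||% prots
  }
  if (nrow(long) == 0) {
    out <- tibble(notation = character(), position = integer(),
                  count = integer(), frequency = double(),
                  percent = character())
  } else {
    out <- long |>
      dplyr::distinct(.data$strain, .data$notation) |>
      dplyr::count(.data$notation, name = "count") |>
      dplyr::mutate(
        position = as.integer(gsub("[^0-9]", "", .data$notation)),
        frequency = .data$count / panel_size,
        percent = sprintf("%.2f%%", 100 * .data$count / panel_size)
      ) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$position) |>
      dplyr::select("notation", "position", "count", "frequency", "percent")
    if (any(out$count > panel_size)) {
      stop("a notation is carried by more strains than panel_size")
    }
  }
  attr(out, "panel_size") <- panel_size
  attr(out, "protein") <- protein
  out
}

#' Pairwise identity matrix for a strain panel
#'
#' Symmetric strain-by-strain identity table from global pairwise alignment,
#' unit diagonal. The off-diagonal min/max (the published-style "identity
#' range at the amino acid level") is attached as attribute `"range"`.
#'
#' @param panel Named character vector of proteins (>= 2 strains), or a
#'   tibble with columns `strain` and `sequence`.
#' @param scheme A [scoring_scheme()].
#' @return Labeled numeric matrix with attribute `range = c(min, max)`.
#' @export
identity_matrix <- function(panel, scheme = scoring_scheme()) {
  if (is.data.frame(panel)) panel <- setNames(panel$sequence, panel$strain)
  n <- length(panel)
  if (n < 2) stop("identity_matrix needs at least 2 strains")
  labs <- names(panel)
  m <- diag(1, n)
  dimnames(m) <- list(labs, labs)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- align_pair(panel[[i]], panel[[j]], scheme)$identity
      m[i, j] <- id
      m[j, i] <- id
    }
  }
  off <- m[upper.tri(m)]
  attr(m, "range") <- c(min = min(off), max = max(off))
  m
}

#' Plot a mutation-frequency table
#'
#' @param freq_table Output of [substitution_frequencies()].
#' @return A ggplot bar chart of per-notation panel frequencies.
#' @export
plot_mutation_frequencies <- function(freq_table) {
  df <- as_tibble(freq_table)
  df$notation <- factor(df$notation, levels = df$notation)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$notation,
                                   y = 100 * .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "panel frequency (%)",
                  title = attr(freq_table, "protein") %||% NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
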