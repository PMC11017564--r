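#' Construct an annotated genome record
#'
#' The in-memory genome model: 0-based half-open feature coordinates on the
#' forward strand, CDS-only feature table sorted by start. All coordinate
#' conversion happens at the GenBank I/O boundary ([read_genbank()] /
#' [write_genbank()]), never here.
#'
#' @param id Accession or strain label.
#' @param length Genome length in bp (> 0).
#' @param features Tibble with columns `locus_tag`, `gene_name`, `start`,
#'   `end`, `strand`, `translation`, `product`. `start`/`end` are 0-based
#'   half-open; `strand` is `"+"` or `"-"`.
#' @param sequence Optional genome sequence (a/c/g/t string of length
#'   `length`).
#' @param topology `"linear"` or `"circular"`.
#' @param source_taxon Optional organism name.
#' @return Object of class `pga_genome`.
#' @export
genome_record <- function(id, length, features = empty_features(),
                          sequence = NULL, topology = c("linear", "circular"),
                          source_taxon = NULL) {
  topology <- match.arg(topology)
  features <- as_tibble(features)
  need <- c("locus_tag", "gene_name", "start", "end", "strand",
            "translation", "product")
  missing_cols <- setdiff(need, names(features))
  for (cc in missing_cols) features[[cc]] <- NA_character_
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  rec <- structure(
    list(id = as.character(id), length = as.integer(length),
         topology = topology, source_taxon = source_taxon,
         sequence = sequence,
         features = features[order(features$start), , drop = FALSE]),
    class = "pga_genome"
  )
  validate_genome_record(rec)
}

empty_features <- function() {
  tibble(locus_tag = character(), gene_name = character(),
         start = integer(), end = integer(), strand = character(),
         translation = character(), product = character())
}

validate_genome_record <- function(rec) {
  if (rec$length <= 0) stop("genome length must be positive")
  f <- rec$features
  if (nrow(f) > 0) {
    if (any(!(f$start >= 0 & f$start < f$end))) {
      stop("every feature must satisfy 0 <= start < end")
    }
    if (rec$topology == "linear" && any(f$end > rec$length)) {
      stop("feature extends beyond the end of a linear genome")
    }
    has_tr <- !is.na(f$translation) & nzchar(f$translation)
    if (any(has_tr & (f$end - f$start) < 3)) {
      stop("a translated CDS must span at least one codon")
    }
    bad <- has_tr & grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"),
                          f$translation)
    if (any(bad)) stop("translation contains non-canonical residues")
    if (!all(f$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  if (!is.null(rec$sequence) && nchar(rec$sequence) != rec$length) {
    stop("sequence length does not match the declared genome length")
  }
  rec
}

#' @export
print.pga_genome <- function(x, ...) {
  cat(sprintf("<pga_genome> %s: %d bp, %s, %d CDS\n",
              x$id, x$length, x$topology, nrow(x$features)))
  invisible(x)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses LOCUS, FEATURES and ORIGIN sections; only CDS features are
#' retained. GenBank 1-based inclusive coordinates are converted to 0-based
#' half-open, `complement(...)` maps to strand `-`. CDS without a
#' `/translation` qualifier are translated from the nucleotide span with
#' genetic code table 11 (terminal stop stripped). Fuzzy (`<`, `>`) and
#' multi-span/origin-crossing locations are rejected.
#'
#' @param path Path to a GenBank flat file.
#' @return A [genome_record()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) stop("malformed GenBank file (no LOCUS line): ", path)
  m <- regmatches(lines[locus_i[1]],
                  regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", lines[locus_i[1]]))[[1]]
  if (length(m) < 3) {
    stop(sprintf("malformed LOCUS header at line %d: %s", locus_i[1], lines[locus_i[1]]))
  }
  id <- m[2]
  glen <- as.integer(m[3])
  topology <- if (grepl("circular", lines[locus_i[1]])) "circular" else "linear"

  taxon <- NULL
  org_i <- grep("^\\s+/organism=", lines)
  if (length(org_i) > 0) {
    taxon <- sub('^\\s+/organism="(.*)"\\s*$', "\\1", lines[org_i[1]])
  }

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//\\s*$", lines)
  stop_feat <- min(c(origin_i, end_i, length(lines) + 1L))

  sequence <- NULL
  if (length(origin_i) > 0) {
    seq_lines <- lines[(origin_i[1] + 1):(min(c(end_i[end_i > origin_i[1]],
                                                length(lines) + 1L)) - 1L)]
    sequence <- tolower(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) == 0) sequence <- NULL
  }

  feats <- empty_features()
  if (length(feat_i) > 0) {
    block <- lines[(feat_i[1] + 1):(stop_feat - 1L)]
    # a new feature starts with exactly 5 spaces then a key
    starts <- grep("^ {5}\\S", block)
    if (length(starts) > 0) {
      bounds <- c(starts, length(block) + 1L)
      rows <- list()
      for (u in seq_along(starts)) {
        chunk <- block[bounds[u]:(bounds[u + 1] - 1L)]
        key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
        if (key != "CDS") next
        loc <- sub("^ {5}\\S+\\s+", "", chunk[1])
        # location may continue on unqualified lines before the first qualifier
        qual_start <- grep("^\\s+/", chunk)
        loc_end <- if (length(qual_start) > 0) qual_start[1] - 1L else length(chunk)
        if (loc_end > 1) {
          loc <- paste0(loc, paste(trimws(chunk[2:loc_end]), collapse = ""))
        }
        parsed <- parse_location(loc, line = chunk[1])
        quals <- parse_qualifiers(chunk[seq_along(chunk) > loc_end])
        translation <- quals[["translation"]]
        if (is.null(translation) && !is.null(sequence)) {
          translation <- translate_span(sequence, parsed$start, parsed$end,
                                        parsed$strand)
        }
        rows[[length(rows) + 1]] <- tibble(
          locus_tag = quals[["locus_tag"]] %||% sprintf("CDS_%d", u),
          gene_name = quals[["gene"]] %||% NA_character_,
          start = parsed$start, end = parsed$end, strand = parsed$strand,
          translation = translation %||% NA_character_,
          product = quals[["product"]] %||% NA_character_
        )
      }
      if (length(rows) > 0) feats <- dplyr::bind_rows(rows)
    }
  }
  genome_record(id = id, length = glen, features = feats,
                sequence = sequence, topology = topology,
                source_taxon = taxon)
}

parse_location <- function(loc, line) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    if (grepl(",", inner, fixed = TRUE)) {
      stop("multi-span (origin-crossing) CDS locations are not supported: ", line)
    }
    loc <- inner
  }
  if (grepl("[<>]", loc)) stop("fuzzy feature locations are not supported: ", line)
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) < 3) stop("cannot parse CDS location: ", line)
  s <- as.integer(m[2]); e <- as.integer(m[3])
  if (s > e) stop("inverted CDS location: ", line)
  list(start = s - 1L, end = e, strand = strand)
}

parse_qualifiers <- function(chunk) {
  if (length(chunk) == 0) return(list())
  qs <- grep("^\\s+/[A-Za-z_]+", chunk)
  out <- list()
  if (length(qs) == 0) return(out)
  bounds <- c(qs, length(chunk) + 1L)
  for (u in seq_along(qs)) {
    txt <- paste(trimws(chunk[bounds[u]:(bounds[u + 1] - 1L)]), collapse = "")
    name <- sub("^/([A-Za-z_]+)[=]?.*$", "\\1", txt)
    if (grepl("=", txt, fixed = TRUE)) {
      val <- sub("^/[A-Za-z_]+=", "", txt)
      val <- gsub('^"|"$', "", val)
      if (name == "translation") val <- gsub("\\s", "", val)
    } else {
      val <- TRUE
    }
    out[[name]] <- val
  }
  out
}

translate_span <- function(sequence, start, end, strand) {
  nt <- substr(sequence, start + 1L, end)
  dna <- Biostrings::DNAString(toupper(nt))
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"), if.fuzzy.codon = "X"
  ))
  sub("\\*$", "", aa)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN sections that [read_genbank()] parses back to
#' an identical feature table. Output is byte-deterministic (fixed date
#' stamp), so identical records produce identical files.
#'
#' @param record A [genome_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(record, path) {
  validate_genome_record(record)
  con <- file(path, open = "wt")
  on.exit(close(con))
  topo <- format(record$topology, width = 8)
  lines <- c(
    sprintf("LOCUS       %-17s %10d bp    DNA     %s BCT 01-JAN-2024",
            record$id, record$length, topo),
    sprintf("DEFINITION  %s.", record$source_taxon %||% "synthetic Bacillus genome"),
    sprintf("ACCESSION   %s", record$id),
    "FEATURES             Location/Qualifiers"
  )
  lines <- c(lines,
             sprintf("     source          1..%d", record$length),
             wrap_qualifier("organism", record$source_taxon %||% "synthetic construct"))
  f <- record$features
  if (nrow(f) > 0) {
    for (k in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[k] + 1L, f$end[k])
      if (f$strand[k] == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines, sprintf("     CDS             %s", loc))
      if (!is.na(f$locus_tag[k])) {
        lines <- c(lines, wrap_qualifier("locus_tag", f$locus_tag[k]))
      }
      if (!is.na(f$gene_name[k])) {
        lines <- c(lines, wrap_qualifier("gene", f$gene_name[k]))
      }
      if (!is.na(f$product[k])) {
        lines <- c(lines, wrap_qualifier("product", f$product[k]))
      }
      if (!is.na(f$translation[k]) && nzchar(f$translation[k])) {
        lines <- c(lines, wrap_qualifier("translation", f$translation[k]))
      }
    }
  }
  if (!is.null(record$sequence)) {
    lines <- c(lines, "ORIGIN", format_origin(record$sequence))
  }
  lines <- c(lines, "//")
  writeLines(lines, con)
  invisible(path)
}

wrap_qualifier <- function(name, value) {
  txt <- sprintf('/%s="%s"', name, value)
  out <- character(0)
  width <- 58
  while (nchar(txt) > width) {
    out <- c(out, paste0(strrep(" ", 21), substr(txt, 1, width)))
    txt <- substr(txt, width + 1, nchar(txt))
  }
  c(out, paste0(strrep(" ", 21), txt))
}

format_origin <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1, n, by = 60)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}

#' Extract the proteome of a genome record
#'
#' One row per CDS carrying a translation, in genome order. Features without
#' a translation are skipped with a message.
#'
#' @param record A [genome_record()].
#' @return Tibble with columns `locus_tag`, `gene_name`, `translation`.
#' @export
extract_proteins <- function(record) {
  stopifnot(inherits(record, "pga_genome"))
  f <- record$features
  has <- !is.na(f$translation) & nzchar(f$translation)
  if (any(!has)) {
    message(sum(!has), " CDS without translation skipped in ", record$id)
  }
  tibble(locus_tag = f$locus_tag[has], gene_name = f$gene_name[has],
         translation = f$translation[has])
}

#' Write genome proteins as multi-FASTA
#'
#' Headers follow `<record_id>|<locus_tag>|<gene_name>`.
#'
#' @param record A [genome_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_protein_fasta <- function(record, path) {
  prot <- extract_proteins(record)
  lines <- character(0)
  for (k in seq_len(nrow(prot))) {
    hdr <- sprintf(">%s|%s|%s", record$id, prot$locus_tag[k],
                   prot$gene_name[k] %||% "")
    lines <- c(lines, hdr, prot$translation[k])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein panel from multi-FASTA
#'
#' Headers are `gene_name|source_strain`; only the first `|`-separated field
#' is used as the gene label.
#'
#' @param path FASTA file path.
#' @return Named character vector of proteins (class `pga_panel`).
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- character(length(hdr))
  labels <- character(length(hdr))
  for (u in seq_along(hdr)) {
    labels[u] <- strsplit(sub("^>", "", lines[hdr[u]]), "|", fixed = TRUE)[[1]][1]
    seqs[u] <- paste(lines[(hdr[u] + 1):(bounds[u + 1] - 1L)], collapse = "")
  }
  structure(setNames(gsub("\\s", "", seqs), labels), class = "pga_panel")
}
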