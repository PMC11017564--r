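# Synthetic-data generators: annotated genomes with planted cluster
# architectures and protein panels with planted substitutions. Everything is
# a pure function of (spec, seed), so fixtures are reproducible ground truth
# rather than stored files.

# Approximate B. subtilis proteome residue composition (cosmetic realism).
BACILLUS_AA_FREQ <- c(
  A = 0.077, C = 0.008, D = 0.052, E = 0.073, F = 0.045, G = 0.069,
  H = 0.023, I = 0.074, K = 0.071, L = 0.097, M = 0.028, N = 0.040,
  P = 0.037, Q = 0.039, R = 0.041, S = 0.063, T = 0.054, V = 0.067,
  W = 0.010, Y = 0.035
)

# One deterministic codon per residue (frequent B. subtilis codons); codon
# usage is cosmetic here, determinism is what matters. All decode to the
# intended residue under translation table 11.
BACK_CODON <- c(
  A = "gca", C = "tgc", D = "gat", E = "gaa", F = "ttt", G = "ggc",
  H = "cat", I = "att", K = "aaa", L = "ctg", M = "atg", N = "aat",
  P = "ccg", Q = "cag", R = "cgc", S = "tca", T = "aca", V = "gtt",
  W = "tgg", Y = "tat"
)

# Default reference lengths (residues), sized like the real enzymes: the
# cluster membrane subunit pgsC smallest, the transpeptidase ggt largest.
default_gene_lengths <- function() {
  c(pgsB = 393, pgsC = 149, pgsA = 380, ywtC = 129, pgdS = 413,
    racE = 272, ggt = 587, pghB = 213, pghC = 229, pghL = 222, pghZ = 235)
}

#' Generate a synthetic reference protein panel
#'
#' Random proteins with Bacillus-like residue composition, one per
#' gamma-PGA gene slot; deterministic per seed. Lengths default to values
#' approximating the real enzymes but are configuration, not biology claims.
#'
#' @param seed Integer seed.
#' @param lengths Named integer vector gene -> residues.
#' @return Named character vector of proteins, class `pga_panel`, with
#'   attribute `source_strain = "synthetic-reference"`.
#' @export
generate_reference_panel <- function(seed = 1, lengths = default_gene_lengths()) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  panel <- withr::with_seed(seed, {
    vapply(names(lengths), function(g) {
      n <- lengths[[g]]
      body <- sample(names(BACILLUS_AA_FREQ), n - 1, replace = TRUE,
                     prob = BACILLUS_AA_FREQ)
      paste0("M", paste(body, collapse = ""))
    }, character(1))
  })
  structure(panel, class = "pga_panel", source_strain = "synthetic-reference")
}

#' Define a planted cluster architecture
#'
#' @param genotype_label Target genotype/subtype label (bookkeeping).
#' @param order Gene names in genome order.
#' @param strands Strand pattern string over `+`/`-`, one char per gene.
#' @param spacings Intergenic gaps in bp between consecutive genes
#'   (length(order) - 1; negative values overlap the downstream gene into
#'   the upstream one, bounded by half the shortest gene).
#' @param lengths Gene lengths in bp including the stop codon (multiples
#'   of 3).
#' @param flank Flanking sequence length in bp on both sides.
#' @param seed Seed for filler sequence and locus naming.
#' @return Object of class `pga_arch_spec`.
#' @export
architecture_spec <- function(genotype_label, order, strands, spacings,
                              lengths, flank = 500, seed = 1) {
  strands_v <- strsplit(strands, "", fixed = TRUE)[[1]]
  n <- length(order)
  if (length(strands_v) != n || length(lengths) != n ||
      length(spacings) != n - 1) {
    stop("order, strands, lengths and spacings must be congruent in length")
  }
  if (any(lengths %% 3 != 0)) stop("gene lengths must be multiples of 3")
  if (any(spacings < -min(lengths) / 2)) {
    stop("spacings must be >= -min(gene length)/2")
  }
  structure(
    list(genotype_label = genotype_label, order = order, strands = strands_v,
         spacings = as.integer(spacings), lengths = as.integer(lengths),
         flank = as.integer(flank), seed = as.integer(seed)),
    class = "pga_arch_spec"
  )
}

#' Architecture template for a packaged genotype or subtype label
#'
#' Derives a generator spec straight from the rule table so rule set and
#' generator are consistent by construction: gene order and strands come
#' from the rule (wildcards resolved to `+`), adjacent spacings default to
#' 150 bp, and any spacing constraint on an adjacent pair is set to the
#' window midpoint (or 110% of its minimum when the window is unbounded).
#'
#' @param label A genotype or subtype label from `rules`.
#' @param panel Reference panel (gene lengths derive from its proteins).
#' @param rules A [load_rules()] rule set.
#' @param seed Seed stored in the spec.
#' @param default_gap Default adjacent intergenic gap (bp).
#' @return A [architecture_spec()].
#' @export
template_for_label <- function(label, panel = generate_reference_panel(),
                               rules = load_rules(), seed = 1,
                               default_gap = 150) {
  panel <- as_panel(panel)
  idx <- match(label, rule_labels(rules))
  if (is.na(idx)) stop("unknown rule label: ", label)
  rule <- rules$rules[[idx]]
  parent <- NULL
  if (rule$kind == "subtype") {
    parent <- rules$rules[[match(rule$parent, rule_labels(rules))]]
  }
  content <- if (!is.null(parent)) parent$required else rule$required
  order <- rule$order %||% parent$order %||% PGA_GENES[PGA_GENES %in% content]
  strands <- rule$strands %||% parent$strands %||%
    paste(rep("+", length(order)), collapse = "")
  strands <- gsub("*", "+", strands, fixed = TRUE)
  missing_genes <- setdiff(order, names(panel))
  if (length(missing_genes) > 0) {
    stop("panel lacks proteins for: ", paste(missing_genes, collapse = ", "))
  }
  lengths <- 3L * (nchar(panel[order]) + 1L)  # + stop codon
  spacings <- rep(as.integer(default_gap), length(order) - 1L)
  # parent constraints first so a subtype's narrower window takes precedence
  constraints <- c(if (!is.null(parent)) parent$spacing, rule$spacing)
  for (sc in constraints) {
    ia <- match(sc$a, order); ib <- match(sc$b, order)
    if (is.na(ia) || is.na(ib) || abs(ia - ib) != 1) next
    target <- if (sc$max < 1e6) round((sc$min + sc$max) / 2)
              else round(sc$min * 1.1)
    spacings[min(ia, ib)] <- as.integer(target)
  }
  architecture_spec(label, order, strands, spacings, lengths,
                    flank = 500, seed = seed)
}

#' Remove a gene from an architecture spec
#'
#' Used for perturbation tests: the downstream spacing of the removed gene
#' is absorbed into the preceding gap.
#'
#' @param spec A [architecture_spec()].
#' @param gene Gene to remove.
#' @return A new `pga_arch_spec`.
#' @export
drop_gene <- function(spec, gene) {
  i <- match(gene, spec$order)
  if (is.na(i)) stop("gene not in spec: ", gene)
  n <- length(spec$order)
  sp <- spec$spacings
  if (n >= 2) {
    if (i == 1) sp <- sp[-1]
    else if (i == n) sp <- sp[-(n - 1)]
    else { sp[i - 1] <- sp[i - 1] + spec$lengths[i] + sp[i]; sp <- sp[-i] }
  }
  architecture_spec(spec$genotype_label, spec$order[-i],
                    paste(spec$strands[-i], collapse = ""), sp,
                    spec$lengths[-i], flank = spec$flank, seed = spec$seed)
}

back_translate <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(BACK_CODON))) {
    stop("cannot back-translate residue outside the 20 canonical amino acids")
  }
  paste0(paste(BACK_CODON[chars], collapse = ""), "taa")
}

revcomp <- function(nt) {
  tolower(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(nt)))
  ))
}

random_filler <- function(n, gc = 0.43) {
  if (n <= 0) return("")
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate an annotated genome with a planted architecture
#'
#' Back-translates each panel protein (deterministic codon choice, table
#' 11), places the CDS at the planted coordinates and strands with
#' seeded-random Bacillus-like (43% GC) filler between and around them.
#' Reading the genome back and rebuilding its architecture recovers the
#' spec exactly.
#'
#' @param spec A [architecture_spec()].
#' @param panel Reference panel covering the spec's genes.
#' @param id Genome id (defaults to a label-derived name).
#' @param mutated_proteins Optional named character vector overriding panel
#'   proteins (e.g. divergent copies with planted substitutions).
#' @return A [genome_record()] with sequence.
#' @export
generate_genome <- function(spec, panel, id = NULL, mutated_proteins = NULL) {
  stopifnot(inherits(spec, "pga_arch_spec"))
  panel <- as_panel(panel)
  if (!all(spec$order %in% names(panel))) {
    stop("panel does not cover the spec's genes: ",
         paste(setdiff(spec$order, names(panel)), collapse = ", "))
  }
  proteins <- panel[spec$order]
  if (!is.null(mutated_proteins)) {
    ov <- intersect(names(mutated_proteins), names(proteins))
    proteins[ov] <- mutated_proteins[ov]
  }
  id <- id %||% paste0("SYN-", gsub("[^A-Za-z0-9.]", "", spec$genotype_label))

  n <- length(spec$order)
  starts <- integer(n); ends <- integer(n)
  pos <- spec$flank
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + spec$lengths[i]
    pos <- ends[i] + (if (i < n) spec$spacings[i] else 0L)
  }
  total <- ends[n] + spec$flank

  withr::with_seed(spec$seed, {
    seq_chars <- strsplit(random_filler(total), "", fixed = TRUE)[[1]]
    for (i in seq_len(n)) {
      cds <- back_translate(proteins[[i]])
      if (nchar(cds) != spec$lengths[i]) {
        stop(sprintf("gene %s: spec length %d bp does not match protein (%d bp)",
                     spec$order[i], spec$lengths[i], nchar(cds)))
      }
      if (spec$strands[i] == "-") cds <- revcomp(cds)
      seq_chars[(starts[i] + 1):ends[i]] <- strsplit(cds, "", fixed = TRUE)[[1]]
    }
    sequence <- paste(seq_chars, collapse = "")
    features <- tibble(
      locus_tag = sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", id),
                          seq_len(n) * 5L),
      gene_name = spec$order,
      start = starts, end = ends, strand = spec$strands,
      translation = unname(proteins),
      product = paste0(spec$order, " gene product")
    )
    genome_record(id = id, length = total, features = features,
                  sequence = sequence, topology = "linear",
                  source_taxon = "Bacillus sp. (synthetic)")
  })
}

#' Define a planted-mutation plan
#'
#' @param protein Gene name the plan applies to.
#' @param events Character vector of D74N-style notations; positions must be
#'   unique and lie within the reference, and each reference residue must
#'   match.
#' @param carrier_fraction Fraction of strains carrying all events, in
#'   `[0, 1]`; carrier counts round up so small panels have deterministic
#'   frequencies.
#' @param n_strains Panel size.
#' @param seed Seed (reserved for future stochastic plans; carrier choice is
#'   deterministic).
#' @return Object of class `pga_mutation_plan`.
#' @export
mutation_plan <- function(protein, events, carrier_fraction, n_strains,
                          seed = 1) {
  m <- regmatches(events, regexec("^([A-Z])(\\d+)([A-Z])$", events))
  if (any(vapply(m, length, integer(1)) != 4)) {
    stop("events must be notations like D74N")
  }
  pos <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (anyDuplicated(pos)) stop("no two events may share a position")
  structure(
    list(protein = protein, events = events,
         ref = vapply(m, `[`, character(1), 2),
         position = pos,
         alt = vapply(m, `[`, character(1), 4),
         carrier_fraction = carrier_fraction,
         n_strains = as.integer(n_strains), seed = as.integer(seed)),
    class = "pga_mutation_plan"
  )
}

#' Draw random substitution notations valid for a reference
#'
#' @param reference Reference protein.
#' @param k Number of events.
#' @param seed Seed.
#' @return Character vector of notations consistent with `reference`.
#' @export
random_substitutions <- function(reference, k, seed = 1) {
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  withr::with_seed(seed, {
    pos <- sort(sample(seq_along(chars), k))
    vapply(pos, function(p) {
      alt <- sample(setdiff(AA20, chars[p]), 1)
      paste0(chars[p], p, alt)
    }, character(1))
  })
}

#' Generate a strain panel with planted substitutions
#'
#' `ceiling(carrier_fraction * n_strains)` strains carry every planned
#' event; the rest are exact reference copies. Carrier status per strain is
#' recorded in the `"truth"` attribute as hidden ground truth for tests.
#'
#' @param plan A [mutation_plan()].
#' @param panel Reference panel containing the plan's protein.
#' @return Named character vector strain -> protein, attribute `truth`
#'   (tibble `strain`, `carrier`).
#' @export
generate_strain_panel <- function(plan, panel) {
  stopifnot(inherits(plan, "pga_mutation_plan"))
  panel <- as_panel(panel)
  reference <- panel[[plan$protein]]
  if (is.null(reference)) stop("panel lacks protein ", plan$protein)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (any(plan$position > length(chars))) {
    stop("event position beyond the reference length")
  }
  bad <- chars[plan$position] != plan$ref
  if (any(bad)) {
    stop("event ", plan$events[which(bad)[1]],
         " does not match the reference residue")
  }
  mutated <- chars
  mutated[plan$position] <- plan$alt
  mutated <- paste(mutated, collapse = "")
  k <- ceiling(plan$carrier_fraction * plan$n_strains)
  strains <- sprintf("strain_%03d", seq_len(plan$n_strains))
  out <- setNames(c(rep(mutated, k), rep(reference, plan$n_strains - k)),
                  strains)
  attr(out, "truth") <- tibble(strain = strains,
                               carrier = seq_len(plan$n_strains) <= k)
  out
}

#' Generate a set of genomes from genotype labels, with a manifest
#'
#' One genome per label (labels may repeat); each genome gets its own seed
#' derived from `seed`. Optionally writes GenBank files plus a ground-truth
#' JSON manifest.
#'
#' @param labels Character vector of genotype/subtype labels.
#' @param panel Reference panel.
#' @param rules Rule set the labels come from.
#' @param seed Base seed.
#' @param dir Optional output directory for `.gbk` files and
#'   `manifest.json`.
#' @return List with `genomes` (list of records) and `manifest` (tibble
#'   `genome_id`, `label`, `file`).
#' @export
generate_genome_set <- function(labels, panel = generate_reference_panel(),
                                rules = load_rules(), seed = 1, dir = NULL) {
  genomes <- vector("list", length(labels))
  files <- rep(NA_character_, length(labels))
  ids <- sprintf("SYN%03d", seq_along(labels))
  for (i in seq_along(labels)) {
    spec <- template_for_label(labels[i], panel = panel, rules = rules,
                               seed = seed + i)
    genomes[[i]] <- generate_genome(spec, panel, id = ids[i])
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files[i] <- file.path(dir, paste0(ids[i], ".gbk"))
      write_genbank(genomes[[i]], files[i])
    }
  }
  manifest <- tibble(genome_id = ids, label = labels, file = files)
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(genomes = genomes, manifest = manifest)
}
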