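#' Load a genotype rule set
#'
#' Reads a declarative rule table (YAML or JSON) defining genotypes and
#' subtypes of gamma-PGA cluster architectures. A rule has a `label`, a
#' `kind` (`"genotype"` or `"subtype"`), `required`/`forbidden` gene sets,
#' and optional `order` (gene list in genome order), `strands` (pattern over
#' `+`, `-`, `*` aligned to `order` or to the genome order of present
#' genes), `spacing` (list of `a`/`b`/`min`/`max` bp windows on the
#' intergenic gap) and, for subtypes, a `parent` genotype.
#'
#' Rules are evaluated in file order with first-match-wins; genotype rules
#' evaluate all their clauses (including spacing, which is how the
#' far-separated-pgdS genotype is told apart from its same-content sibling).
#'
#' @param config Path to a YAML/JSON rule file, or `"default"` for the
#'   packaged `bacillus-pga-v1` table.
#' @return Object of class `pga_ruleset`.
#' @export
load_rules <- function(config = "default") {
  if (identical(config, "default")) {
    config <- system.file("extdata", "rules", "bacillus_pga_v1.yaml",
                          package = "pgatyper", mustWork = TRUE)
  }
  doc <- yaml::read_yaml(config)
  validate_ruleset(doc, source = config)
}

validate_ruleset <- function(doc, source = "<ruleset>") {
  if (is.null(doc$rules) || length(doc$rules) == 0) {
    stop("rule config error at /rules: no rules defined in ", source)
  }
  labels <- vapply(doc$rules, function(r) r$label %||% NA_character_, character(1))
  if (anyNA(labels)) stop("rule config error: every rule needs a label")
  if (anyDuplicated(labels)) {
    stop("rule config error: duplicate label ",
         labels[duplicated(labels)][1])
  }
  geno_labels <- labels[vapply(doc$rules, function(r) identical(r$kind, "genotype"),
                               logical(1))]
  rules <- lapply(seq_along(doc$rules), function(i) {
    r <- doc$rules[[i]]
    ptr <- sprintf("/rules/%d", i - 1)
    r$kind <- r$kind %||% "genotype"
    if (!r$kind %in% c("genotype", "subtype")) {
      stop("rule config error at ", ptr, "/kind: must be genotype or subtype")
    }
    r$required <- normalize_gene_name(as.character(r$required %||% character(0)))
    r$forbidden <- normalize_gene_name(as.character(r$forbidden %||% character(0)))
    if (length(intersect(r$required, r$forbidden)) > 0) {
      stop("rule config error at ", ptr,
           ": required and forbidden sets overlap (",
           paste(intersect(r$required, r$forbidden), collapse = ", "), ")")
    }
    if (!is.null(r$order)) r$order <- normalize_gene_name(as.character(r$order))
    if (!is.null(r$strands)) {
      if (grepl("[^+*-]", r$strands)) {
        stop("rule config error at ", ptr, "/strands: pattern must be over +,-,*")
      }
    }
    if (r$kind == "subtype") {
      if (is.null(r$parent) || !r$parent %in% geno_labels) {
        stop("rule config error at ", ptr,
             "/parent: subtype must name an existing genotype")
      }
    }
    if (!is.null(r$spacing)) {
      r$spacing <- lapply(r$spacing, function(sc) {
        if (is.null(sc$a) || is.null(sc$b) || is.null(sc$min) || is.null(sc$max)) {
          stop("rule config error at ", ptr, "/spacing: need a, b, min, max")
        }
        list(a = normalize_gene_name(sc$a), b = normalize_gene_name(sc$b),
             min = as.numeric(sc$min), max = as.numeric(sc$max))
      })
    }
    r
  })
  structure(list(version = doc$version %||% "unversioned", rules = rules),
            class = "pga_ruleset")
}

#' Serialize a rule set back to YAML
#'
#' `load_rules(write_rules(rs, f))` reproduces `rs` exactly.
#'
#' @param ruleset A `pga_ruleset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rules <- function(ruleset, path) {
  doc <- list(version = ruleset$version, rules = ruleset$rules)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.pga_ruleset <- function(x, ...) {
  kinds <- vapply(x$rules, function(r) r$kind, character(1))
  cat(sprintf("<pga_ruleset> %s: %d genotypes, %d subtypes\n",
              x$version, sum(kinds == "genotype"), sum(kinds == "subtype")))
  invisible(x)
}

rule_labels <- function(ruleset, kind = NULL) {
  keep <- if (is.null(kind)) rep(TRUE, length(ruleset$rules))
          else vapply(ruleset$rules, function(r) r$kind == kind, logical(1))
  vapply(ruleset$rules[keep], function(r) r$label, character(1))
}

check_rule <- function(rule, arch) {
  present <- arch$present
  ev <- list()
  note <- function(clause, ok) {
    ev[[length(ev) + 1]] <<- tibble(rule = rule$label, clause = clause, ok = ok)
  }
  ok <- TRUE
  for (g in rule$required) {
    hit <- g %in% present
    note(paste0("required ", g), hit)
    ok <- ok && hit
  }
  for (g in rule$forbidden) {
    hit <- !(g %in% present)
    note(paste0("forbidden ", g), hit)
    ok <- ok && hit
  }
  if (ok && !is.null(rule$order)) {
    same <- identical(arch$genes$gene, rule$order)
    note("order template", same)
    ok <- ok && same
  }
  if (ok && !is.null(rule$strands)) {
    pat <- strsplit(rule$strands, "", fixed = TRUE)[[1]]
    obs <- strsplit(arch$strand_pattern, "", fixed = TRUE)[[1]]
    same <- length(pat) == length(obs) && all(pat == "*" | pat == obs)
    if (any(pat == "*")) note("strand template (contains wildcards)", same)
    else note("strand template", same)
    ok <- ok && same
  }
  if (ok && !is.null(rule$spacing)) {
    for (sc in rule$spacing) {
      inside <- FALSE
      if (all(c(sc$a, sc$b) %in% present)) {
        d <- intergenic_distance(arch, sc$a, sc$b)
        inside <- d >= sc$min && d <= sc$max
      }
      note(sprintf("spacing %s-%s in [%g, %g]", sc$a, sc$b, sc$min, sc$max),
           inside)
      ok <- ok && inside
    }
  }
  list(ok = ok, evidence = if (length(ev) > 0) dplyr::bind_rows(ev)
                           else tibble(rule = character(), clause = character(),
                                       ok = logical()))
}

#' Assign a genotype and subtype to a cluster architecture
#'
#' First genotype rule (in rule-table order) whose clauses all hold wins;
#' among its subtypes, the first whose order/strand/spacing clauses hold
#' wins. No genotype match yields `"untyped"`; a genotype without a matching
#' subtype yields subtype `"unassigned"`.
#'
#' @param arch A [build_architecture()] result.
#' @param rules A [load_rules()] rule set.
#' @return One-row tibble: `genome_id`, `genotype`, `subtype`, `n_genes`,
#'   plus an `evidence` list-column of evaluated clauses.
#' @export
assign_genotype <- function(arch, rules = load_rules()) {
  stopifnot(inherits(arch, "pga_architecture"), inherits(rules, "pga_ruleset"))
  evidence <- list()
  genotype <- "untyped"
  subtype <- "unassigned"
  for (r in rules$rules) {
    if (r$kind != "genotype") next
    res <- check_rule(r, arch)
    evidence[[length(evidence) + 1]] <- res$evidence
    if (res$ok) { genotype <- r$label; break }
  }
  if (genotype != "untyped") {
    for (r in rules$rules) {
      if (r$kind != "subtype" || !identical(r$parent, genotype)) next
      res <- check_rule(r, arch)
      evidence[[length(evidence) + 1]] <- res$evidence
      if (res$ok) { subtype <- r$label; break }
    }
  }
  tibble(
    genome_id = arch$genome_id,
    genotype = genotype,
    subtype = subtype,
    n_genes = nrow(arch$genes),
    evidence = list(dplyr::bind_rows(evidence))
  )
}

#' Count genotype and subtype assignments
#'
#' @param assignments Tibble of [assign_genotype()] rows.
#' @return Tibble `label`, `level` (genotype/subtype/untyped), `n`, sorted by
#'   descending count then label.
#' @export
summarize_genotypes <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(label = character(), level = character(), n = integer()))
  }
  geno <- assignments |>
    dplyr::count(.data$genotype, name = "n") |>
    dplyr::transmute(label = .data$genotype,
                     level = ifelse(.data$label == "untyped", "untyped",
                                    "genotype"),
                     n = .data$n)
  sub <- assignments |>
    dplyr::filter(.data$genotype != "untyped",
                  .data$subtype != "unassigned") |>
    dplyr::count(.data$subtype, name = "n") |>
    dplyr::transmute(label = .data$subtype, level = "subtype", n = .data$n)
  dplyr::bind_rows(geno, sub) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label)
}
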