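test_that("the packaged rule table has 7 genotypes and >= 21 subtypes", {
  rules <- load_rules()
  kinds <- vapply(rules$rules, function(r) r$kind, "")
  expect_equal(sum(kinds == "genotype"), 7)
  expect_gte(sum(kinds == "subtype"), 21)
  labels <- vapply(rules$rules, function(r) r$label, "")
  expect_setequal(labels[kinds == "genotype"], paste0("G", 1:7))
})

test_that("invalid rule configs fail with pointed errors", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("version: t", "rules:",
               "- label: G1", "  kind: genotype",
               "  required: [pgsB]", "  forbidden: [pgsB]"), f)
  expect_error(load_rules(f), "required and forbidden")

  writeLines(c("version: t", "rules:",
               "- label: G1", "  kind: genotype", "  required: [pgsB]",
               "- label: G1", "  kind: genotype", "  required: [pgsC]"), f)
  expect_error(load_rules(f), "duplicate label")

  writeLines(c("version: t", "rules:",
               "- label: SG1.1", "  kind: subtype", "  parent: G9"), f)
  expect_error(load_rules(f), "parent")
})

test_that("rule sets round-trip through serialization", {
  rules <- load_rules()
  f <- tempfile(fileext = ".yaml")
  write_rules(rules, f)
  back <- load_rules(f)
  expect_equal(back$version, rules$version)
  expect_equal(back$rules, rules$rules)
})

test_that("pgsE is accepted as an alias of ywtC in rules and panels", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("version: t", "rules:",
               "- label: GX", "  kind: genotype", "  required: [pgsE, pgsB]"),
             f)
  rules <- load_rules(f)
  expect_setequal(rules$rules[[1]]$required, c("ywtC", "pgsB"))
})

test_that("generate -> detect -> classify returns the generating label", {
  panel <- tiny_panel()
  rules <- load_rules()
  for (lb in c("SG1.1", "SG1.9", "SG2.1", "SG2.8", "SG3.2", "SG6.9", "SG6.10")) {
    spec <- template_for_label(lb, panel = panel, rules = rules, seed = 31)
    g <- generate_genome(spec, panel)
    asg <- assign_genotype(build_architecture(find_gene_hits(g, panel), g),
                           rules)
    expect_equal(asg$subtype, lb)
    expect_equal(asg$genotype, sub("^SG(\\d+).*$", "G\\1", lb))
  }
  for (lb in c("G4", "G5", "G7")) {
    spec <- template_for_label(lb, panel = panel, rules = rules, seed = 32)
    g <- generate_genome(spec, panel)
    asg <- assign_genotype(build_architecture(find_gene_hits(g, panel), g),
                           rules)
    expect_equal(asg$genotype, lb)
    expect_equal(asg$subtype, "unassigned")
  }
})

test_that("a G6-content genome lacking ywtC is called G7", {
  panel <- tiny_panel()
  rules <- load_rules()
  spec <- drop_gene(template_for_label("SG6.6", panel = panel, seed = 41),
                    "ywtC")
  g <- generate_genome(spec, panel)
  asg <- assign_genotype(build_architecture(find_gene_hits(g, panel), g), rules)
  expect_equal(asg$genotype, "G7")
})

test_that("deleting a required gene moves the call away from the genotype", {
  panel <- tiny_panel()
  rules <- load_rules()
  for (case in list(c("SG1.1", "racE", "G1"), c("SG2.1", "pghL", "G2"),
                    c("SG6.1", "pghC", "G6"))) {
    spec <- drop_gene(template_for_label(case[1], panel = panel, seed = 43),
                      case[2])
    g <- generate_genome(spec, panel)
    asg <- assign_genotype(build_architecture(find_gene_hits(g, panel), g),
                           rules)
    expect_false(identical(asg$genotype, case[3]))
  }
})

test_that("empty architectures are untyped, and assignment is deterministic", {
  rules <- load_rules()
  empty <- build_architecture(
    tibble::tibble(genome_id = character(), gene = character(),
                   locus_tag = character(), start = integer(),
                   end = integer(), strand = character(), identity = double(),
                   coverage = double(), score = double()),
    genome_record("NOHITS", 5000)
  )
  a1 <- assign_genotype(empty, rules)
  expect_equal(a1$genotype, "untyped")
  expect_equal(a1$subtype, "unassigned")
  a2 <- assign_genotype(empty, rules)
  expect_equal(a1[, c("genome_id", "genotype", "subtype", "n_genes")],
               a2[, c("genome_id", "genotype", "subtype", "n_genes")])
  expect_gt(nrow(a1$evidence[[1]]), 0)
})

test_that("genotype summaries count planted mixtures exactly", {
  panel <- tiny_panel()
  rules <- load_rules()
  withr::with_seed(11, {
    labels <- sample(c(rep("SG1.1", 7), rep("SG2.1", 5)))
  })
  set <- generate_genome_set(labels, panel = panel, rules = rules, seed = 50)
  assignments <- purrr::map_dfr(set$genomes, function(g) {
    assign_genotype(build_architecture(find_gene_hits(g, panel), g), rules)
  })
  got <- summarize_genotypes(assignments)
  expect_equal(got$n[got$label == "SG1.1"], 7L)
  expect_equal(got$n[got$label == "SG2.1"], 5L)
  expect_equal(got$n[got$label == "G1"], 7L)
  expect_equal(got$n[got$label == "G2"], 5L)

  simple <- tibble::tibble(genome_id = c("a", "b", "c"),
                           genotype = c("G1", "G1", "G7"),
                           subtype = "unassigned", n_genes = 1)
  s <- summarize_genotypes(simple)
  expect_equal(s$n[s$label == "G1"], 2L)
  expect_equal(s$n[s$label == "G7"], 1L)
  expect_equal(nrow(summarize_genotypes(simple[0, ])), 0)
})
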