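test_that("identical sequences align with identity 1 and diagonal score", {
  sc <- default_scheme
  al <- align_pair("ACDE", "ACDE", sc)
  expected <- sum(diag(sc$matrix[c("A", "C", "D", "E"), c("A", "C", "D", "E")]))
  expect_equal(al$score, expected)
  expect_equal(al$identity, 1.0)
  expect_equal(al$coverage_a, 1.0)

  # self-alignment holds for realistic generated proteins too
  panel <- tiny_panel()
  for (g in c("pgsB", "pgsC", "ggt")) {
    al <- align_pair(panel[[g]], panel[[g]], sc)
    chars <- strsplit(panel[[g]], "", fixed = TRUE)[[1]]
    expect_equal(al$identity, 1.0)
    expect_equal(al$score, sum(sc$matrix[cbind(chars, chars)]))
  }
})

test_that("a single mismatch gives identity 3/4 with no gaps", {
  al <- align_pair("ACDE", "ACDA", default_scheme)
  expect_equal(al$identity, 0.75)
  expect_false(grepl("-", al$aligned_a, fixed = TRUE))
})

test_that("X is neutral: scores zero against any residue", {
  sc <- default_scheme
  al <- align_pair("AXA", "AAA", sc)
  expect_equal(al$score, 2 * sc$matrix["A", "A"])
})

test_that("argument errors name the offending input", {
  expect_error(align_pair("", "ACD", default_scheme), "non-empty")
  expect_error(align_pair("ACD", "AC1D", default_scheme), "position 3")
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -5), "gap_open")
})

test_that("alignment score is symmetric under a symmetric matrix", {
  sc <- default_scheme
  withr::with_seed(11, {
    for (i in 1:25) {
      a <- random_peptide(sample(3:20, 1), AA <- c("A","C","D","E","K","L","S","V"))
      b <- random_peptide(sample(3:20, 1), AA)
      expect_equal(align_pair(a, b, sc)$score, align_pair(b, a, sc)$score)
    }
  })
})

test_that("planting extra substitutions never increases identity", {
  sc <- default_scheme
  panel <- tiny_panel()
  ref <- panel[["pgdS"]]
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  withr::with_seed(3, {
    prev <- 1.0
    mut <- chars
    pos_pool <- sample(seq_along(chars))
    for (k in seq_len(floor(nchar(ref) / 2))[1:12]) {
      p <- pos_pool[k]
      mut[p] <- sample(setdiff(AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY","")[[1]],
                               mut[p]), 1)
      id <- align_pair(ref, paste(mut, collapse = ""), sc)$identity
      expect_lte(id, prev + 1e-12)
      prev <- id
    }
  })
})

test_that("dynamic-programming scores equal brute-force enumeration", {
  sc <- default_scheme
  withr::with_seed(29, {
    for (i in 1:150) {
      a <- random_peptide(sample(1:6, 1))
      b <- random_peptide(sample(1:6, 1))
      expect_equal(align_pair(a, b, sc)$score,
                   enumerate_alignment_score(a, b, sc),
                   info = paste(a, b))
    }
  })
})

test_that("scores agree with an independent aligner on longer sequences", {
  # Biostrings charges open+extend for a gap's first residue; open = 10,
  # extend = 1 reproduces our -11/-1 convention.
  sc <- default_scheme
  mat <- sc$matrix[setdiff(rownames(sc$matrix), "X"),
                   setdiff(colnames(sc$matrix), "X")]
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- random_peptide(sample(20:40, 1), rownames(mat))
      b <- random_peptide(sample(20:40, 1), rownames(mat))
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
        type = "global", scoreOnly = TRUE
      )
      expect_equal(align_pair(a, b, sc)$score, ref)
    }
  })
})

test_that("identity range reports exact extremes", {
  expect_equal(percent_identity_range(c(0.9738, 1.0)),
               c(min = 0.9738, max = 1.0))
  expect_equal(percent_identity_range(0.5), c(min = 0.5, max = 0.5))
  withr::with_seed(5, {
    ids <- runif(100)
    expect_equal(unname(percent_identity_range(ids)),
                 unname(sort(ids)[c(1, 100)]))
  })
  expect_error(percent_identity_range(numeric(0)), "empty")
})

test_that("gene detection finds exact and diverged planted genes", {
  panel <- tiny_panel()
  rules <- load_rules()
  spec <- template_for_label("SG2.1", panel = panel, rules = rules, seed = 2)
  g <- generate_genome(spec, panel)
  hits <- find_gene_hits(g, panel)
  expect_setequal(hits$gene, spec$order)
  expect_true(all(hits$identity == 1))
  expect_true(all(diff(hits$start) > 0))

  # a pgsA diverged to ~70% identity is still found, with identity close to
  # the planted value
  ref <- panel[["pgsA"]]
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  k <- round(0.30 * length(chars))
  withr::with_seed(8, {
    pos <- sample(seq_along(chars), k)
    for (p in pos) chars[p] <- sample(setdiff(rownames(default_scheme$matrix)[1:20],
                                              chars[p]), 1)
  })
  mut <- paste(chars, collapse = "")
  g2 <- generate_genome(spec, panel, id = "DIVERGED",
                        mutated_proteins = c(pgsA = mut))
  hits2 <- find_gene_hits(g2, panel, min_identity = 0.5, min_coverage = 0.5)
  expect_true("pgsA" %in% hits2$gene)
  planted_id <- 1 - k / nchar(ref)
  expect_lt(abs(hits2$identity[hits2$gene == "pgsA"] - planted_id), 0.02)
})

test_that("genomes without related CDS yield an empty hit table", {
  feats <- tibble::tibble(
    locus_tag = "Z_0001", gene_name = NA_character_, start = 10L, end = 73L,
    strand = "+", translation = paste(rep("W", 21), collapse = ""),
    product = NA_character_
  )
  g <- genome_record("EMPTYISH", 200, feats)
  hits <- find_gene_hits(g, tiny_panel())
  expect_equal(nrow(hits), 0)
})
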