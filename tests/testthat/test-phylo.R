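test_that("MSA handles identical sequences and forced terminal gaps", {
  m <- build_msa(c(a = "ACDE", b = "ACDE"))
  expect_equal(unname(unclass(m)), c("ACDE", "ACDE"))

  m2 <- build_msa(c(a = "ACDE", b = "ACDE", c = "ACD"))
  rows <- unclass(m2)
  expect_equal(nchar(rows[["c"]]), 4)
  expect_equal(sum(strsplit(rows[["c"]], "")[[1]] == "-"), 1)
  expect_equal(gsub("-", "", rows[["c"]]), "ACD")
  expect_error(build_msa(c(a = "ACDE")), "at least 2")
})

test_that("MSA rows de-gap to their inputs", {
  panel <- tiny_panel()
  seqs <- setNames(panel[c("pgsB", "pgsC", "pgsA")], c("s1", "s2", "s3"))
  m <- build_msa(seqs)
  for (nm in names(seqs)) {
    expect_equal(gsub("-", "", unclass(m)[[nm]]), unname(seqs[[nm]]))
  }
})

test_that("the returned MSA never scores below the naive star alignment", {
  sc <- default_scheme
  withr::with_seed(37, {
    for (i in 1:25) {
      seqs <- setNames(vapply(1:3, function(k)
        random_peptide(sample(2:6, 1)), character(1)), c("a", "b", "c"))
      m <- build_msa(seqs, sc)
      sp <- pgatyper:::sp_score_cpp(unname(unclass(m)), sc$matrix,
                                    sc$alphabet, sc$gap_open, sc$gap_extend)
      # independent star construction around each possible center; the MSA
      # must match or beat the best naive star
      star_best <- -Inf
      score <- matrix(0, 3, 3)
      for (x in 1:2) for (y in (x + 1):3) {
        s <- align_pair(seqs[[x]], seqs[[y]], sc)$score
        score[x, y] <- score[y, x] <- s
      }
      star <- pgatyper:::star_msa(seqs, score, sc)
      star_sp <- pgatyper:::sp_score_cpp(unname(star), sc$matrix, sc$alphabet,
                                         sc$gap_open, sc$gap_extend)
      expect_gte(sp, star_sp - 1e-9)
    }
  })
})

test_that("p-distances count mismatches over pairwise-comparable columns", {
  m <- structure(c(a = "ACDE", b = "ACDE"), class = "pga_msa")
  expect_equal(pdistance_matrix(m)["a", "b"], 0)
  m2 <- structure(c(a = "ACDE", b = "ACDA"), class = "pga_msa")
  expect_equal(pdistance_matrix(m2)["a", "b"], 0.25)
  m3 <- structure(c(a = "AC-E", b = "ACD-"), class = "pga_msa")
  expect_equal(pdistance_matrix(m3)["a", "b"], 0)

  withr::with_seed(41, {
    rows <- vapply(1:4, function(k) {
      s <- strsplit(random_peptide(30), "")[[1]]
      s[sample(30, 5)] <- "-"
      paste(s, collapse = "")
    }, character(1))
    names(rows) <- letters[1:4]
    dm <- pdistance_matrix(structure(rows, class = "pga_msa"))
    # per-pair recount oracle
    for (i in 1:3) for (j in (i + 1):4) {
      x <- strsplit(rows[i], "")[[1]]; y <- strsplit(rows[j], "")[[1]]
      both <- x != "-" & y != "-"
      expect_equal(dm[i, j], sum(x[both] != y[both]) / sum(both))
    }
  })

  m4 <- structure(c(a = "A--", b = "-CC"), class = "pga_msa")
  expect_error(pdistance_matrix(m4), "no comparable columns")
})

test_that("neighbor joining matches the three-point closed form", {
  labs <- c("A", "B", "C")
  dm <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
               dimnames = list(labs, labs))
  tr <- neighbor_joining(dm)
  expect_equal(sort(tr$edge.length), c(0.1, 0.1, 0.3))
  co <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(co, dm, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NJ recovers additive trees exactly and the degenerate cases", {
  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(4:8, 1)
      true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
      D <- ape::cophenetic.phylo(true)
      tr <- neighbor_joining(D)
      D2 <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
      expect_lt(max(abs(D - D2)), 1e-9)
    }
  })
  t2 <- neighbor_joining(matrix(c(0, .3, .3, 0), 2,
                                dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(ape::cophenetic.phylo(t2)["x", "y"], 0.3)
  bad <- matrix(c(0, .1, .3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(neighbor_joining(bad), "asymmetric")
})

test_that("NJ topology agrees with an independent implementation", {
  withr::with_seed(19, {
    for (i in 1:10) {
      n <- sample(5:8, 1)
      labs <- paste0("t", 1:n)
      # noisy (non-additive) symmetric distances, no ties
      D <- matrix(0, n, n, dimnames = list(labs, labs))
      v <- runif(n * (n - 1) / 2, 0.1, 1)
      D[upper.tri(D)] <- v
      D <- D + t(D)
      ours <- neighbor_joining(D)
      theirs <- ape::nj(as.dist(D))
      expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("negative NJ branch estimates are clamped and recorded", {
  labs <- c("a", "b", "c", "d")
  # non-additive: the a/d three-point estimate comes out negative
  D <- matrix(c(0, 0.23, 0.72, 0.21,
                0.23, 0, 0.59, 0.95,
                0.72, 0.59, 0, 0.95,
                0.21, 0.95, 0.95, 0), 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  cl <- attr(tr, "clamped")
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$raw < 0))
})

test_that("bootstrap is seeded-reproducible and certain on clean signal", {
  A <- paste(rep("K", 200), collapse = "")
  C <- paste(rep("D", 200), collapse = "")
  msa <- build_msa(c(A = A, B = A, C = C, D = C))
  b1 <- bootstrap_support(msa, replicates = 300, seed = 42)
  b2 <- bootstrap_support(msa, replicates = 300, seed = 42)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_true(all(attr(b1, "support")$support == 100))
  expect_error(bootstrap_support(msa, replicates = 0), "replicates")
})

test_that("bootstrap supports on conflicted signal stay in [0, 100]", {
  withr::with_seed(13, {
    mk <- function(ch, n) paste(ch, collapse = "")
    # 3:1 column conflict between the AB|CD and AC|BD splits
    colAB <- c("K", "K", "D", "D")
    colAC <- c("K", "D", "K", "D")
    cols <- c(rep(list(colAB), 30), rep(list(colAC), 10))
    rows <- vapply(1:4, function(r)
      paste(vapply(cols, `[`, "", r), collapse = ""), character(1))
    names(rows) <- c("A", "B", "C", "D")
    msa <- structure(rows, class = "pga_msa")
    bt <- bootstrap_support(msa, replicates = 400, seed = 3)
    sup <- attr(bt, "support")$support
    expect_true(all(sup >= 0 & sup <= 100))
    expect_gt(sup[1], 50)  # majority signal wins most replicates
  })
})

test_that("newick round-trip preserves topology, lengths and supports", {
  A <- paste(rep("K", 150), collapse = "")
  C <- paste(rep("D", 150), collapse = "")
  msa <- build_msa(c(A = A, B = A, C = C, D = C))
  tr <- bootstrap_support(msa, replicates = 100, seed = 2)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(setdiff(back$node.label, ""), setdiff(tr$node.label, ""))
})

test_that("variant counting is exact", {
  expect_equal(count_variants(rep("MKV", 5)), 1)
  expect_equal(count_variants(c("A", "A", "B", "C")), 3)
  panel <- tiny_panel()
  ref <- panel[["racE"]]
  evs <- random_substitutions(ref, 2, seed = 4)
  plan <- mutation_plan("racE", evs, carrier_fraction = 0.5, n_strains = 10)
  strains <- generate_strain_panel(plan, panel)
  expect_equal(count_variants(strains), 2)
  expect_error(count_variants(character(0)), "at least one")
})
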