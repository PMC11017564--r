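test_that("substitutions are reported in reference-anchored notation", {
  ref <- notation_reference()  # D at position 74
  q <- sub("D", "N", ref, fixed = TRUE)
  ev <- call_substitutions(ref, q)
  expect_equal(ev$notation, "D74N")
  expect_equal(ev$position, 74L)
  expect_equal(nrow(call_substitutions(ref, ref)), 0)
  expect_error(call_substitutions("AC-D", "ACD"), "gap")
})

test_that("planted substitution sets are recovered exactly (no indels)", {
  panel <- generate_reference_panel(seed = 17,
                                    lengths = c(pgsB = 400, pgsC = 150))
  ref <- panel[["pgsB"]]
  for (s in 1:5) {
    evs <- random_substitutions(ref, sample(3:6, 1), seed = s)
    plan <- mutation_plan("pgsB", evs, carrier_fraction = 1, n_strains = 3)
    strains <- generate_strain_panel(plan, panel)
    for (q in strains) {
      called <- call_substitutions(ref, q)
      expect_setequal(called$notation, evs)  # precision = recall = 1
    }
  }
})

test_that("events plus indels reconstruct the query exactly", {
  panel <- tiny_panel()
  ref <- panel[["ggt"]]
  withr::with_seed(23, {
    for (i in 1:5) {
      chars <- strsplit(ref, "", fixed = TRUE)[[1]]
      p <- sample(seq_along(chars), 3)
      for (k in p) chars[k] <- sample(setdiff(c("K", "R", "E", "D"), chars[k]), 1)
      # one deletion and one insertion, away from the substitutions
      chars <- chars[-(30:33)]
      q <- paste(c(chars[1:10], "WWW", chars[11:length(chars)]), collapse = "")
      ev <- call_substitutions(ref, q)
      expect_equal(reconstruct_query(ref, ev), q)
      expect_gt(nrow(attr(ev, "indels")), 0)
    }
  })
})

test_that("frequencies divide carrier counts by the panel size", {
  tb <- tibble::tibble(strain = c("s1", "s2", "s3"), notation = "E119K")
  ft <- substitution_frequencies(tb, panel_size = 4)
  expect_equal(ft$count, 3L)
  expect_equal(ft$percent, "75.00%")

  # 162 of 183 carriers print as 88.52% (162/183 = 0.88525)
  tb2 <- tibble::tibble(strain = sprintf("s%03d", 1:162), notation = "L235S")
  ft2 <- substitution_frequencies(tb2, panel_size = 183)
  expect_equal(ft2$percent, "88.52%")
  expect_equal(ft2$frequency, 162 / 183)

  expect_error(substitution_frequencies(tb, panel_size = 0), "panel_size")
  mixed <- tibble::tibble(strain = "s", notation = "A1G",
                          protein = c("pgsA", "pgsB"))
  expect_error(substitution_frequencies(mixed, 2), "inconsistent protein")
})

test_that("rows sort by descending frequency then position", {
  tb <- tibble::tibble(
    strain = c("s1", "s2", "s3", "s1", "s1", "s2"),
    notation = c("K10R", "K10R", "K10R", "A5G", "D80N", "D80N")
  )
  ft <- substitution_frequencies(tb, panel_size = 3)
  expect_equal(ft$notation, c("K10R", "D80N", "A5G"))
})

test_that("ceiling carrier counts give exact planted frequencies", {
  panel <- tiny_panel()
  ref <- panel[["pgsC"]]
  evs <- random_substitutions(ref, 2, seed = 2)
  for (case in list(c(0.75, 4, "75.00%"), c(0.8, 200, "80.00%"))) {
    plan <- mutation_plan("pgsC", evs, carrier_fraction = as.numeric(case[1]),
                          n_strains = as.integer(case[2]))
    strains <- generate_strain_panel(plan, panel)
    long <- purrr::imap_dfr(strains, function(s, nm) {
      ev <- call_substitutions(ref, s)
      if (nrow(ev) == 0) return(tibble::tibble())
      ev$strain <- nm
      ev
    })
    ft <- substitution_frequencies(long, panel_size = plan$n_strains)
    expect_true(all(ft$percent == case[3]))
    truth <- attr(strains, "truth")
    expect_equal(sum(truth$carrier), unique(ft$count))
  }
})

test_that("identity matrices are symmetric with unit diagonal and exact range", {
  two <- c(a = "MKKLV", b = "MKKLV")
  m <- identity_matrix(two)
  expect_equal(attr(m, "range"), c(min = 1, max = 1))

  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 98), "C", "C"), collapse = "")
  m2 <- identity_matrix(c(x = s1, y = s2))
  expect_equal(m2["x", "y"], 0.98)

  panel <- tiny_panel()
  seqs <- setNames(panel[1:4], c("w", "x", "y", "z"))
  m3 <- identity_matrix(seqs)
  expect_equal(m3, t(m3))
  expect_equal(unname(diag(m3)), rep(1, 4))
  # element-wise oracle: direct pairwise recomputation
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(m3[i, j], align_pair(seqs[[i]], seqs[[j]])$identity)
  }
  expect_error(identity_matrix(c(a = "MK")), "at least 2")
})

test_that("catalog_variation aggregates events, frequencies and ranges", {
  panel <- tiny_panel()
  ref <- panel[["pgdS"]]
  evs <- random_substitutions(ref, 3, seed = 5)
  plan <- mutation_plan("pgdS", evs, carrier_fraction = 0.5, n_strains = 6)
  strains <- generate_strain_panel(plan, panel)
  cv <- catalog_variation(strains, "pgdS", panel)
  expect_equal(cv$n_strains, 6)
  expect_setequal(cv$frequencies$notation, evs)
  expect_true(all(cv$frequencies$percent == "50.00%"))
  expect_lt(cv$identity_range["min"], 1)
  expect_equal(unname(cv$identity_range["max"]), 1)
})
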