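test_that("p-distance applies pairwise deletion and CpG masking", {
  pd <- p_distance("ACGT", "ACGA", mask_cpg = FALSE)
  expect_equal(pd, list(D = 0.25, sites = 4L))

  pd <- p_distance("AC-T", "ACGT", mask_cpg = FALSE)
  expect_equal(pd, list(D = 0, sites = 3L))

  # CG in sequence a masks both positions in the pair
  expect_equal(p_distance("TTCGTT", "TTTATT", mask_cpg = FALSE)$D, 2 / 6)
  pd <- p_distance("TTCGTT", "TTTATT", mask_cpg = TRUE)
  expect_equal(pd, list(D = 0, sites = 4L))

  expect_error(p_distance("---", "AAA"), "no comparable sites")
})

test_that("p-distance is symmetric, bounded, and masking never adds sites", {
  withr::with_seed(31, {
    for (k in 1:20) {
      a <- rand_dna(300, k)
      b <- rand_dna(300, k + 100)
      for (mask in c(TRUE, FALSE)) {
        ab <- p_distance(a, b, mask)
        ba <- p_distance(b, a, mask)
        expect_identical(ab, ba)
        expect_gte(ab$D, 0)
        expect_lte(ab$D, 1)
      }
      expect_lte(p_distance(a, b, TRUE)$sites, p_distance(a, b, FALSE)$sites)
    }
  })
})

test_that("age estimates follow T = D% / 0.34, halved for LTR pairs", {
  # plant exactly 3.4% divergence between two LTR-like sequences
  L <- 1000L
  a <- rand_dna(L, 5)
  ch <- strsplit(a, "")[[1]]
  idx <- round(seq(10, 990, length.out = 34)) # spread, so no gap artefacts
  ch[idx] <- chartr("ACGT", "CATG", ch[idx]) # derangement: every base changes
  b <- paste(ch, collapse = "")
  D <- p_distance(a, b, mask_cpg = FALSE)$D
  est <- estimate_age(list(id = "x", ltr5 = a, ltr3 = b), REF, "ltr_vs_ltr",
                      mask_cpg = FALSE)
  expect_equal(est$T, (D * 100) / 0.34 / 2)
  gag_est <- estimate_age(list(id = "x", gag = b), REF, "gag_vs_consensus",
                          consensus = a, mask_cpg = FALSE)
  expect_equal(gag_est$T, (D * 100) / 0.34) # no halving

  ident <- estimate_age(list(ltr5 = a, ltr3 = a), REF, "ltr_vs_ltr")
  expect_equal(ident$T, 0)

  expect_error(estimate_age(list(ltr5 = a, ltr3 = b), REF, "ltr_vs_consensus"),
               "consensus")
})

test_that("consensus construction uses plurality with reference tie-breaking", {
  prs <- lapply(c("a", "b", "c"), function(id) {
    project_locus(REF$provirus, REF, id)
  })
  cons <- build_consensus(prs, REF, "LTR5")
  expect_equal(cons, REF$ltr) # identical members -> that sequence

  # plurality and ties on a constructed column set
  p1 <- prs[[1]]; p2 <- prs[[2]]; p3 <- prs[[3]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(REF$ltr, 1, 1))
  p1$matched[1] <- alt[1]; p2$matched[1] <- alt[1]; p3$matched[1] <- alt[2]
  expect_equal(substr(build_consensus(list(p1, p2, p3), REF, "LTR5"), 1, 1),
               alt[1]) # plurality wins
  p2$matched[1] <- alt[2]
  p3$matched[1] <- substr(REF$ltr, 1, 1)
  expect_equal(substr(build_consensus(list(p1, p2, p3), REF, "LTR5"), 1, 1),
               substr(REF$ltr, 1, 1)) # tie broken toward the reference
  # columns gapped in >50% of members become gaps
  p1$matched[2] <- "-"; p2$matched[2] <- "-"
  expect_equal(substr(build_consensus(list(p1, p2, p3), REF, "LTR5"), 2, 2), "-")

  expect_error(build_consensus(list(), REF), "empty")
})

test_that("age summaries use standard medians and type-7 quartiles", {
  est <- tibble::tibble(category = "c", T = c(1, 2, 3))
  s <- summarize_ages(est)
  expect_equal(s$median, 2)
  one <- summarize_ages(tibble::tibble(category = "c", T = 7))
  expect_equal(c(one$median, one$q1, one$q3), c(7, 7, 7))
  four <- summarize_ages(tibble::tibble(category = "c", T = c(1, 2, 3, 10)))
  expect_equal(four$median, 2.5)
  expect_equal(four$q1, stats::quantile(c(1, 2, 3, 10), 0.25, names = FALSE))
})

test_that("LTR-vs-LTR and LTR-vs-consensus agree on planted loci", {
  for (T in c(6, 18)) {
    loc <- simulate_locus(REF, "macaque", T = T, seed = 70 + T, id = "agr")
    e1 <- estimate_age(loc, REF, "ltr_vs_ltr")
    e2 <- estimate_age(loc, REF, "ltr_vs_consensus", consensus = REF$ltr)
    expect_lt(abs(e1$T - e2$T), 0.16)
  }
})

test_that("boosted CpG mutation inflates unmasked but not masked estimates", {
  m <- build_reference(3, cpg_free = FALSE)
  loc <- simulate_locus(m, "macaque", T = 10, seed = 77, id = "cpg",
                        cpg_boost = 12)
  masked <- estimate_age(loc, m, "ltr_vs_ltr", mask_cpg = TRUE)
  unmasked <- estimate_age(loc, m, "ltr_vs_ltr", mask_cpg = FALSE)
  expect_gt(unmasked$T, masked$T)
  expect_lt(abs(masked$T - 10), abs(unmasked$T - 10))
})
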