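aligned_matrix <- function(seqs) {
  m <- t(vapply(seqs, function(s) strsplit(s, "")[[1]],
                character(nchar(seqs[1]))))
  rownames(m) <- names(seqs)
  m
}

test_that("distance matrices are symmetric p-distances over shared columns", {
  m <- aligned_matrix(c(a = "ACGT", b = "ACGA", c = "TCGA"))
  d <- distance_matrix(m, mask_cpg = FALSE)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(d["b", "c"], 0.25)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  ident <- aligned_matrix(c(a = "ACTT", b = "ACTT", c = "ACTT"))
  expect_true(all(distance_matrix(ident) == 0))

  # masking is a no-op on CpG-free input
  free <- aligned_matrix(c(a = "ACTT", b = "ACTA", c = "TCTA"))
  expect_equal(distance_matrix(free, mask_cpg = TRUE),
               distance_matrix(free, mask_cpg = FALSE))

  gappy <- aligned_matrix(c(a = "AC--", b = "AC--", c = "--GT"))
  expect_error(distance_matrix(gappy, mask_cpg = FALSE), "no shared columns")
})

test_that("NJ recovers the generating tree from additive distances", {
  # ((A:0.1,B:0.1):0.2,(C:0.1,D:0.1)) -> dAB = dCD = 0.2, cross = 0.4
  d <- matrix(0.4, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                         c("A", "B", "C", "D")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 4)
  # the AB|CD split is present and path lengths reproduce the input
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(coph, d, tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ is exact on random additive matrices (path-length oracle)", {
  withr::with_seed(101, {
    for (k in 1:15) {
      n <- sample(6:10, 1)
      gen <- ape::rtree(n, br = function(x) stats::runif(x, 0.05, 0.5))
      gen <- ape::unroot(gen)
      d <- ape::cophenetic.phylo(gen)
      rec <- nj_tree(d)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(rec), gen)), 0)
      expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                   tolerance = 1e-9)
    }
  })
})

test_that("tip label order does not change the tree", {
  loci <- lapply(1:5, function(i) {
    simulate_locus(REF, "macaque", T = 4 * i, seed = 200 + i,
                   id = sprintf("t%d", i))
  })
  prs <- lapply(loci, function(l) project_locus(l$seq, REF, l$id))
  d <- distance_matrix(prs, REF, region = "LTR5")
  t1 <- nj_tree(d)
  perm <- c(3, 1, 5, 2, 4)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("bootstrap supports distinguish planted clades and are reproducible", {
  # two clades: within-clade divergence ~1%, between ~20%
  base1 <- rand_dna(800, 1)
  base2 <- withr::with_seed(2, {
    ch <- strsplit(base1, "")[[1]]
    idx <- sample(800, 160)
    ch[idx] <- chartr("ACGT", "CATG", ch[idx])
    paste(ch, collapse = "")
  })
  jitter <- function(s, seed) {
    withr::with_seed(seed, {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(800, 8)
      ch[idx] <- chartr("ACGT", "CATG", ch[idx])
      paste(ch, collapse = "")
    })
  }
  seqs <- c(
    setNames(vapply(1:4, function(i) jitter(base1, 10 + i), character(1)),
             paste0("x", 1:4)),
    setNames(vapply(1:4, function(i) jitter(base2, 20 + i), character(1)),
             paste0("y", 1:4))
  )
  m <- aligned_matrix(seqs)
  tr <- bootstrap_support(m, n_reps = 200, seed = 7)
  sup <- split_support(tr, paste0("x", 1:4))
  if (is.na(sup)) sup <- split_support(tr, paste0("y", 1:4))
  expect_gte(sup, 95)

  tr2 <- bootstrap_support(m, n_reps = 200, seed = 7)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  tr1 <- bootstrap_support(m, n_reps = 1, seed = 3)
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})
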