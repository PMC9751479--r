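test_that("global alignment matches hand-checkable scores", {
  aln <- global_align("ACGT", "ACGT")
  expect_equal(aln$score, 8)
  expect_equal(aln$a, "ACGT")
  expect_equal(aln$b, "ACGT")

  # one 1-nt deletion: 3 matches - (open + extend) = 6 - 7 = -1
  aln <- global_align("ACGT", "AGT")
  expect_equal(aln$score, -1)
  expect_equal(nchar(aln$a), 4)
  expect_equal(sum(strsplit(aln$b, "")[[1]] == "-"), 1)

  # swapping the inputs swaps insertion/deletion roles, same score
  a <- rand_dna(40, 1); b <- rand_dna(35, 2)
  expect_equal(global_align(a, b)$score, global_align(b, a)$score)

  # N mismatches everything, including N
  expect_equal(global_align("NN", "NN")$score, -6)
})

test_that("Gotoh scores equal an independent cubic-DP oracle on short pairs", {
  withr::with_seed(99, {
    for (case in 1:25) {
      n <- sample(3:14, 1); m <- sample(3:14, 1)
      a <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
      expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("projecting the reference onto itself is the identity", {
  pr <- project_locus(REF$provirus, REF, "self")
  expect_equal(paste(pr$matched, collapse = ""), REF$provirus)
  expect_equal(nrow(pr$ins), 0)
  expect_equal(nrow(call_indels(pr, REF)), 0)
  ann <- annotate_regions(pr, REF)
  expect_true(all(ann$regions$coverage == 1))
  expect_true(ann$full_length)
  expect_equal(ervkit:::gc_content("ACGT"), 0.5)
})

test_that("planted signature indels are recovered with exact lengths", {
  loc <- simulate_locus(REF, "macaque", T = 10, env_variant = "1", seed = 21)
  pr <- project_locus(loc$seq, REF, "m")
  ind <- call_indels(pr, REF)
  del <- ind[ind$kind == "deletion", ]
  ins <- ind[ind$kind == "insertion", ]
  expect_equal(del$length, 12)
  expect_lte(abs(del$ref_start - (region_span(REF, "gag")$start + 1)), 2)
  expect_equal(ins$length, 96)
  expect_lte(abs(ins$ref_start - REF$ltr_len - 745), 2)
  expect_true(all(grepl("gag", ind$region)))

  locI <- simulate_locus(REF, "human", T = 5, env_type = "I", seed = 22)
  indI <- call_indels(project_locus(locI$seq, REF, "h"), REF)
  expect_equal(indI$length, 292)
  expect_equal(indI$region, "env")
})

test_that("indel lengths balance the locus-length bookkeeping", {
  withr::with_seed(7, {
    for (variant in c("1", "2", "3")) {
      loc <- simulate_locus(REF, "macaque", T = 12, env_variant = variant,
                            seed = sample.int(1000, 1), parent = MER)
      pr <- project_locus(loc$seq, REF)
      ind <- call_indels(pr, REF)
      covered <- sum(pr$matched != "-")
      net <- sum(ind$length[ind$kind == "insertion"]) -
        sum(ind$length[ind$kind == "deletion"])
      expect_equal(net, nchar(loc$seq) - nchar(REF$provirus))
      expect_equal(covered + sum(ind$length[ind$kind == "insertion"]),
                   nchar(loc$seq))
    }
  })
})

test_that("region annotation flags truncated loci", {
  # truncate after pro: keep LTR5 + internal through pro end
  pro_end <- region_span(REF, "pro")$end
  trunc <- substr(REF$provirus, 1, pro_end)
  ann <- annotate_regions(project_locus(trunc, REF), REF)
  cov <- setNames(ann$regions$coverage, ann$regions$region)
  expect_equal(unname(cov["gag"]), 1)
  expect_lt(unname(cov["pol"]), 0.8)
  expect_lt(unname(cov["env"]), 0.8)
  expect_false(ann$full_length)
})
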