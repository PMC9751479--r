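test_that("segmentation handles pure-parent and hand-checkable mosaics", {
  pa <- strrep("A", 30); pb <- strrep("C", 30)
  s <- segment_two_parents(pa, pa, pb, sigma = 3)
  expect_equal(nrow(s$segments), 1)
  expect_equal(s$segments$parent, "A")
  expect_equal(s$cost, 0)
  expect_equal(nrow(s$breakpoints), 0)

  q <- paste0(strrep("A", 10), strrep("C", 10), strrep("A", 10))
  s <- segment_two_parents(q, pa, pb, sigma = 3)
  expect_equal(s$segments$parent, c("A", "B", "A"))
  expect_equal(s$segments$start, c(1L, 11L, 21L))
  expect_equal(s$segments$end, c(10L, 20L, 30L))
  expect_equal(s$cost, 6)

  expect_error(segment_two_parents(q, pa, pb, sigma = -1), "sigma")

  o <- oracle_segment(strrep("C", 20), strrep("A", 20), strrep("C", 20))
  expect_equal(o$segments$parent, "B")
  expect_error(oracle_segment(strrep("A", 1500), pa, pb), "1000")
})

test_that("switching can only reduce cost, and sigma monotonically curbs switches", {
  withr::with_seed(91, {
    for (k in 1:10) {
      q <- rand_dna(150, k)
      pa <- rand_dna(150, k + 50)
      pb <- rand_dna(150, k + 90)
      cA <- sum(ervkit:::parent_cost(q, pa))
      cB <- sum(ervkit:::parent_cost(q, pb))
      prev_switches <- Inf
      for (sigma in c(0.5, 2, 5, 20)) {
        s <- segment_two_parents(q, pa, pb, sigma)
        expect_lte(s$cost, min(cA, cB))
        n_sw <- nrow(s$segments) - 1
        expect_lte(n_sw, prev_switches)
        prev_switches <- n_sw
      }
    }
  })
})

test_that("the DP equals the exhaustive oracle on few-breakpoint instances", {
  withr::with_seed(92, {
    for (k in 1:25) {
      q <- rand_dna(200, k)
      pa <- rand_dna(200, k + 500)
      pb <- rand_dna(200, k + 900)
      dp <- segment_two_parents(q, pa, pb, sigma = 3)
      or <- oracle_segment(q, pa, pb, sigma = 3, max_breakpoints = 2)
      expect_lte(dp$cost, or$cost)
      if (nrow(dp$segments) <= 3) expect_equal(dp$cost, or$cost)
    }
  })
})

test_that("planted breakpoints on divergent parents are recovered within 5 nt", {
  withr::with_seed(93, {
    miss <- 0
    for (k in 1:30) {
      pa <- rand_dna(400, k)          # unrelated parents: ~75% divergent
      pb <- rand_dna(400, k + 1000)
      b1 <- sample(100:150, 1); b2 <- sample(250:300, 1)
      q <- paste0(substr(pa, 1, b1), substr(pb, b1 + 1, b2),
                  substr(pa, b2 + 1, 400))
      s <- segment_two_parents(q, pa, pb, sigma = 3)
      bseg <- s$segments[s$segments$parent == "B", ]
      expect_equal(nrow(bseg), 1)
      if (abs(bseg$start - (b1 + 1)) > 5 || abs(bseg$end - b2) > 5) {
        miss <- miss + 1
      }
    }
    expect_equal(miss, 0)
  })
})

test_that("a synthetic variant-3 env resolves into stub / MER11A / stub", {
  loc <- simulate_locus(REF, "macaque", T = 5.6, env_variant = "3", seed = 1,
                        id = "v3", parent = MER)
  env <- locus_true_region(loc, REF, "env")
  s <- segment_two_parents(env, ervkit:::region_seq(REF, "env"), MER$seq,
                           sigma = 3)
  expect_equal(s$segments$parent, c("A", "B", "A"))
  b <- s$segments[s$segments$parent == "B", ]
  expect_lte(abs(b$length - 673), 2)
  # only short stubs of the original env remain
  a <- s$segments[s$segments$parent == "A", ]
  expect_true(all(a$length < 200))
  expect_equal(tidy(s), s$segments)
})
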