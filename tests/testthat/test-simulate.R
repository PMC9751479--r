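test_that("divergence planting is exact and disjoint between LTR copies", {
  d0 <- plant_divergence(REF$ltr, REF$internal, 0, seed = 1)
  expect_equal(d0$ltr5, REF$ltr)
  expect_equal(d0$ltr3, REF$ltr)

  d5 <- plant_divergence(REF$ltr, REF$internal, 5, seed = 1)
  ham <- sum(strsplit(d5$ltr5, "")[[1]] != strsplit(d5$ltr3, "")[[1]])
  expect_equal(ham, 2 * round(968 * 0.0034 * 5)) # 32 sites
  # each copy diverges from the ancestor at half the pair divergence
  expect_equal(sum(strsplit(d5$ltr5, "")[[1]] != strsplit(REF$ltr, "")[[1]]),
               round(968 * 0.0034 * 5))

  expect_error(plant_divergence(REF$ltr, REF$internal, 150, seed = 1),
               "saturates")
})

test_that("planted divergence closes the loop with the dating module", {
  for (T in c(5, 10, 22)) {
    loc <- simulate_locus(REF, "macaque", T = T, seed = 40 + T, id = "cl")
    est <- estimate_age(loc, REF, "ltr_vs_ltr")
    expect_lt(abs(est$T - T), 0.16) # one LTR-site quantum
  }
})

test_that("signature profiles plant the recorded indels", {
  loc <- simulate_locus(REF, "macaque", T = 10, env_variant = "1", seed = 2)
  expect_equal(nrow(loc$indels), 2)
  del <- loc$indels[loc$indels$kind == "deletion", ]
  expect_equal(del$length, 12)
  expect_equal(del$ref_start, region_span(REF, "gag")$start + 1L)
  ins <- loc$indels[loc$indels$kind == "insertion", ]
  expect_equal(ins$length, 96)
  expect_equal(ins$ref_start - REF$ltr_len, 745)

  # human profile, type II, no variant: zero planted indels
  h <- simulate_locus(REF, "human", T = 10, seed = 3)
  expect_equal(nrow(h$indels), 0)

  # variant 3 truth records the donor-length replacement
  v3 <- simulate_locus(REF, "macaque", T = 5, env_variant = "3", seed = 4,
                       parent = MER)
  expect_equal(v3$recomb_breakpoints, c(150, 823))
  expect_equal(nchar(locus_true_region(v3, REF, "env")), 150 + 673 + 120)
})

test_that("incompatible profile and variant combinations error", {
  expect_error(simulate_locus(REF, "macaque", env_type = "I", seed = 1),
               "human-only")
  expect_error(simulate_locus(REF, "human", env_variant = "3", seed = 1,
                              parent = MER), "macaque-only")
  expect_error(simulate_locus(REF, "macaque", env_variant = "3", seed = 1),
               "parent")
})

test_that("solo LTR loci are a single diverged LTR copy", {
  s <- simulate_locus(REF, "macaque", T = 8, solo_ltr = TRUE, seed = 5)
  expect_true(s$solo_ltr)
  expect_equal(nchar(s$seq), 968)
  expect_equal(s$parts$name, "LTR5")
  expect_error(estimate_age(s, REF, "ltr_vs_ltr"), "unavailable")
  # consensus-based dating still applies to solo LTRs
  est <- estimate_age(s, REF, "ltr_vs_consensus", consensus = REF$ltr)
  expect_lt(abs(est$T - 8), 0.16)
})

test_that("cohorts honour configured counts, round-trip, and are deterministic", {
  cfg <- cohort_config(n_human_shared = 2, n_macaque_shared = 4,
                       n_species_specific = 3)
  co <- simulate_cohort(cfg, seed = 11)
  counts <- dplyr::count(co$truth, category)
  expect_equal(counts$n[match(c("human_shared", "macaque_shared",
                                "species_specific"), counts$category)],
               c(2L, 4L, 3L))
  expect_equal(sum(co$truth$solo_ltr), 1)

  # category is a pure function of the species set
  expect_true(all(
    (co$truth$category == "human_shared") ==
      grepl("human", co$truth$species_set)))
  expect_true(all(
    (co$truth$category == "species_specific") ==
      !grepl(",", co$truth$species_set)))

  # extracting each recorded interval reproduces the stored locus sequence
  for (i in seq_len(nrow(co$placements))) {
    p <- co$placements[i, ]
    s <- substr(co$genomes[[p$species]], p$start + 1, p$end)
    if (p$strand == "-") s <- ervkit:::revcomp(s)
    expect_identical(s, co$loci[[paste(p$locus_id, p$species, sep = ":")]]$seq)
  }

  co2 <- simulate_cohort(cfg, seed = 11)
  expect_identical(co$genomes, co2$genomes)
  co3 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(co$genomes, co3$genomes))
})

test_that("unknown cohort config keys error", {
  expect_error(cohort_config(nn_loci = 5), "unknown")
})
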