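test_that("the reference's own genes are intact with full domain sets", {
  pr <- project_locus(REF$provirus, REF, "self")
  gag <- orf_integrity(pr, REF, "gag")
  expect_true(gag$intact)
  expect_equal(gag$premature_stops, 0L)
  expect_false(gag$frameshift)
  expect_equal(gag$n_zinc_knuckle, 2L)
  expect_equal(strsplit(gag$domains_present, ",")[[1]], c("MA", "CA", "NC"))
  pol <- orf_integrity(pr, REF, "pol")
  expect_true(pol$intact)
  expect_equal(strsplit(pol$domains_present, ",")[[1]], c("RT", "RH", "IN"))
  env <- orf_integrity(pr, REF, "env")
  expect_true(env$intact)
  expect_true(env$nls && env$nes)
})

test_that("planted stops and frameshifts break intactness", {
  # plant a TAA at an interior gag codon (aa 300)
  gag <- region_span(REF, "gag")
  pos0 <- gag$start + 3 * 299
  mutant <- paste0(substr(REF$provirus, 1, pos0), "TAA",
                   substr(REF$provirus, pos0 + 4, nchar(REF$provirus)))
  rep <- orf_integrity(project_locus(mutant, REF), REF, "gag")
  expect_false(rep$intact)
  expect_equal(rep$premature_stops, 1L)
  expect_false(rep$frameshift)

  # a 1-nt insertion mid-gene shifts the frame
  fs <- paste0(substr(REF$provirus, 1, gag$start + 600), "A",
               substr(REF$provirus, gag$start + 601, nchar(REF$provirus)))
  repfs <- orf_integrity(project_locus(fs, REF), REF, "gag")
  expect_true(repfs$frameshift)
  expect_false(repfs$intact)

  # absent gene reports intact = FALSE with zero coverage
  ltr_only <- substr(REF$provirus, 1, 968)
  repabs <- orf_integrity(project_locus(ltr_only, REF), REF, "env")
  expect_false(repabs$intact)
  expect_equal(repabs$coverage, 0)
})

test_that("frameshift depends on net indel phase, not indel placement", {
  gag <- region_span(REF, "gag")
  # +1 and +2 insertions at different places: net phase 0 -> no frameshift
  s <- REF$provirus
  twoins <- paste0(substr(s, 1, gag$start + 300), "A",
                   substr(s, gag$start + 301, gag$start + 900), "CT",
                   substr(s, gag$start + 901, nchar(s)))
  rep <- orf_integrity(project_locus(twoins, REF), REF, "gag")
  expect_false(rep$frameshift)
})

test_that("motif scanning matches the knuckle pattern and tolerant peptides", {
  hits <- scan_motifs("CAACAAAAHAAAAC")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 1L)
  expect_equal(hits$motif, "zinc_knuckle")
  expect_equal(nrow(scan_motifs("AAAA")), 0)
  # overlapping matches are reported
  expect_equal(sum(scan_motifs("CAACAAAAHAAAACAACAAAAHAAAAC")$motif ==
                     "zinc_knuckle"), 2)
  # NLS with one substituted residue still matches
  pep <- REF$motif_peptides$NLS
  substr(pep, 3, 3) <- "G"
  expect_true("NLS" %in% scan_motifs(paste0("AAA", pep, "AAA"), REF)$motif)
})

test_that("domain presence reflects coverage of the reference span", {
  pr <- project_locus(REF$provirus, REF)
  expect_equal(domain_presence(pr, REF, "gag"), c("MA", "CA", "NC"))
  # truncate before the nucleocapsid: MA and CA only
  nc <- REF$domains[REF$domains$name == "NC", ]
  trunc <- substr(REF$provirus, 1, nc$start - 100)
  prt <- project_locus(trunc, REF)
  expect_equal(domain_presence(prt, REF, "gag"), c("MA", "CA"))
})

test_that("Rec detection separates variants 1/2 from variant 3", {
  v1 <- simulate_locus(REF, "macaque", T = 10, env_variant = "1", seed = 81)
  r1 <- detect_rec(project_locus(v1$seq, REF), REF)
  expect_true(r1$rec_present && r1$nls && r1$nes)

  v2 <- simulate_locus(REF, "macaque", T = 10, env_variant = "2", seed = 82)
  r2 <- detect_rec(project_locus(v2$seq, REF), REF)
  expect_true(r2$rec_present && r2$nls && r2$nes)

  v3 <- simulate_locus(REF, "macaque", T = 10, env_variant = "3", seed = 83,
                       parent = MER)
  r3 <- detect_rec(project_locus(v3$seq, REF), REF)
  expect_false(r3$rec_present || r3$nls || r3$nes)

  ltr_only <- substr(REF$provirus, 1, 968)
  r0 <- detect_rec(project_locus(ltr_only, REF), REF)
  expect_false(r0$rec_present || r0$nls || r0$nes)
})

test_that("truth-marked coding status agrees with the reported ORF calls", {
  cfg <- cohort_config(n_human_shared = 2, n_macaque_shared = 3,
                       n_species_specific = 2,
                       age_human_shared = 8, age_macaque_shared = 5,
                       age_species_specific = 2)
  co <- simulate_cohort(cfg, seed = 55)
  m <- co$model # the cohort builds its reference from its own seed
  for (i in seq_len(nrow(co$placements))) {
    p <- co$placements[i, ]
    loc <- co$loci[[paste(p$locus_id, p$species, sep = ":")]]
    if (loc$solo_ltr) next
    pr <- project_locus(loc$seq, m, p$locus_id)
    for (g in c("gag", "pol", "env")) {
      expect_equal(orf_integrity(pr, m, g)$intact, p[[paste0(g, "_intact")]],
                   info = paste(p$locus_id, p$species, g))
    }
  }
})
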