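test_that("FASTA reading normalizes and validates records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgu", ">y", "ACGT", "NNRT"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("x", "y"))
  expect_equal(rec$description[1], "some description")
  expect_equal(rec$seq[1], "ACGT")        # lowercase + U -> T
  expect_equal(rec$seq[2], "ACGTNNNT")    # ambiguity codes collapse to N

  writeLines(c(">x", "ACQT"), f)
  expect_error(read_fasta(f), "x")
  writeLines(c(">empty", "", ">y", "ACGT"), f)
  expect_error(read_fasta(f), "empty")
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")), "not found")
})

test_that("FASTA writer round-trips records", {
  f <- withr::local_tempfile(fileext = ".fa")
  recs <- tibble::tibble(id = c("a", "b"), description = c("", "d"),
                         seq = c(rand_dna(200, 1), rand_dna(35, 2)))
  write_fasta(recs, f, width = 60)
  expect_equal(read_fasta(f), recs)
})

test_that("BED6 writing follows the 0-based half-open convention and round-trips", {
  f <- withr::local_tempfile(fileext = ".bed")
  loci <- tibble::tibble(contig = "chr1", start = 10L, end = 20L, name = "L1",
                         score = 0L, strand = "+")
  write_bed(loci, f)
  expect_equal(readLines(f), "chr1\t10\t20\tL1\t0\t+")
  expect_equal(read_bed(f), loci)

  write_bed(loci[0, ], f)
  expect_equal(file.size(f), 0)
  expect_equal(nrow(read_bed(f)), 0)

  expect_error(write_bed(dplyr::mutate(loci, start = 25L), f), "start")
})

test_that("Newick writing stores branch lengths and supports, and round-trips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  write_newick(tr, f)
  expect_equal(readLines(f), "(A:0.1,B:0.2);")

  tr4 <- ape::read.tree(text = "((A:0.1,B:0.1)97:0.2,(C:0.1,D:0.1):0.05);")
  write_newick(tr4, f)
  back <- read_newick(f)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr4))),
               0)
  expect_true("97" %in% back$node.label)
  expect_equal(sort(back$edge.length), sort(tr4$edge.length))

  dup <- tr
  dup$tip.label <- c("A", "A")
  expect_error(write_newick(dup, f), "duplicate")
  neg <- tr
  neg$edge.length[1] <- -0.1
  expect_error(write_newick(neg, f), "negative")
})

test_that("coordinate converters compose to the identity", {
  iv <- iv_from_1based(156, 2297)
  expect_equal(iv, list(start = 155L, end = 2297L))
  expect_equal(iv_to_1based(iv$start, iv$end), list(start = 156L, end = 2297L))
})

test_that("run configuration rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(k = 12, bootstrap_reps = 50), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$k, 12)
  expect_equal(cfg$bootstrap_reps, 50)
  yaml::write_yaml(list(kmer = 12), f)
  expect_error(read_run_config(f), "unknown config key")
  expect_error(validate_config(default_config(k = 4)))
})
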