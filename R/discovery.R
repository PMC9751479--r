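# Seed-and-extend discovery of proviral loci and cross-species orthology
# classification from flanking sequence.

# Reference k-mer catalog: every k-mer of the reference provirus on both
# strands, labelled with the reference part it comes from.
reference_seeds <- function(model, k) {
  if (nchar(model$provirus) < k) abort("reference shorter than k")
  prov <- model$provirus
  n <- nchar(prov) - k + 1L
  starts <- seq_len(n)
  kmers <- substring(prov, starts, starts + k - 1L)
  part <- dplyr::case_when(
    starts + k - 1L <= model$ltr_len ~ "LTR5",
    starts > model$ltr_len + model$internal_len ~ "LTR3",
    starts > model$ltr_len & starts + k - 1L <= model$ltr_len + model$internal_len ~ "internal",
    TRUE ~ "junction"
  )
  fw <- tibble(kmer = kmers, ref_pos = starts, part = part, strand = "+")
  rv <- tibble(kmer = unname(revcomp(kmers)), ref_pos = starts, part = part,
               strand = "-")
  dplyr::bind_rows(fw, rv) |> dplyr::filter(!grepl("N", .data$kmer, fixed = TRUE))
}

#' Scan a genome for HML2-like loci by seed-and-extend k-mer matching
#'
#' Exact k-mer seeds from the reference provirus (both strands) are located in
#' the genome, clustered into candidate loci (seeds on the same strand closer
#' than `merge_gap` are merged), and filtered: a cluster must contain at least
#' `min_seeds` seeds, and clusters shorter than `min_internal_len` are kept
#' only if they contain LTR seeds (solo LTRs). A hit whose seeds include an
#' LTR but no internal sequence is flagged `solo_ltr`.
#'
#' @param genome A genome sequence (string) or a one-row tibble from
#'   [read_fasta()].
#' @param model An `erv_reference`.
#' @param k Seed length (default 16, minimum 8).
#' @param min_internal_len Minimum hit span without LTR seeds (default 500).
#' @param merge_gap Maximum gap between chained seeds (default 2000).
#' @param min_seeds Minimum seed count per hit (default 5); guards against
#'   chance k-mer matches in megabase-scale genomes.
#' @param contig Contig name for the output intervals.
#' @return A tibble of hits: `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `score` (seed count), `matched_parts`, `solo_ltr`.
#' @export
scan_genome <- function(genome, model, k = 16, min_internal_len = 500,
                        merge_gap = 2000, min_seeds = 5, contig = "chr1") {
  if (is.data.frame(genome)) {
    contig <- genome$id[1]
    genome <- genome$seq[1]
  }
  stopifnot(k >= 8, nchar(genome) > 0)
  seeds <- reference_seeds(model, k)
  uniq <- unique(seeds$kmer)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome))
  counts <- S4Vectors::elementNROWS(m)
  if (sum(counts) == 0) return(empty_hits())
  gpos <- BiocGenerics::start(BiocGenerics::unlist(m))
  kidx <- rep.int(seq_along(uniq), counts)
  matches <- tibble(kmer = uniq[kidx], gpos = gpos) |>
    dplyr::inner_join(seeds, by = "kmer", relationship = "many-to-many")

  clusters <- matches |>
    dplyr::group_by(.data$strand) |>
    dplyr::arrange(.data$gpos, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(c(1L, diff(.data$gpos) > merge_gap))) |>
    dplyr::group_by(.data$strand, .data$cluster) |>
    dplyr::group_split()

  hits <- purrr::map_dfr(clusters, function(cl) {
    cluster_to_hit(cl, model, k, contig, nchar(genome))
  })
  if (nrow(hits) == 0) return(empty_hits())
  hits <- hits |>
    dplyr::filter(.data$score >= min_seeds,
                  (.data$end - .data$start) >= min_internal_len |
                    .data$has_ltr) |>
    dplyr::mutate(solo_ltr = .data$has_ltr & !.data$has_internal) |>
    dplyr::arrange(.data$start) |>
    dplyr::select("contig", "start", "end", "strand", "score",
                  "matched_parts", "solo_ltr")

  merge_overlapping_hits(hits)
}

# One seed cluster -> one hit, with seed-and-extend boundary refinement.
# Divergence erodes the outermost exact seeds, so raw cluster bounds sit
# inside the true element; the edge positions are recovered by diagonal
# voting. On the plus strand a seed on diagonal d = gpos - ref_pos implies
# element start d (and end d + reference length when read through the 3' LTR
# copy of the k-mer); on the minus strand q = gpos + ref_pos + k - 2 plays the
# same role mirrored. The dominant diagonal among seeds at each physical edge
# of the cluster gives the boundary; clusters without LTR-anchored edge seeds
# keep their raw bounds.
cluster_to_hit <- function(cl, model, k, contig, genome_len) {
  ltr_len <- model$ltr_len
  int_end <- ltr_len + model$internal_len
  ref_len <- nchar(model$provirus)
  strand <- cl$strand[1]
  raw_start <- min(cl$gpos) - 1L
  raw_end <- as.integer(max(cl$gpos) + k - 1L)
  left_zone <- cl$gpos <= min(cl$gpos) + 2L * ltr_len
  right_zone <- cl$gpos >= max(cl$gpos) - 2L * ltr_len
  vote <- function(x, min_votes = 3L) {
    if (length(x) < min_votes) return(NA_integer_)
    tab <- table(x)
    if (max(tab) < min_votes) return(NA_integer_)
    as.integer(names(tab)[which.max(tab)])
  }
  if (strand == "+") {
    d <- cl$gpos - cl$ref_pos
    s_est <- vote(d[cl$ref_pos <= ltr_len & left_zone])
    e_est <- vote(d[cl$ref_pos > int_end & right_zone])
    start <- if (is.na(s_est)) raw_start else s_est
    end <- if (is.na(e_est)) raw_end else e_est + ref_len
  } else {
    q <- cl$gpos + cl$ref_pos + k - 2L
    e_est <- vote(q[cl$ref_pos <= ltr_len & right_zone])
    s_est <- vote(q[cl$ref_pos > int_end & left_zone])
    start <- if (is.na(s_est)) raw_start else s_est - ref_len
    end <- if (is.na(e_est)) raw_end else e_est
  }
  start <- max(0L, min(start, raw_start))
  end <- min(genome_len, max(end, raw_end))
  tibble(
    contig = contig, start = as.integer(start), end = as.integer(end),
    strand = strand, score = dplyr::n_distinct(cl$gpos),
    has_ltr = any(cl$part %in% c("LTR5", "LTR3")),
    has_internal = any(cl$part == "internal"),
    matched_parts = paste(sort(unique(cl$part[cl$part != "junction"])),
                          collapse = ",")
  )
}

empty_hits <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         strand = character(), score = integer(), matched_parts = character(),
         solo_ltr = logical())
}

# Hits overlapping by >= 1 bp after strand-wise chaining are unioned
# (leftmost start wins ties; strand taken from the higher-scoring hit).
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  hits <- hits |> dplyr::arrange(.data$start, .data$end)
  out <- list(hits[1, ])
  for (i in 2:nrow(hits)) {
    cur <- out[[length(out)]]
    nxt <- hits[i, ]
    if (nxt$start < cur$end) {
      cur$end <- max(cur$end, nxt$end)
      if (nxt$score > cur$score) cur$strand <- nxt$strand
      cur$score <- cur$score + nxt$score
      parts <- union(strsplit(cur$matched_parts, ",")[[1]],
                     strsplit(nxt$matched_parts, ",")[[1]])
      cur$matched_parts <- paste(sort(parts), collapse = ",")
      cur$solo_ltr <- any(c("LTR5", "LTR3") %in% parts) && !("internal" %in% parts)
      out[[length(out)]] <- cur
    } else {
      out[[length(out) + 1L]] <- nxt
    }
  }
  dplyr::bind_rows(out)
}

#' Extract a discovered locus sequence (plus-strand)
#'
#' @param genome Genome string.
#' @param hit One row of a [scan_genome()] hit table.
#' @return The locus sequence; reverse-complemented for minus-strand hits.
#' @export
extract_hit <- function(genome, hit) {
  s <- extract_iv(genome, hit$start, hit$end)
  if (hit$strand == "-") revcomp(s) else s
}

flank_identity <- function(fa, fb, threshold = 0.9) {
  # fast path: equal-length ungapped comparison; orthologous flanks that pass
  # it need no alignment. Otherwise align globally and score end-gap-free
  # identity: hit boundaries are only seed-accurate, so the two windows can be
  # offset by a few bases, and the resulting terminal overhangs reflect
  # boundary uncertainty rather than sequence divergence.
  if (nchar(fa) == nchar(fb)) {
    ua <- mean(seq_chars(fa) == seq_chars(fb))
    if (ua >= threshold) return(ua)
  }
  aln <- global_align(fa, fb)
  ca <- seq_chars(aln$a)
  cb <- seq_chars(aln$b)
  gap <- ca == "-" | cb == "-"
  inner <- which(!gap)
  if (length(inner) == 0) return(0)
  keep <- inner[1]:inner[length(inner)]
  mean(ca[keep] == cb[keep] & ca[keep] != "-")
}

#' Classify cross-species orthology of discovered loci from their flanks
#'
#' Loci from different species whose upstream and downstream flanking
#' sequences both align at `min_flank_identity` or better are grouped as
#' orthologs (symmetric/transitive closure). Groups containing the outgroup
#' species are `human_shared`; groups spanning at least two non-outgroup
#' species are `macaque_shared`; singleton-species loci are
#' `species_specific`. Loci whose flank would run off the contig are flagged
#' `unclassifiable`.
#'
#' @param hits_by_species Named list (species -> hit tibble from
#'   [scan_genome()]).
#' @param genomes Named character vector of genome sequences.
#' @param flank_len Flank length to compare (default 200).
#' @param min_flank_identity Identity threshold (default 0.9).
#' @param outgroup Outgroup species name (default `"human"`).
#' @return A tibble: `species`, `contig`, `start`, `end`, `strand`,
#'   `solo_ltr`, `group_id`, `category`.
#' @export
classify_orthology <- function(hits_by_species, genomes, flank_len = 200,
                               min_flank_identity = 0.9, outgroup = "human") {
  if (length(hits_by_species) < 2) abort("need hits from at least 2 species")
  all_hits <- dplyr::bind_rows(
    purrr::imap(hits_by_species, function(h, sp) dplyr::mutate(h, species = sp))
  )
  n <- nrow(all_hits)
  all_hits$row_id <- seq_len(n)
  up <- character(n)
  down <- character(n)
  classifiable <- logical(n)
  for (i in seq_len(n)) {
    g <- genomes[[all_hits$species[i]]]
    s <- all_hits$start[i]
    e <- all_hits$end[i]
    if (s - flank_len < 0 || e + flank_len > nchar(g)) {
      classifiable[i] <- FALSE
      next
    }
    up[i] <- extract_iv(g, s - flank_len, s)
    down[i] <- extract_iv(g, e, e + flank_len)
    classifiable[i] <- TRUE
  }

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  idx <- which(classifiable)
  sp <- all_hits$species
  for (a_i in seq_along(idx)) {
    i <- idx[a_i]
    for (b_i in seq_len(a_i - 1L)) {
      j <- idx[b_i]
      if (sp[i] == sp[j]) next
      if (find(i) == find(j)) next
      if (flank_identity(up[i], up[j], min_flank_identity) >= min_flank_identity &&
          flank_identity(down[i], down[j], min_flank_identity) >= min_flank_identity) {
        parent[find(i)] <- find(j)
      }
    }
  }
  group <- vapply(seq_len(n), find, integer(1))
  group_species <- tapply(sp, group, function(x) unique(x))
  category <- vapply(seq_len(n), function(i) {
    if (!classifiable[i]) return("unclassifiable")
    gs <- group_species[[as.character(group[i])]]
    if (length(gs) < 2) "species_specific"
    else if (outgroup %in% gs) "human_shared"
    else "macaque_shared"
  }, character(1))

  all_hits |>
    dplyr::mutate(group_id = match(group, sort(unique(group))),
                  category = category) |>
    dplyr::select("species", "contig", "start", "end", "strand", "score",
                  "matched_parts", "solo_ltr", "group_id", "category")
}
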