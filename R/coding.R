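# Residual coding capacity: ORF integrity, domain presence, motif scanning.

#' Assess the ORF integrity of a gene in a projected locus
#'
#' The gene sequence is spliced from the projection (aligned bases plus
#' insertions), translated in the reading frame of the reference gene start
#' (if the 5' end is missing, translation starts at the first present in-frame
#' position). Premature stops are stop codons before the reference terminal
#' stop; the frameshift flag is set when the net indel length within the gene
#' is not a multiple of 3. A gene is intact iff it has no premature stop, no
#' frameshift and at least `min_cov` reference coverage.
#'
#' @param projection An `erv_projection`.
#' @param model An `erv_reference`.
#' @param gene One of `"gag"`, `"pro"`, `"pol"`, `"env"`.
#' @param min_cov Coverage required for intactness (default 0.95).
#' @return A one-row tibble: `locus_id`, `gene`, `intact`, `premature_stops`,
#'   `frameshift`, `coverage`, `protein_length`, `domains_present`,
#'   `n_zinc_knuckle`, `nls`, `nes`.
#' @export
orf_integrity <- function(projection, model, gene, min_cov = 0.95) {
  s <- region_span(model, gene)
  pos <- (s$start + 1L):s$end
  bases <- projection$matched[pos]
  coverage <- mean(bases != "-")
  if (coverage == 0) {
    return(tibble(
      locus_id = projection$locus_id, gene = gene, intact = FALSE,
      premature_stops = NA_integer_, frameshift = NA, coverage = 0,
      protein_length = 0L, domains_present = "", n_zinc_knuckle = 0L,
      nls = FALSE, nes = FALSE
    ))
  }
  # frame offset: first present reference position, snapped to the gene frame
  first_present <- which(bases != "-")[1]
  skip <- (3L - ((first_present - 1L) %% 3L)) %% 3L
  gseq <- projected_region_seq_from(projection, model, gene, first_present + skip)
  aa <- translate_dna(gseq)
  aa_chars <- seq_chars(aa)
  n_aa <- length(aa_chars)
  premature <- if (n_aa > 1) sum(aa_chars[-n_aa] == "*") else 0L

  indels <- call_indels(projection, model)
  in_gene <- indels$ref_start > s$start & indels$ref_start <= s$end
  net <- sum(ifelse(indels$kind[in_gene] == "insertion",
                    indels$length[in_gene], -indels$length[in_gene]))
  frameshift <- (net %% 3L) != 0L

  doms <- domain_presence(projection, model, gene)
  motifs <- scan_motifs(aa, model)
  tibble(
    locus_id = projection$locus_id, gene = gene,
    intact = premature == 0L && !frameshift && coverage >= min_cov,
    premature_stops = as.integer(premature), frameshift = frameshift,
    coverage = coverage, protein_length = n_aa,
    domains_present = paste(doms, collapse = ","),
    n_zinc_knuckle = sum(motifs$motif == "zinc_knuckle"),
    nls = any(motifs$motif == "NLS"), nes = any(motifs$motif == "NES")
  )
}

# splice the projected gene sequence starting at a given in-frame reference
# offset within the gene span
projected_region_seq_from <- function(projection, model, gene, from_rel) {
  s <- region_span(model, gene)
  start1 <- s$start + from_rel
  pos <- start1:s$end
  bases <- projection$matched[pos]
  ins <- projection$ins[projection$ins$anchor >= start1 &
                          projection$ins$anchor < s$end, , drop = FALSE]
  if (nrow(ins) == 0) return(chars_seq(bases[bases != "-"]))
  out <- character(0)
  prev <- start1 - 1L
  ins <- ins[order(ins$anchor), ]
  for (k in seq_len(nrow(ins))) {
    seg <- projection$matched[(prev + 1L):ins$anchor[k]]
    out <- c(out, seg[seg != "-"], seq_chars(ins$seq[k]))
    prev <- ins$anchor[k]
  }
  seg <- projection$matched[(prev + 1L):s$end]
  chars_seq(c(out, seg[seg != "-"]))
}

#' Scan a protein for retroviral motifs
#'
#' Finds zinc knuckles (the nucleocapsid CX2CX4HX4C pattern; overlapping
#' matches allowed) and the NLS/NES peptides recorded in the reference model.
#' The NLS/NES peptides are matched with up to one mismatched residue per
#' four (2 for the 8-aa NLS, 3 for the 12-aa NES), since a neutral
#' substitution should not abolish a signal a motif scanner would still call.
#'
#' @param protein Amino-acid string (may contain `*` and `X`).
#' @param model An `erv_reference` (supplies the NLS/NES peptides). If `NULL`,
#'   only zinc knuckles are scanned.
#' @return A tibble: `motif`, `position` (1-based aa), `match`.
#' @export
scan_motifs <- function(protein, model = NULL) {
  out <- list()
  zk <- gregexpr("(?=(C.{2}C.{4}H.{4}C))", protein, perl = TRUE)[[1]]
  if (zk[1] != -1) {
    out[[1]] <- tibble(motif = "zinc_knuckle", position = as.integer(zk),
                       match = substring(protein, zk, zk + 13L))
  }
  if (!is.null(model)) {
    chars <- seq_chars(protein)
    for (nm in c("NLS", "NES")) {
      pep <- seq_chars(model$motif_peptides[[nm]])
      L <- length(pep)
      max_sub <- L %/% 4L
      n <- length(chars)
      if (n < L) next
      hits <- integer(0)
      for (i in seq_len(n - L + 1L)) {
        if (sum(chars[i:(i + L - 1L)] != pep) <= max_sub) hits <- c(hits, i)
      }
      if (length(hits) > 0) {
        out[[length(out) + 1L]] <- tibble(
          motif = nm, position = hits,
          match = vapply(hits, function(i) chars_seq(chars[i:(i + L - 1L)]),
                         character(1)))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(motif = character(), position = integer(), match = character()))
  }
  dplyr::bind_rows(out)
}

#' Which of a gene's domains are present in a projected locus
#'
#' A domain is present iff at least `min_cov` of its reference span is covered
#' by aligned locus bases.
#'
#' @param projection An `erv_projection`.
#' @param model An `erv_reference`.
#' @param gene Gene name.
#' @param min_cov Coverage threshold (default 0.9).
#' @return Character vector of present domain names.
#' @export
domain_presence <- function(projection, model, gene, min_cov = 0.9) {
  doms <- model$domains[model$domains$gene == gene, ]
  present <- vapply(seq_len(nrow(doms)), function(k) {
    pos <- (doms$start[k] + 1L):doms$end[k]
    mean(projection$matched[pos] != "-") >= min_cov
  }, logical(1))
  doms$name[present]
}

#' Detect an intact Rec coding portion in a projected env
#'
#' Rec is present iff its reference interval is covered at >= 0.95 and is
#' frame-intact (net indel phase 0 inside Rec); point substitutions, including
#' nonsense ones, do not remove the Rec portion structurally. The NLS and NES
#' flags come from scanning the Rec translation.
#'
#' @param projection An `erv_projection`.
#' @param model An `erv_reference`.
#' @return A list: `rec_present`, `nls`, `nes`.
#' @export
detect_rec <- function(projection, model) {
  s <- region_span(model, "Rec")
  pos <- (s$start + 1L):s$end
  bases <- projection$matched[pos]
  coverage <- mean(bases != "-")
  if (coverage < 0.95) return(list(rec_present = FALSE, nls = FALSE, nes = FALSE))
  indels <- call_indels(projection, model)
  in_rec <- indels$ref_start > s$start & indels$ref_start <= s$end
  net <- sum(ifelse(indels$kind[in_rec] == "insertion",
                    indels$length[in_rec], -indels$length[in_rec]))
  rec_present <- (net %% 3L) == 0L
  aa <- translate_dna(projected_region_seq(projection, model, "Rec"))
  motifs <- scan_motifs(aa, model)
  list(rec_present = rec_present,
       nls = rec_present && any(motifs$motif == "NLS"),
       nes = rec_present && any(motifs$motif == "NES"))
}
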