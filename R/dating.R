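# Integration-time estimation from nucleotide divergence.
#
# T = D% / 0.34, where 0.34 is the primate substitution rate in
# %/nucleotide/Myr; for LTR-vs-LTR comparisons T is further halved because the
# two LTR copies accumulate mutations independently after integration.

RATE_PCT_PER_MYR <- 0.34

#' Proportion of differing sites between two aligned sequences
#'
#' Computes the p-distance with pairwise deletion: positions where either
#' sequence has a gap or `N` are excluded from the compared-site count. With
#' `mask_cpg = TRUE`, positions that are part of a CG dinucleotide in either
#' sequence (on the aligned strings) are additionally excluded, removing the
#' hypermutable methyl-CpG signal.
#'
#' @param a,b Aligned DNA strings of equal length (gaps as `-`).
#' @param mask_cpg Exclude CpG positions (default `TRUE`).
#' @return A list with `D` (mismatch fraction) and `sites` (compared sites).
#' @export
p_distance <- function(a, b, mask_cpg = TRUE) {
  ca <- if (length(a) > 1) a else seq_chars(a)
  cb <- if (length(b) > 1) b else seq_chars(b)
  if (length(ca) != length(cb)) abort("aligned lengths differ")
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (mask_cpg) {
    n <- length(ca)
    cpg <- rep(FALSE, n)
    if (n >= 2) {
      i <- seq_len(n - 1L)
      hit <- (ca[i] == "C" & ca[i + 1L] == "G") | (cb[i] == "C" & cb[i + 1L] == "G")
      cpg[i][hit] <- TRUE
      cpg[i + 1L][hit] <- TRUE
    }
    ok <- ok & !cpg
  }
  sites <- sum(ok)
  if (sites == 0) abort("no comparable sites")
  list(D = sum(ca[ok] != cb[ok]) / sites, sites = as.integer(sites))
}

divergence_to_age <- function(D, method) {
  T <- (D * 100) / RATE_PCT_PER_MYR
  if (method == "ltr_vs_ltr") T <- T / 2
  T
}

#' Estimate the integration time of a locus
#'
#' Four estimators are supported: `ltr_vs_ltr` (divergence between the
#' locus's own 5' and 3' LTR, halved because each copy mutates independently),
#' `ltr_vs_consensus`, `gag_vs_consensus` and `pol_vs_consensus` (divergence
#' of the named part from a consensus standing in for the ancestral state).
#' Divergence is the CpG-masked p-distance with pairwise deletion, and
#' T = D% / 0.34 Myr.
#'
#' @param locus An `erv_locus`, or a list with the required part sequences
#'   (`ltr5`/`ltr3` or the gene named by the method).
#' @param model An `erv_reference`.
#' @param method One of `"ltr_vs_ltr"`, `"ltr_vs_consensus"`,
#'   `"gag_vs_consensus"`, `"pol_vs_consensus"`.
#' @param consensus Consensus sequence (required for consensus methods).
#' @param mask_cpg Exclude CpG positions (default `TRUE`).
#' @return A one-row tibble: `locus_id`, `method`, `D`, `sites`, `T`.
#' @export
estimate_age <- function(locus, model, method = "ltr_vs_ltr", consensus = NULL,
                         mask_cpg = TRUE) {
  method <- match.arg(method, c("ltr_vs_ltr", "ltr_vs_consensus",
                                "gag_vs_consensus", "pol_vs_consensus"))
  parts <- locus_part_seqs(locus, model)
  if (method == "ltr_vs_ltr") {
    if (is.null(parts$ltr3) || isTRUE(locus$solo_ltr)) {
      abort("method unavailable: locus lacks two LTRs (solo LTR?)")
    }
    aln <- global_align(parts$ltr5, parts$ltr3)
  } else {
    if (is.null(consensus)) abort("consensus sequence required")
    part <- switch(method,
      ltr_vs_consensus = parts$ltr5 %||% parts$ltr3,
      gag_vs_consensus = parts$gag,
      pol_vs_consensus = parts$pol)
    if (is.null(part) || nchar(part) == 0) {
      abort(sprintf("method unavailable: locus lacks the %s part", method))
    }
    aln <- global_align(gsub("-", "", consensus, fixed = TRUE), part)
  }
  pd <- p_distance(aln$a, aln$b, mask_cpg = mask_cpg)
  tibble(
    locus_id = if (is.list(locus) && !is.null(locus$id)) locus$id else NA_character_,
    method = method, D = pd$D, sites = pd$sites,
    T = divergence_to_age(pd$D, method)
  )
}

# Part sequences from either a simulated erv_locus (anchor truth) or a list
# carrying explicit part sequences / a projection.
locus_part_seqs <- function(locus, model) {
  if (inherits(locus, "erv_locus")) {
    parts <- list(
      ltr5 = locus_true_region(locus, model, "LTR5"),
      ltr3 = locus_true_region(locus, model, "LTR3"),
      gag = locus_true_region(locus, model, "gag"),
      pol = locus_true_region(locus, model, "pol")
    )
    return(lapply(parts, function(s) if (nchar(s) == 0) NULL else s))
  }
  if (inherits(locus, "erv_projection")) {
    parts <- list(
      ltr5 = projected_region_seq(locus, model, "LTR5"),
      ltr3 = projected_region_seq(locus, model, "LTR3"),
      gag = projected_region_seq(locus, model, "gag"),
      pol = projected_region_seq(locus, model, "pol")
    )
    return(lapply(parts, function(s) if (nchar(s) == 0) NULL else s))
  }
  if (is.list(locus)) return(locus)
  abort("unsupported locus object")
}

#' Build a consensus sequence over a cluster of projected loci
#'
#' Per reference column: the plurality base among non-gap members, with ties
#' broken toward the reference base; columns gapped in more than half of the
#' members are emitted as gaps.
#'
#' @param projections A list of `erv_projection` over one cluster (>= 2).
#' @param model An `erv_reference`.
#' @param region Region name (default `"LTR5"`, the LTR consensus).
#' @return A DNA string with `-` for consensus gaps.
#' @export
build_consensus <- function(projections, model, region = "LTR5") {
  if (length(projections) == 0) abort("empty cluster")
  s <- region_span(model, region)
  pos <- (s$start + 1L):s$end
  mat <- vapply(projections, function(p) p$matched[pos],
                character(length(pos)))
  mat <- matrix(mat, nrow = length(pos))
  ref <- seq_chars(region_seq(model, region))
  out <- vapply(seq_along(pos), function(i) {
    col <- mat[i, ]
    bases <- col[col %in% DNA_BASES]
    if (length(bases) < length(col) / 2) return("-")
    tab <- table(factor(bases, levels = DNA_BASES))
    best <- names(tab)[tab == max(tab)]
    if (ref[i] %in% best) ref[i] else best[1]
  }, character(1))
  chars_seq(out)
}

#' Summarize age estimates per category
#'
#' Median and quartiles (linear interpolation, quantile type 7) of the
#' estimated integration times, grouped by category.
#'
#' @param estimates A tibble with columns `category` and `T`.
#' @return A tibble: `category`, `n`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_ages <- function(estimates) {
  stopifnot(all(c("category", "T") %in% names(estimates)))
  empty <- estimates |> dplyr::filter(is.na(.data$T))
  if (nrow(empty) > 0) warning(sprintf("%d estimate(s) without T dropped", nrow(empty)))
  estimates |>
    dplyr::filter(!is.na(.data$T)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$T),
      q1 = stats::quantile(.data$T, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$T, 0.75, type = 7, names = FALSE),
      min = min(.data$T),
      max = max(.data$T),
      .groups = "drop"
    )
}
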