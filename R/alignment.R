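# Global alignment and reference-anchored projection.
#
# Every locus is compared to the reference by one affine-gap global alignment
# and then projected into reference coordinate space (a pseudo-MSA over shared
# reference columns), which replaces a true multiple alignment: all downstream
# comparisons are locus-vs-reference or column-wise over reference positions.

#' Affine-gap global alignment (Gotoh)
#'
#' Optimal global alignment with affine gap costs: a gap of length L costs
#' `|gap_open| + L * |gap_extend|`. `N` mismatches everything, including `N`.
#' Traceback tie-breaking is deterministic (match > deletion > insertion).
#'
#' @param a,b DNA strings (`a` is the reference side).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A list with aligned strings `a`, `b` and the `score`.
#' @export
global_align <- function(a, b, match = 2, mismatch = -3,
                         gap_open = -5, gap_extend = -2) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  gotoh_align_cpp(a, b, match, mismatch, abs(gap_open), abs(gap_extend))
}

#' Project a locus onto reference coordinates
#'
#' Globally aligns a locus to the reference provirus and stores, per reference
#' position, the aligned locus base (or a gap), plus an insertion store keyed
#' by the reference anchor position. Projecting the reference onto itself is
#' the identity.
#'
#' @param locus_seq Locus DNA string (plus-strand).
#' @param model An `erv_reference`.
#' @param locus_id Optional identifier carried through reports.
#' @param gap_open,gap_extend Gap penalties for the projection alignment.
#'   The defaults are stiffer than [global_align()]'s general-purpose scores:
#'   a high opening cost keeps each indel in one run instead of splitting it
#'   around chance matches, so called indel lengths stay faithful to the
#'   underlying event.
#' @return An object of class `erv_projection`.
#' @export
project_locus <- function(locus_seq, model, locus_id = NA_character_,
                          gap_open = -12, gap_extend = -1) {
  aln <- global_align(model$provirus, locus_seq,
                      gap_open = gap_open, gap_extend = gap_extend)
  ra <- seq_chars(aln$a)
  rb <- seq_chars(aln$b)
  is_ref <- ra != "-"
  refpos <- cumsum(is_ref)
  matched <- rb[is_ref]
  ins_cols <- which(!is_ref)
  ins <- tibble(anchor = integer(), seq = character())
  if (length(ins_cols) > 0) {
    grp <- cumsum(c(1L, diff(ins_cols) != 1L))
    ins <- tibble(
      anchor = as.integer(tapply(refpos[ins_cols], grp, `[`, 1L)),
      seq = as.character(tapply(rb[ins_cols], grp, paste, collapse = ""))
    )
  }
  structure(list(matched = matched, ins = ins, score = aln$score,
                 locus_id = locus_id, locus_len = nchar(locus_seq)),
            class = "erv_projection")
}

#' @export
print.erv_projection <- function(x, ...) {
  cat(sprintf("<erv_projection> %s: %d/%d reference positions covered, %d insertion run(s)\n",
              x$locus_id %||% "?", sum(x$matched != "-"), length(x$matched),
              nrow(x$ins)))
  invisible(x)
}

#' Call indels from a reference projection
#'
#' Maximal runs of reference positions with no aligned locus base become one
#' deletion each; each insertion run becomes one insertion anchored between
#' reference positions. Events are annotated with the containing region.
#'
#' @param projection An `erv_projection`.
#' @param model An `erv_reference`.
#' @return A tibble with columns `kind`, `ref_start` (1-based reference
#'   position: deletion start, or the position an insertion follows),
#'   `length`, `region`.
#' @export
call_indels <- function(projection, model) {
  gaps <- projection$matched == "-"
  dels <- empty_indels()
  if (any(gaps)) {
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    dels <- tibble(
      kind = "deletion",
      ref_start = as.integer(starts[keep]),
      length = as.integer(r$lengths[keep]),
      region = mapply(function(p, l) region_of_span(model, p, p + l - 1L),
                      starts[keep], r$lengths[keep])
    )
  }
  inss <- empty_indels()
  if (nrow(projection$ins) > 0) {
    inss <- tibble(
      kind = "insertion",
      ref_start = projection$ins$anchor,
      length = nchar(projection$ins$seq),
      region = vapply(projection$ins$anchor,
                      function(p) region_of_position(model, max(p, 1L)),
                      character(1))
    )
  }
  dplyr::bind_rows(dels, inss) |> dplyr::arrange(.data$ref_start)
}

# Splice the projected sequence of a reference span: matched bases plus
# insertions anchored strictly inside the span.
projected_region_seq <- function(projection, model, name) {
  s <- region_span(model, name)
  pos <- (s$start + 1L):s$end
  bases <- projection$matched[pos]
  ins <- projection$ins[projection$ins$anchor >= s$start + 1L &
                          projection$ins$anchor < s$end, , drop = FALSE]
  if (nrow(ins) == 0) return(chars_seq(bases[bases != "-"]))
  out <- character(0)
  prev <- s$start
  ins <- ins[order(ins$anchor), ]
  for (k in seq_len(nrow(ins))) {
    seg <- projection$matched[(prev + 1L):ins$anchor[k]]
    out <- c(out, seg[seg != "-"], seq_chars(ins$seq[k]))
    prev <- ins$anchor[k]
  }
  seg <- projection$matched[(prev + 1L):s$end]
  chars_seq(c(out, seg[seg != "-"]))
}

#' Annotate region completeness of a projected locus
#'
#' Per reference region: fraction of the reference span covered by aligned
#' locus bases, observed length (aligned bases plus internal insertions) and
#' GC fraction. A locus is declared full-length when every gene reaches the
#' coverage threshold.
#'
#' @param projection An `erv_projection`.
#' @param model An `erv_reference`.
#' @param full_len_threshold Per-gene coverage required for the full-length
#'   flag (default 0.8).
#' @return A list of class `erv_annotation` with elements `regions` (tibble:
#'   `region`, `coverage`, `length`, `gc`), `full_length`, `locus_len`.
#' @export
annotate_regions <- function(projection, model, full_len_threshold = 0.8) {
  region_names <- c("LTR5", "gag", "pro", "pol", "env", "LTR3")
  rows <- purrr::map_dfr(region_names, function(nm) {
    s <- region_span(model, nm)
    pos <- (s$start + 1L):s$end
    bases <- projection$matched[pos]
    seq <- projected_region_seq(projection, model, nm)
    tibble(region = nm,
           coverage = mean(bases != "-"),
           length = nchar(seq),
           gc = if (nchar(seq) > 0) gc_content(seq) else NA_real_)
  })
  genes <- rows[rows$region %in% c("gag", "pro", "pol", "env"), ]
  structure(list(
    regions = rows,
    full_length = all(genes$coverage >= full_len_threshold),
    locus_len = projection$locus_len,
    locus_id = projection$locus_id
  ), class = "erv_annotation")
}

#' @export
print.erv_annotation <- function(x, ...) {
  cat(sprintf("<erv_annotation> %s (%d nt, %sfull-length)\n",
              x$locus_id %||% "?", x$locus_len,
              if (x$full_length) "" else "not "))
  print(x$regions)
  invisible(x)
}
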