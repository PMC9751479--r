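# env subtype (I/II) and variant (1/2/3) classification from indel signatures
# and recombination evidence.

#' Classify an env gene into type I/II and variant 1/2/3
#'
#' Rule order (variant): (1) a recombination segmentation showing a parent-B
#' (MER11A) segment of at least `min_b_len` nt inside env calls variant 3;
#' (2) otherwise an insertion of 150-250 nt inside the TM domain calls
#' variant 2; (3) otherwise variant 1. The MER11A replacement destroys the
#' other signals' context, hence its precedence. Type: a deletion of
#' 280-300 nt at the type-I anchor calls type I, else type II. Conflicting
#' evidence (both a type-I deletion and a MER11A segment) is resolved by rule
#' order and flagged in the evidence.
#'
#' @param indels Indel tibble (from [call_indels()]) for one locus.
#' @param model An `erv_reference`.
#' @param recomb Optional `erv_segmentation` of the env against
#'   (reference env, MER11A).
#' @param env_present Set `FALSE` when the locus has no env (returns
#'   undetermined/undetermined).
#' @param min_b_len Minimum parent-B segment length for variant 3 (default 300).
#' @param anchor_tol Tolerance around the type-I deletion anchor (default 20 nt).
#' @return A one-row tibble: `type`, `variant`, `evidence`.
#' @export
classify_env <- function(indels, model, recomb = NULL, env_present = TRUE,
                         min_b_len = 300, anchor_tol = 20) {
  if (!env_present) {
    return(tibble(type = "undetermined", variant = "undetermined",
                  evidence = "env absent"))
  }
  env <- region_span(model, "env")
  tm <- region_span(model, "TM")
  in_env <- indels$ref_start > env$start & indels$ref_start <= env$end
  env_indels <- indels[in_env, , drop = FALSE]
  evidence <- character(0)

  b_len <- 0L
  if (!is.null(recomb)) {
    segs <- recomb$segments
    b_segs <- segs[segs$parent == "B", , drop = FALSE]
    if (nrow(b_segs) > 0) b_len <- max(b_segs$length)
  }

  ins_tm <- env_indels$kind == "insertion" &
    env_indels$length >= 150 & env_indels$length <= 250 &
    env_indels$ref_start > tm$start & env_indels$ref_start <= tm$end

  t1 <- model$signature$type1_del
  del_t1 <- env_indels$kind == "deletion" &
    env_indels$length >= 280 & env_indels$length <= 300 &
    abs(env_indels$ref_start - (t1$start + 1L)) <= anchor_tol

  if (b_len >= min_b_len) {
    variant <- "3"
    evidence <- c(evidence, sprintf("MER11A segment %d nt", b_len))
    if (any(del_t1)) evidence <- c(evidence, "conflict: type-I deletion also present")
  } else if (any(ins_tm)) {
    variant <- "2"
    evidence <- c(evidence, sprintf("TM insertion %d nt",
                                    env_indels$length[ins_tm][1]))
  } else {
    variant <- "1"
  }

  if (any(del_t1)) {
    type <- "I"
    evidence <- c(evidence, sprintf("env deletion %d nt at type-I anchor",
                                    env_indels$length[del_t1][1]))
  } else {
    type <- "II"
  }

  tibble(type = type, variant = variant,
         evidence = if (length(evidence) == 0) "reference-like env" else
           paste(evidence, collapse = "; "))
}
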