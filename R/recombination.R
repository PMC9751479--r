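# Two-parent recombination detection by minimal-mismatch segmentation.
#
# Each parent is globally aligned to the query; per query position the cost of
# assigning that position to a parent is 0 if the aligned parent base matches
# and 1 otherwise (a gap counts as a mismatch). The optimal parent-label path
# minimizes total mismatch cost plus sigma per label switch (a 2-state DP).

# Per-query-position mismatch cost of one parent. The parent alignment uses
# stiff gap penalties (one long gap is fine, scattered short gaps are not):
# with permissive gaps the aligner stitches chance matches inside non-parental
# segments, which blurs the mismatch signal the segmentation DP relies on.
parent_cost <- function(query, parent, gap_open = -12, gap_extend = -1) {
  aln <- global_align(query, parent, gap_open = gap_open,
                      gap_extend = gap_extend)
  cq <- seq_chars(aln$a)
  cp <- seq_chars(aln$b)
  is_q <- cq != "-"
  cost <- as.integer(cq[is_q] != cp[is_q] | cp[is_q] == "-")
  cost
}

#' Segment a query between two parents by minimal-mismatch DP
#'
#' Labels every query position with the parent (`A` or `B`) it locally
#' matches, with a switch penalty `sigma`; the returned label path has minimal
#' total cost (mismatches to the active parent plus `sigma` per switch).
#' Breakpoints falling in runs of label-indifferent positions (equal cost to
#' both parents) are reported at the midpoint of the ambiguous run, with the
#' run as an interval.
#'
#' @param query,parentA,parentB DNA strings.
#' @param sigma Switch penalty (default 3).
#' @return An object of class `erv_segmentation`: `labels` (per-position),
#'   `segments` (tibble: `parent`, `start`, `end`, `length`; 1-based inclusive
#'   query coordinates), `breakpoints` (tibble: `position`, `lo`, `hi`),
#'   `cost`, `sigma`.
#' @export
segment_two_parents <- function(query, parentA, parentB, sigma = 3) {
  if (sigma < 0) abort("sigma must be >= 0")
  stopifnot(nchar(query) > 0, nchar(parentA) > 0, nchar(parentB) > 0)
  cA <- parent_cost(query, parentA)
  cB <- parent_cost(query, parentB)
  n <- length(cA)

  # forward DP; ties prefer staying on the current parent, then parent A
  fA <- numeric(n); fB <- numeric(n)
  fA[1] <- cA[1]; fB[1] <- cB[1]
  if (n >= 2) for (i in 2:n) {
    fA[i] <- cA[i] + min(fA[i - 1], fB[i - 1] + sigma)
    fB[i] <- cB[i] + min(fB[i - 1], fA[i - 1] + sigma)
  }
  cost <- min(fA[n], fB[n])

  # backward DP (cost of labeling i..n with the given label at i)
  bA <- numeric(n); bB <- numeric(n)
  bA[n] <- cA[n]; bB[n] <- cB[n]
  if (n >= 2) for (i in (n - 1):1) {
    bA[i] <- cA[i] + min(bA[i + 1], bB[i + 1] + sigma)
    bB[i] <- cB[i] + min(bB[i + 1], bA[i + 1] + sigma)
  }

  labels <- character(n)
  state <- if (fA[n] <= fB[n]) "A" else "B"
  labels[n] <- state
  if (n >= 2) for (i in n:2) {
    if (state == "A") {
      state <- if (fA[i - 1] <= fB[i - 1] + sigma) "A" else "B"
    } else {
      state <- if (fB[i - 1] <= fA[i - 1] + sigma) "B" else "A"
    }
    labels[i - 1] <- state
  }

  segments <- labels_to_segments(labels)
  # Breakpoint ambiguity: a switch p->q placed after position j is optimal iff
  # f_p[j] + sigma + b_q[j+1] equals the optimal cost; report the midpoint of
  # the maximal run of such j around the traceback's choice.
  breakpoints <- tibble(position = integer(), lo = integer(), hi = integer())
  if (nrow(segments) > 1) {
    bps <- purrr::map_dfr(seq_len(nrow(segments) - 1L), function(k) {
      p <- segments$parent[k]
      q <- segments$parent[k + 1L]
      i <- segments$end[k]
      fs <- if (p == "A") fA else fB
      bs <- if (q == "A") bA else bB
      j <- seq_len(n - 1L)
      opt <- abs(fs[j] + sigma + bs[j + 1L] - cost) < 1e-9
      lo <- i
      while (lo > 1 && opt[lo - 1L]) lo <- lo - 1L
      hi <- i
      while (hi < n - 1L && opt[hi + 1L]) hi <- hi + 1L
      tibble(position = as.integer(floor((lo + hi) / 2)),
             lo = as.integer(lo), hi = as.integer(hi))
    })
    # re-centre segment bounds on the ambiguity midpoints
    for (k in seq_len(nrow(segments) - 1L)) {
      segments$end[k] <- bps$position[k]
      segments$start[k + 1L] <- bps$position[k] + 1L
    }
    segments$length <- segments$end - segments$start + 1L
    breakpoints <- bps
  }
  structure(list(labels = labels, segments = segments,
                 breakpoints = breakpoints, cost = cost, sigma = sigma,
                 n = n),
            class = "erv_segmentation")
}

labels_to_segments <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(parent = r$values, start = starts, end = ends, length = r$lengths)
}

# A breakpoint between positions i and i+1 can slide freely across a run of
# positions where both parents cost the same; report the midpoint of that run.
locate_breakpoints <- function(labels, cA, cB) {
  switches <- which(labels[-length(labels)] != labels[-1])
  if (length(switches) == 0) {
    return(tibble(position = integer(), lo = integer(), hi = integer()))
  }
  tie <- cA == cB
  purrr::map_dfr(switches, function(i) {
    lo <- i
    while (lo > 1 && tie[lo]) lo <- lo - 1L
    hi <- i + 1L
    while (hi < length(labels) && tie[hi]) hi <- hi + 1L
    # [lo, hi-1] are the candidate split points
    tibble(position = as.integer(floor((lo + hi - 1) / 2)),
           lo = as.integer(lo), hi = as.integer(hi - 1L))
  })
}

#' @export
print.erv_segmentation <- function(x, ...) {
  cat(sprintf("<erv_segmentation> %d nt, cost %.1f (sigma %.1f), %d segment(s)\n",
              x$n, x$cost, x$sigma, nrow(x$segments)))
  print(x$segments)
  invisible(x)
}

#' @export
tidy.erv_segmentation <- function(x, ...) {
  x$segments
}

#' Exhaustive segmentation oracle (up to two breakpoints)
#'
#' Enumerates every parent labeling with at most `max_breakpoints` switches
#' and returns the minimum-cost segmentation. Used to verify
#' [segment_two_parents()]; refuses queries longer than 1,000 nt.
#'
#' @inheritParams segment_two_parents
#' @param max_breakpoints 0, 1 or 2.
#' @return An `erv_segmentation`.
#' @export
oracle_segment <- function(query, parentA, parentB, sigma = 3,
                           max_breakpoints = 2) {
  if (nchar(query) > 1000) abort("oracle limited to queries <= 1000 nt")
  stopifnot(max_breakpoints %in% 0:2)
  cA <- parent_cost(query, parentA)
  cB <- parent_cost(query, parentB)
  n <- length(cA)
  SA <- c(0, cumsum(cA))
  SB <- c(0, cumsum(cB))
  seg_cost <- function(parent, from, to) {
    if (parent == "A") SA[to + 1] - SA[from] else SB[to + 1] - SB[from]
  }
  best <- NULL
  consider <- function(bounds, parents) {
    k <- length(parents)
    cost <- sigma * (k - 1)
    for (j in seq_len(k)) {
      cost <- cost + seg_cost(parents[j], bounds[j] + 1L, bounds[j + 1L])
    }
    if (is.null(best) || cost < best$cost) {
      best <<- list(cost = cost, bounds = bounds, parents = parents)
    }
  }
  for (p in c("A", "B")) consider(c(0L, n), p)
  if (max_breakpoints >= 1 && n >= 2) {
    for (b in 1:(n - 1L)) {
      consider(c(0L, b, n), c("A", "B"))
      consider(c(0L, b, n), c("B", "A"))
    }
  }
  if (max_breakpoints >= 2 && n >= 3) {
    # vectorized over the second breakpoint for speed
    for (b1 in 1:(n - 2L)) {
      b2 <- (b1 + 1L):(n - 1L)
      for (parents in list(c("A", "B", "A"), c("B", "A", "B"))) {
        p1 <- parents[1]; p2 <- parents[2]; p3 <- parents[3]
        c1 <- seg_cost(p1, 1L, b1)
        c2 <- if (p2 == "A") SA[b2 + 1] - SA[b1 + 1] else SB[b2 + 1] - SB[b1 + 1]
        c3 <- if (p3 == "A") SA[n + 1] - SA[b2 + 1] else SB[n + 1] - SB[b2 + 1]
        tot <- c1 + c2 + c3 + 2 * sigma
        j <- which.min(tot)
        if (is.null(best) || tot[j] < best$cost) {
          best <- list(cost = tot[j], bounds = c(0L, b1, b2[j], n),
                       parents = parents)
        }
      }
    }
  }
  labels <- character(n)
  for (j in seq_along(best$parents)) {
    labels[(best$bounds[j] + 1L):best$bounds[j + 1L]] <- best$parents[j]
  }
  structure(list(labels = labels, segments = labels_to_segments(labels),
                 breakpoints = locate_breakpoints(labels, cA, cB),
                 cost = best$cost, sigma = sigma, n = n),
            class = "erv_segmentation")
}
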