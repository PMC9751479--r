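# Synthetic reference-provirus model: an HML2-like provirus with the published
# region layout (LTR5 - internal - LTR3; gag/pro/pol/env with overlapping
# reading frames), nucleocapsid zinc-knuckle motifs, and Rec NLS/NES peptides.

LTR_LEN <- 968L
INTERNAL_LEN <- 8000L

# Published internal-relative 1-based inclusive gene coordinates.
PAPER_REGIONS <- list(
  gag = c(156L, 2297L),
  pro = c(2063L, 3082L),
  pol = c(3037L, 5785L),
  env = c(5624L, 7951L)
)

# Domain layout (internal-relative 1-based), chosen to nest inside the genes:
# matrix/capsid/nucleocapsid in gag, RT/RNaseH/integrase in pol, SU/TM and the
# Rec coding portion (with NLS and NES) in env.
PAPER_DOMAINS <- tibble::tribble(
  ~name, ~gene, ~p1,    ~p2,
  "MA",  "gag", 156L,  455L,
  "CA",  "gag", 603L,  1415L,
  "NC",  "gag", 1803L, 2255L,
  "RT",  "pol", 3037L, 3936L,
  "RH",  "pol", 3994L, 4296L,
  "IN",  "pol", 4384L, 5226L,
  "SU",  "env", 5624L, 7003L,
  "TM",  "env", 7016L, 7933L,
  "Rec", "env", 5924L, 6523L
)

# Fixed motif peptides (recorded in the model so scanning is well-defined).
ZN_PEPTIDE <- "CKTCNAEKHLAWTC" # matches CX2CX4HX4C
NLS_PEPTIDE <- "RKKRRKQR"
NES_PEPTIDE <- "LQLPPLERLTLD"

# CpG-free codon encodings of the motif peptides.
CODON_TABLE <- c(
  C = "TGT", K = "AAA", T = "ACA", N = "AAT", A = "GCA", E = "GAA",
  H = "CAT", L = "CTT", W = "TGG", R = "AGA", Q = "CAA", P = "CCA",
  D = "GAT", G = "GGA", S = "TCA", I = "ATT", V = "GTT", F = "TTT",
  M = "ATG", Y = "TAT"
)

encode_peptide <- function(pep) {
  seq_chars(paste(unname(CODON_TABLE[seq_chars(pep)]), collapse = ""))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_dna <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n == 0) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  chars_seq(unname(aa))
}

# Markov sampler of neutral DNA; cpg_free forbids G after C, with base weights
# tuned so overall GC stays near the target despite the exclusion.
sample_dna <- function(n, gc = 0.41, cpg_free = TRUE) {
  if (n == 0) return("")
  if (!cpg_free) {
    at <- (1 - gc) / 2
    return(chars_seq(sample(DNA_BASES, n, TRUE,
                            prob = c(at, gc / 2, gc / 2, at))))
  }
  pr_nc <- c(A = 0.260, C = 0.205, G = 0.258, T = 0.277)
  pr_c <- c(A = 0.370, C = 0.205, G = 0, T = 0.425)
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    p <- if (identical(prev, "C")) pr_c else pr_nc
    out[i] <- sample(DNA_BASES, 1L, prob = p)
    prev <- out[i]
  }
  chars_seq(out)
}

# Internal-relative 1-based position -> provirus 0-based index helpers.
int1_to_prov0 <- function(p) LTR_LEN + p - 1L
prov0_to_int1 <- function(p) p - LTR_LEN + 1L

gene_codon_starts <- function(gene) {
  # internal-relative 1-based codon start positions, terminal stop excluded
  r <- PAPER_REGIONS[[gene]]
  n_codon <- (r[2] - r[1] + 1L) %/% 3L
  r[1] + 3L * (seq_len(n_codon) - 1L)
}

gene_terminal_stop <- function(gene) {
  s <- gene_codon_starts(gene)
  s[length(s)]
}

creates_cpg <- function(chars, pos, base) {
  left <- if (pos > 1) chars[pos - 1] else ""
  right <- if (pos < length(chars)) chars[pos + 1] else ""
  (base == "G" && left == "C") || (base == "C" && right == "G")
}

# Remove premature stop codons from every gene frame (including overlap
# regions, where two frames constrain the same bases) by single-base edits
# that are CpG-safe and do not touch protected motif/terminal-stop positions.
repair_stops <- function(chars, protected, cpg_free, max_iter = 400) {
  genes <- names(PAPER_REGIONS)
  codon_at <- function(chars, s) chars_seq(chars[s:(s + 2L)])
  find_stops <- function(chars) {
    out <- integer(0)
    for (g in genes) {
      ss <- gene_codon_starts(g)
      ss <- ss[ss != gene_terminal_stop(g)]
      starts3 <- chars[ss]
      cand <- ss[starts3 == "T"]
      for (s in cand) {
        if (codon_at(chars, s) %in% STOP_CODONS) out <- c(out, s)
      }
    }
    sort(unique(out))
  }
  in_some_stop <- function(chars, p) {
    for (g in genes) {
      r <- PAPER_REGIONS[[g]]
      if (p < r[1] || p > r[2]) next
      s <- r[1] + 3L * ((p - r[1]) %/% 3L)
      if (s + 2L > r[2]) next
      if (s == gene_terminal_stop(g)) next
      if (codon_at(chars, s) %in% STOP_CODONS) return(TRUE)
    }
    FALSE
  }
  for (iter in seq_len(max_iter)) {
    stops <- find_stops(chars)
    if (length(stops) == 0) return(chars)
    fixed <- FALSE
    for (s in stops) {
      for (off in 0:2) {
        p <- s + off
        if (protected[p]) next
        for (base in setdiff(DNA_BASES, chars[p])) {
          if (cpg_free && creates_cpg(chars, p, base)) next
          old <- chars[p]
          chars[p] <- base
          if (!in_some_stop(chars, p)) { fixed <- TRUE; break }
          chars[p] <- old
        }
        if (fixed) break
      }
      if (fixed) break
    }
    if (!fixed) return(NULL)
  }
  NULL
}

#' Build the synthetic reference-provirus model
#'
#' Constructs a deterministic HML2-like reference: a 968-nt LTR, an 8,000-nt
#' internal region annotated with the published gene layout (gag 156-2,297,
#' pro 2,063-3,082, pol 3,037-5,785, env 5,624-7,951; internal-relative,
#' 1-based), nested domains (MA/CA/NC, RT/RH/IN, SU/TM, Rec with NLS and NES),
#' two zinc-knuckle motifs in the nucleocapsid, and the recurrent signature
#' indel elements used by the cohort simulator. All gene reading frames
#' (including the gag/pro, pro/pol and pol/env overlaps) are stop-free up to
#' the terminal stop codon.
#'
#' By default the sequence is CpG-free, so that CpG masking during dating is
#' exactly neutral on simulated data; set `cpg_free = FALSE` to obtain a
#' reference with CpG dinucleotides for exercising hypermutation and masking.
#'
#' @param seed Integer seed; the model is byte-identical for a given seed.
#' @param gc_target Target GC fraction (default 0.41, the observed composition
#'   of macaque HML2 elements).
#' @param cpg_free Construct without CG dinucleotides (default `TRUE`).
#' @return An object of class `erv_reference`.
#' @export
build_reference <- function(seed = 1, gc_target = 0.41, cpg_free = TRUE) {
  for (attempt in 0:19) {
    model <- with_seed(seed_stream(seed, paste0("reference", attempt)), {
      build_reference_once(gc_target, cpg_free)
    })
    if (!is.null(model)) {
      model$seed <- as.integer(seed)
      return(model)
    }
  }
  abort("reference construction failed: frame constraints unsatisfiable")
}

build_reference_once <- function(gc_target, cpg_free) {
  ltr <- sample_dna(LTR_LEN, gc_target, cpg_free)
  internal <- seq_chars(sample_dna(INTERNAL_LEN, gc_target, cpg_free))

  protected <- rep(FALSE, INTERNAL_LEN)
  put <- function(chars, p1, block) {
    idx <- p1:(p1 + length(block) - 1L)
    chars[idx] <- block
    protected[idx] <<- TRUE
    chars
  }
  # zinc knuckles at gag aa 600 and 620; NLS at env aa 110; NES at env aa 250
  zn <- encode_peptide(ZN_PEPTIDE)
  internal <- put(internal, 1953L, zn)
  internal <- put(internal, 2013L, zn)
  internal <- put(internal, 5951L, encode_peptide(NLS_PEPTIDE))
  internal <- put(internal, 6371L, encode_peptide(NES_PEPTIDE))
  for (g in names(PAPER_REGIONS)) {
    internal <- put(internal, gene_terminal_stop(g), c("T", "A", "A"))
  }

  internal <- repair_stops(internal, protected, cpg_free)
  if (is.null(internal)) return(NULL)
  internal_str <- chars_seq(internal)

  gc_all <- gc_content(paste0(ltr, internal_str, ltr))
  if (abs(gc_all - gc_target) > 0.02) return(NULL)

  regions <- dplyr::bind_rows(
    tibble(name = "LTR5", start = 0L, end = LTR_LEN),
    tibble(name = "internal", start = LTR_LEN, end = LTR_LEN + INTERNAL_LEN),
    tibble(name = "LTR3", start = LTR_LEN + INTERNAL_LEN,
           end = 2L * LTR_LEN + INTERNAL_LEN),
    dplyr::bind_rows(lapply(names(PAPER_REGIONS), function(g) {
      r <- PAPER_REGIONS[[g]]
      tibble(name = g, start = int1_to_prov0(r[1]), end = int1_to_prov0(r[2]) + 1L)
    }))
  )
  domains <- PAPER_DOMAINS |>
    dplyr::mutate(start = int1_to_prov0(.data$p1), end = int1_to_prov0(.data$p2) + 1L) |>
    dplyr::select("name", "gene", "start", "end")
  motif_sites <- tibble(
    name = c("zinc_knuckle", "zinc_knuckle", "NLS", "NES"),
    start = int1_to_prov0(c(1953L, 2013L, 5951L, 6371L)),
    end = int1_to_prov0(c(1994L, 2054L, 5974L, 6406L)) + 1L
  )

  # Recurrent signature elements. Coordinates are provirus-relative: spans are
  # 0-based half-open; insertion anchors are "insert after this many bases".
  ins96 <- build_gag_insertion(internal, cpg_free)
  if (is.null(ins96)) return(NULL)
  signature <- list(
    gag_del = list(start = int1_to_prov0(156L), len = 12L),
    gag_ins = list(anchor = int1_to_prov0(745L) + 1L, seq = ins96),
    type1_del = list(start = int1_to_prov0(6024L), len = 292L),
    var2_ins = list(anchor = int1_to_prov0(7300L) + 1L,
                    seq = sample_dna(191L, 0.41, cpg_free)),
    var3 = list(stub5 = 150L, stub3 = 120L, donor_len = 673L)
  )

  structure(list(
    ltr = ltr,
    internal = internal_str,
    provirus = paste0(ltr, internal_str, ltr),
    ltr_len = LTR_LEN,
    internal_len = INTERNAL_LEN,
    regions = regions,
    domains = domains,
    motif_sites = motif_sites,
    motif_peptides = list(zinc_knuckle = ZN_PEPTIDE, NLS = NLS_PEPTIDE,
                          NES = NES_PEPTIDE),
    signature = signature,
    gc_target = gc_target,
    cpg_free = cpg_free
  ), class = "erv_reference")
}

# The 96-nt gag insertion lands mid-codon at anchor 745; build it so the gag
# reading frame across the insertion stays stop-free in the reference context.
build_gag_insertion <- function(internal_chars, cpg_free) {
  for (try in 1:50) {
    ins <- seq_chars(sample_dna(96L, 0.41, cpg_free))
    full <- c(internal_chars[744:745], ins, internal_chars[746])
    starts <- seq(1L, length(full) - 2L, by = 3L)
    codons <- vapply(starts, function(s) chars_seq(full[s:(s + 2L)]), character(1))
    if (!any(codons %in% STOP_CODONS)) return(chars_seq(ins))
  }
  NULL
}

#' Retrieve a named region or domain span from the reference model
#'
#' @param model An `erv_reference`.
#' @param name Region (`LTR5`, `internal`, `LTR3`, `gag`, `pro`, `pol`, `env`)
#'   or domain (`MA`, `CA`, `NC`, `RT`, `RH`, `IN`, `SU`, `TM`, `Rec`) name.
#' @return A list with `start`, `end` (0-based half-open, provirus-relative).
#' @export
region_span <- function(model, name) {
  r <- model$regions[model$regions$name == name, ]
  if (nrow(r) == 0) r <- model$domains[model$domains$name == name, ]
  if (nrow(r) == 0) abort(sprintf("unknown region: %s", name))
  list(start = r$start[[1]], end = r$end[[1]])
}

#' @rdname region_span
#' @export
region_paper_coords <- function(model, name) {
  s <- region_span(model, name)
  c(prov0_to_int1(s$start), prov0_to_int1(s$end - 1L))
}

region_seq <- function(model, name) {
  s <- region_span(model, name)
  extract_iv(model$provirus, s$start, s$end)
}

#' @export
print.erv_reference <- function(x, ...) {
  cat(sprintf("<erv_reference> provirus %d nt (LTR %d + internal %d + LTR %d)\n",
              nchar(x$provirus), x$ltr_len, x$internal_len, x$ltr_len))
  cat(sprintf("  GC %.3f, %s\n", gc_content(x$provirus),
              if (x$cpg_free) "CpG-free" else "with CpG"))
  genes <- x$regions[x$regions$name %in% names(PAPER_REGIONS), ]
  for (k in seq_len(nrow(genes))) {
    pc <- region_paper_coords(x, genes$name[k])
    cat(sprintf("  %-4s %5d-%5d (internal 1-based)\n", genes$name[k], pc[1], pc[2]))
  }
  invisible(x)
}

#' Build the MER11A-like recombination parent
#'
#' A synthetic stand-in for the HML8 MER11A LTR that donates the 673-nt
#' segment found in variant-3 env genes. The donor segment occupies positions
#' 201-873 (1-based) of the parent.
#'
#' @param seed Integer seed.
#' @param length Parent length in nt.
#' @param cpg_free Sample without CG dinucleotides.
#' @return A list with `seq`, `donor` (673 nt) and `donor_span`.
#' @export
build_mer11a_parent <- function(seed = 1, length = 1200, cpg_free = TRUE) {
  stopifnot(length >= 873)
  seq <- with_seed(seed_stream(seed, "mer11a"), sample_dna(length, 0.41, cpg_free))
  donor_span <- list(start = 200L, end = 873L)
  list(seq = seq,
       donor = extract_iv(seq, donor_span$start, donor_span$end),
       donor_span = donor_span)
}
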