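# Cohort simulator: plants proviral loci of known age, structure and category
# into neutral multi-species genomes, with a complete truth table.

#' Plant lineage divergence on a provirus
#'
#' Mutates the two LTR copies and the internal region of an ancestral provirus
#' to emulate `T` million years of neutral divergence at `rate`
#' substitutions/nt/Myr. Each LTR copy receives exactly
#' `round(L * rate * T)` substitutions at sites disjoint between the two
#' copies (no coincident or multiple hits), so the observed LTR-vs-LTR
#' p-distance is `2 * rate * T` up to the rounding quantum and each copy is
#' `rate * T` diverged from the ancestor. The internal region is mutated at
#' the same per-lineage fraction.
#'
#' By default substitutions never create a CG dinucleotide, so CpG masking is
#' exactly neutral on simulated data. `cpg_boost > 1` additionally hits CpG
#' cytosines (C->T) with probability `(cpg_boost - 1) * rate * T`, emulating
#' methyl-C deamination, and disables the CG-avoidance constraint.
#'
#' @param ltr,internal Ancestral LTR and internal sequences.
#' @param T Age in Myr.
#' @param seed Integer seed.
#' @param rate Substitution rate per nt per Myr (default 0.0034).
#' @param cpg_boost CpG hypermutation factor (default 1 = off).
#' @return A list with `ltr5`, `ltr3`, `internal`, and the planted site counts.
#' @export
plant_divergence <- function(ltr, internal, T, seed, rate = 0.0034,
                             cpg_boost = 1) {
  stopifnot(T >= 0, rate > 0, cpg_boost >= 1)
  if (2 * rate * T >= 1) abort("divergence saturates: 2 * rate * T >= 1")
  cpg_safe <- cpg_boost <= 1
  with_seed(seed, {
    L <- nchar(ltr)
    n_ltr <- round(L * rate * T)
    sites <- if (n_ltr > 0) sample.int(L, 2L * n_ltr) else integer(0)
    ltr5 <- mutate_sites(seq_chars(ltr), sites[seq_len(n_ltr)], cpg_safe)
    ltr3 <- mutate_sites(seq_chars(ltr), sites[n_ltr + seq_len(n_ltr)], cpg_safe)
    len_i <- nchar(internal)
    n_int <- round(len_i * rate * T)
    int_sites <- if (n_int > 0) sample.int(len_i, n_int) else integer(0)
    internal_m <- mutate_sites(seq_chars(internal), int_sites, cpg_safe)
    if (cpg_boost > 1) {
      p_hit <- min(1, (cpg_boost - 1) * rate * T)
      ltr5 <- hypermutate_cpg(ltr5, p_hit)
      ltr3 <- hypermutate_cpg(ltr3, p_hit)
      internal_m <- hypermutate_cpg(internal_m, p_hit)
    }
    list(ltr5 = chars_seq(ltr5), ltr3 = chars_seq(ltr3),
         internal = chars_seq(internal_m), n_ltr_sites = n_ltr,
         n_internal_sites = n_int)
  })
}

mutate_sites <- function(chars, sites, cpg_safe) {
  for (p in sites) {
    cand <- sample(setdiff(DNA_BASES, chars[p]))
    for (b in cand) {
      if (cpg_safe && creates_cpg(chars, p, b)) next
      chars[p] <- b
      break
    }
  }
  chars
}

hypermutate_cpg <- function(chars, p_hit) {
  n <- length(chars)
  if (n < 2) return(chars)
  is_cpg_c <- chars[-n] == "C" & chars[-1] == "G"
  hit <- which(is_cpg_c)
  hit <- hit[stats::runif(length(hit)) < p_hit]
  chars[hit] <- "T"
  chars
}

# -- locus container -----------------------------------------------------

# An erv_locus tracks, next to the realized sequence, the provirus-relative
# anchor of every base (inserted bases get anchor = preceding position + 0.5),
# which gives exact truth coordinates for every downstream stage.

new_locus <- function(id, species, profile, bases, anchor, model,
                      T_true = NA_real_, category = NA_character_,
                      env_type = "II", env_variant = NA_character_,
                      solo_ltr = FALSE, indels = empty_indels(),
                      recomb_breakpoints = NULL) {
  parts <- locus_parts(anchor, model)
  structure(list(
    id = id, species = species, profile = profile,
    seq = chars_seq(bases), bases = bases, anchor = anchor,
    parts = parts, T_true = T_true, category = category,
    env_type = env_type, env_variant = env_variant, solo_ltr = solo_ltr,
    indels = indels, recomb_breakpoints = recomb_breakpoints
  ), class = "erv_locus")
}

empty_indels <- function() {
  tibble(kind = character(), ref_start = integer(), length = integer(),
         region = character())
}

locus_parts <- function(anchor, model) {
  ltr_len <- model$ltr_len
  int_end <- ltr_len + model$internal_len
  n1 <- sum(anchor <= ltr_len)
  n2 <- sum(anchor > ltr_len & anchor <= int_end)
  n3 <- sum(anchor > int_end)
  parts <- tibble(
    name = c("LTR5", "internal", "LTR3"),
    start = c(0L, n1, n1 + n2),
    end = c(n1, n1 + n2, n1 + n2 + n3)
  )
  parts[parts$end > parts$start, ]
}

#' @export
print.erv_locus <- function(x, ...) {
  cat(sprintf("<erv_locus> %s [%s] %d nt%s\n", x$id,
              x$species %||% "?", nchar(x$seq),
              if (isTRUE(x$solo_ltr)) " (solo LTR)" else ""))
  invisible(x)
}

apply_deletion <- function(bases, anchor, start1, len) {
  keep <- !(anchor >= start1 & anchor <= start1 + len - 1L)
  list(bases = bases[keep], anchor = anchor[keep])
}

apply_insertion <- function(bases, anchor, after1, seq) {
  at <- sum(anchor <= after1 + 0.4)
  ins <- seq_chars(seq)
  list(bases = append(bases, ins, after = at),
       anchor = append(anchor, rep(after1 + 0.5, length(ins)), after = at))
}

region_of_position <- function(model, pos1) {
  region_of_span(model, pos1, pos1)
}

# genes (or LTRs) overlapping a 1-based inclusive reference span
region_of_span <- function(model, start1, end1) {
  genes <- model$regions[model$regions$name %in% names(PAPER_REGIONS), ]
  hit <- genes$name[start1 <= genes$end & end1 > genes$start]
  if (length(hit) == 0) {
    r <- model$regions[model$regions$name %in% c("LTR5", "LTR3"), ]
    hit <- r$name[start1 <= r$end & end1 > r$start]
  }
  if (length(hit) == 0) "intergenic" else paste(hit, collapse = ",")
}

#' Apply a species signature profile to a simulated locus
#'
#' Plants the recurrent structural signatures: the macaque profile carries the
#' 12-nt deletion at the gag 5' end (reference 156-167) and the 96-nt
#' insertion anchored at reference 745; env variant 2 adds the 191-nt
#' transmembrane insertion; env variant 3 replaces the interior of env (all
#' but 150-nt 5' and 120-nt 3' stubs) with the contiguous 673-nt MER11A donor
#' segment; env type I deletes 292 nt inside the Rec portion of env. Type I is
#' human-only and variant 3 macaque-only; incompatible combinations error.
#'
#' @param locus An `erv_locus` (as built by [simulate_locus()]).
#' @param model An `erv_reference`.
#' @param profile `"human"` or `"macaque"`.
#' @param env_variant `"none"`, `"1"`, `"2"` or `"3"`.
#' @param env_type `"I"` or `"II"`.
#' @param parent MER11A parent (required for variant 3).
#' @return The modified `erv_locus`, with its `indels` truth updated.
#' @export
apply_signature_profile <- function(locus, model, profile = c("human", "macaque"),
                                    env_variant = "none",
                                    env_type = "II", parent = NULL) {
  profile <- match.arg(profile)
  env_variant <- as.character(env_variant)
  stopifnot(env_variant %in% c("none", "1", "2", "3"), env_type %in% c("I", "II"))
  if (env_type == "I" && profile != "human") {
    abort("type I env is human-only: incompatible with macaque profile")
  }
  if (env_variant == "3" && profile != "macaque") {
    abort("variant 3 env is macaque-only: incompatible with human profile")
  }
  if (env_variant %in% c("2", "3") && env_type == "I") {
    abort("type I env is incompatible with macaque env variants 2/3")
  }
  if (env_variant == "3" && is.null(parent)) abort("variant 3 requires the MER11A parent")

  bases <- locus$bases
  anchor <- locus$anchor
  sig <- model$signature
  dels <- list()
  inss <- list()
  if (profile == "macaque") {
    dels <- c(dels, list(list(start1 = sig$gag_del$start + 1L, len = sig$gag_del$len)))
    inss <- c(inss, list(list(after1 = sig$gag_ins$anchor, seq = sig$gag_ins$seq)))
  }
  if (env_type == "I") {
    dels <- c(dels, list(list(start1 = sig$type1_del$start + 1L, len = sig$type1_del$len)))
  }
  recomb_breakpoints <- NULL
  if (env_variant == "2") {
    inss <- c(inss, list(list(after1 = sig$var2_ins$anchor, seq = sig$var2_ins$seq)))
  } else if (env_variant == "3") {
    env <- region_span(model, "env")
    rep_start1 <- env$start + sig$var3$stub5 + 1L
    rep_end1 <- env$end - sig$var3$stub3
    dels <- c(dels, list(list(start1 = rep_start1, len = rep_end1 - rep_start1 + 1L)))
    inss <- c(inss, list(list(after1 = rep_start1 - 1L, seq = parent$donor)))
    recomb_breakpoints <- c(sig$var3$stub5, sig$var3$stub5 + sig$var3$donor_len)
  }
  for (d in dels) {
    res <- apply_deletion(bases, anchor, d$start1, d$len)
    bases <- res$bases; anchor <- res$anchor
  }
  for (i in inss) {
    res <- apply_insertion(bases, anchor, i$after1, i$seq)
    bases <- res$bases; anchor <- res$anchor
  }
  indels <- dplyr::bind_rows(
    empty_indels(),
    purrr::map_dfr(dels, function(d) {
      tibble(kind = "deletion", ref_start = as.integer(d$start1),
             length = as.integer(d$len),
             region = region_of_position(model, d$start1))
    }),
    purrr::map_dfr(inss, function(i) {
      tibble(kind = "insertion", ref_start = as.integer(i$after1),
             length = nchar(i$seq),
             region = region_of_position(model, i$after1))
    })
  )
  new_locus(locus$id, locus$species, profile, bases, anchor, model,
            T_true = locus$T_true, category = locus$category,
            env_type = env_type, env_variant = env_variant,
            solo_ltr = FALSE, indels = indels,
            recomb_breakpoints = recomb_breakpoints)
}

#' Simulate a single proviral locus
#'
#' Builds one provirus from the reference model: plants `T` Myr of lineage
#' divergence with [plant_divergence()], then applies the species signature
#' profile with [apply_signature_profile()]. A solo LTR locus is a single
#' (diverged) LTR copy.
#'
#' @inheritParams apply_signature_profile
#' @param T True insertion age in Myr.
#' @param seed Integer seed.
#' @param solo_ltr Emit a solo LTR instead of a full provirus.
#' @param id,species Locus identity metadata.
#' @param cpg_boost Passed to [plant_divergence()].
#' @return An `erv_locus`.
#' @export
simulate_locus <- function(model, profile = c("human", "macaque"), T = 10,
                           env_type = "II", env_variant = "none",
                           solo_ltr = FALSE, seed = 1, parent = NULL,
                           id = "locus1", species = NA_character_,
                           cpg_boost = 1) {
  profile <- match.arg(profile)
  div <- plant_divergence(model$ltr, model$internal, T,
                          seed_stream(seed, paste0("div:", id)),
                          cpg_boost = cpg_boost)
  if (solo_ltr) {
    bases <- seq_chars(div$ltr5)
    anchor <- seq_len(model$ltr_len)
    return(new_locus(id, species, profile, bases, anchor, model,
                     T_true = T, solo_ltr = TRUE,
                     env_variant = NA_character_))
  }
  bases <- c(seq_chars(div$ltr5), seq_chars(div$internal), seq_chars(div$ltr3))
  anchor <- seq_len(2L * model$ltr_len + model$internal_len)
  locus <- new_locus(id, species, profile, bases, anchor, model, T_true = T)
  apply_signature_profile(locus, model, profile, env_variant, env_type, parent)
}

#' Extract a locus part or gene truth sequence
#'
#' Uses the locus's planted anchor bookkeeping (not alignment) to recover the
#' realized sequence of a reference region, giving truth values for the
#' annotation pipeline to be compared against.
#'
#' @param locus An `erv_locus`.
#' @param model An `erv_reference`.
#' @param name Region/domain name (see [region_span()]).
#' @return A DNA string (possibly empty).
#' @export
locus_true_region <- function(locus, model, name) {
  s <- region_span(model, name)
  g1 <- s$start + 1L
  g2 <- s$end
  chars_seq(locus$bases[locus$anchor >= g1 & locus$anchor <= g2])
}

locus_truth_coding <- function(locus, model) {
  out <- list()
  for (g in c("gag", "pol", "env")) {
    s <- region_span(model, g)
    seqg <- locus_true_region(locus, model, g)
    in_gene <- locus$indels$ref_start > s$start & locus$indels$ref_start <= s$end
    net <- sum(ifelse(locus$indels$kind[in_gene] == "insertion",
                      locus$indels$length[in_gene],
                      -locus$indels$length[in_gene]))
    frameshift <- (net %% 3L) != 0L
    aa <- translate_dna(seqg)
    stops <- sum(seq_chars(substr(aa, 1, max(0, nchar(aa) - 1L))) == "*")
    covered <- sum(locus$anchor >= s$start + 1L & locus$anchor <= s$end &
                     locus$anchor == floor(locus$anchor))
    coverage <- covered / (s$end - s$start)
    out[[paste0(g, "_intact")]] <- stops == 0L && !frameshift && coverage >= 0.95
  }
  out
}

# -- cohort --------------------------------------------------------------

#' Default cohort configuration
#'
#' The defaults reproduce the study conditions: three species with 12
#' human-shared, 46 macaque-shared and 19 macfas-specific loci, planted at the
#' reported macfas category median ages (32.4, 15.7, 5.6 Myr), one solo LTR
#' among the macaque-shared loci, 6-nt target-site duplications and 200-nt
#' orthologous flanks. Flanking neutral DNA diverges at its own rate
#' (0.1%/nt/Myr per lineage, a genome-wide primate neutral rate) so that
#' orthologous flanks remain recognizable at the oldest planted ages.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    species = c("human", "macfas", "rhesus"),
    outgroup = "human",
    specific_species = "macfas",
    n_human_shared = 12L,
    n_macaque_shared = 46L,
    n_species_specific = 19L,
    age_human_shared = 32.4,
    age_macaque_shared = 15.7,
    age_species_specific = 5.6,
    flank_len = 200L,
    spacer_len = 3000L,
    tsd_len = 6L,
    solo_ltr_count = 1L,
    variant_probs = list(
      human_shared = c(1, 0, 0),
      macaque_shared = c(0.45, 0.35, 0.20),
      species_specific = c(0.15, 0.15, 0.70)
    ),
    rate = 0.0034,
    flank_rate = 0.001,
    gc = 0.41,
    minus_strand_prob = 0.3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(sprintf("unknown cohort config key(s): %s",
                                     paste(bad, collapse = ", ")))
  utils::modifyList(cfg, over)
}

draw_age <- function(spec) {
  if (length(spec) == 2) stats::runif(1, spec[1], spec[2]) else spec
}

#' Simulate a multi-species genome cohort with planted proviruses
#'
#' Every planted locus is embedded in neutral flanking DNA with a target-site
#' duplication; orthologous loci share identical ancestral 200-nt flanks
#' across carrier species, independently mutated per lineage. Returns the
#' genomes together with the reference model, the MER11A parent and a
#' complete truth table. Deterministic per seed.
#'
#' @param config A [cohort_config()] list.
#' @param seed Integer seed.
#' @return An object of class `erv_cohort`: a list with `genomes` (named
#'   character vector of contig sequences), `model`, `parent`, `truth`
#'   (tibble, one row per planted locus), `placements` (tibble, one row per
#'   locus copy per carrier species), `loci` (list of `erv_locus` by
#'   locus/species), `config` and `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  model <- build_reference(seed)
  parent <- build_mer11a_parent(seed)
  categories <- c(
    rep("human_shared", config$n_human_shared),
    rep("macaque_shared", config$n_macaque_shared),
    rep("species_specific", config$n_species_specific)
  )
  n <- length(categories)
  macaques <- setdiff(config$species, config$outgroup)

  solo_ids <- integer(0)
  if (config$solo_ltr_count > 0) {
    cand <- which(categories == "macaque_shared")
    if (length(cand) < config$solo_ltr_count) cand <- seq_len(n)
    solo_ids <- cand[seq_len(config$solo_ltr_count)]
  }

  loci_meta <- with_seed(seed_stream(seed, "cohort-meta"), {
    purrr::map(seq_len(n), function(k) {
      cat_k <- categories[k]
      sp_set <- switch(cat_k,
        human_shared = config$species,
        macaque_shared = macaques,
        species_specific = config$specific_species)
      age_spec <- switch(cat_k,
        human_shared = config$age_human_shared,
        macaque_shared = config$age_macaque_shared,
        species_specific = config$age_species_specific)
      variant <- sample(c("1", "2", "3"), 1, prob = config$variant_probs[[cat_k]])
      list(
        id = sprintf("L%03d", k), category = cat_k, species_set = sp_set,
        T_true = draw_age(age_spec), env_variant = variant,
        solo_ltr = k %in% solo_ids,
        strand = if (stats::runif(1) < config$minus_strand_prob) "-" else "+",
        flank_left = sample_dna(config$flank_len, config$gc, cpg_free = FALSE),
        flank_right = sample_dna(config$flank_len, config$gc, cpg_free = FALSE),
        tsd = sample_dna(config$tsd_len, config$gc, cpg_free = FALSE)
      )
    })
  })

  loci <- list()
  truth_rows <- list()
  pieces <- stats::setNames(vector("list", length(config$species)), config$species)
  placements <- list()

  for (k in seq_len(n)) {
    m <- loci_meta[[k]]
    # the planted env variant only manifests in macaque-profile copies
    for (sp in m$species_set) {
      is_out <- sp == config$outgroup
      profile <- if (is_out) "human" else "macaque"
      variant <- if (is_out || m$solo_ltr) "none" else m$env_variant
      loc <- simulate_locus(
        model, profile = profile, T = m$T_true, env_type = "II",
        env_variant = variant, solo_ltr = m$solo_ltr,
        seed = seed_stream(seed, paste0("locus:", m$id, ":", sp)),
        parent = parent, id = m$id, species = sp
      )
      intact <- if (m$solo_ltr) {
        list(gag_intact = FALSE, pol_intact = FALSE, env_intact = FALSE)
      } else {
        locus_truth_coding(loc, model)
      }
      fl <- mutate_flank(m$flank_left, m$T_true, config$flank_rate,
                         seed_stream(seed, paste0("flankL:", m$id, ":", sp)))
      fr <- mutate_flank(m$flank_right, m$T_true, config$flank_rate,
                         seed_stream(seed, paste0("flankR:", m$id, ":", sp)))
      inserted <- if (m$strand == "-") revcomp(loc$seq) else loc$seq
      block <- paste0(fl, m$tsd, inserted, m$tsd, fr)
      pieces[[sp]] <- c(pieces[[sp]], list(list(id = m$id, block = block,
        offset_in_block = nchar(fl) + nchar(m$tsd), locus_len = nchar(loc$seq))))
      loci[[paste(m$id, sp, sep = ":")]] <- loc
      placements[[length(placements) + 1L]] <- tibble(
        locus_id = m$id, species = sp,
        gag_intact = intact$gag_intact, pol_intact = intact$pol_intact,
        env_intact = intact$env_intact
      )
    }
    truth_rows[[k]] <- tibble(
      locus_id = m$id, category = m$category,
      species_set = paste(m$species_set, collapse = ","),
      T_true = m$T_true, env_type = "II",
      env_variant = if (m$solo_ltr) NA_character_ else m$env_variant,
      solo_ltr = m$solo_ltr, strand = m$strand,
      recomb_b1 = if (!m$solo_ltr && m$env_variant == "3") model$signature$var3$stub5 else NA_integer_,
      recomb_b2 = if (!m$solo_ltr && m$env_variant == "3") {
        model$signature$var3$stub5 + model$signature$var3$donor_len
      } else NA_integer_
    )
  }

  genomes <- character(0)
  placement_rows <- list()
  for (sp in config$species) {
    spacers <- with_seed(seed_stream(seed, paste0("spacer:", sp)), {
      replicate(length(pieces[[sp]]) + 1L,
                sample_dna(config$spacer_len, config$gc, cpg_free = FALSE))
    })
    parts <- character(0)
    pos <- 0L
    for (j in seq_along(pieces[[sp]])) {
      pc <- pieces[[sp]][[j]]
      parts <- c(parts, spacers[j])
      pos <- pos + nchar(spacers[j])
      start0 <- pos + pc$offset_in_block
      placement_rows[[length(placement_rows) + 1L]] <- tibble(
        locus_id = pc$id, species = sp, contig = "chr1",
        start = start0, end = start0 + pc$locus_len
      )
      parts <- c(parts, pc$block)
      pos <- pos + nchar(pc$block)
    }
    parts <- c(parts, spacers[length(spacers)])
    genomes[[sp]] <- paste(parts, collapse = "")
  }

  placements_tbl <- dplyr::bind_rows(placement_rows) |>
    dplyr::left_join(dplyr::bind_rows(placements), by = c("locus_id", "species")) |>
    dplyr::left_join(dplyr::bind_rows(truth_rows) |>
                       dplyr::select("locus_id", "strand"), by = "locus_id")

  structure(list(
    genomes = genomes, model = model, parent = parent,
    truth = dplyr::bind_rows(truth_rows), placements = placements_tbl,
    loci = loci, config = config, seed = as.integer(seed)
  ), class = "erv_cohort")
}

mutate_flank <- function(flank, T, rate, seed) {
  n <- round(nchar(flank) * rate * T)
  if (n == 0) return(flank)
  with_seed(seed, {
    chars <- seq_chars(flank)
    sites <- sample.int(length(chars), n)
    chars_seq(mutate_sites(chars, sites, cpg_safe = FALSE))
  })
}

#' @export
print.erv_cohort <- function(x, ...) {
  cat(sprintf("<erv_cohort> %d loci across %s (seed %d)\n", nrow(x$truth),
              paste(names(x$genomes), collapse = ", "), x$seed))
  print(dplyr::count(x$truth, .data$category))
  invisible(x)
}
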