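# Standard formats: FASTA, BED6, Newick, TSV reports, run configuration.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are normalized to uppercase DNA (lowercase raised, `U` mapped to
#' `T`, IUPAC ambiguity codes collapsed to `N`). A record with an empty
#' sequence or a non-IUPAC character is a format error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- chartr("U", "T", seqs)
  for (k in seq_along(seqs)) {
    if (ids[k] == "") abort(sprintf("record %d has an empty id", k))
    if (nchar(seqs[k]) == 0) {
      abort(sprintf("record '%s' has an empty sequence", ids[k]))
    }
    s <- gsub(sprintf("[%s]", paste(IUPAC_AMBIG, collapse = "")), "N", seqs[k])
    validate_dna(s, ids[k])
    seqs[k] <- s
  }
  tibble(id = unname(ids), description = unname(desc), seq = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with columns `id`, `seq` (optionally
#'   `description`), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    records <- tibble(id = names(records), description = "", seq = unname(records))
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[k] else ""
    header <- if (nzchar(desc)) paste(records$id[k], desc) else records$id[k]
    writeLines(paste0(">", header), con)
    s <- records$seq[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write genomic intervals as a BED6 file
#'
#' Intervals are 0-based half-open, the native BED convention. Round-trips
#' through [read_bed()].
#'
#' @param loci A tibble with columns `contig`, `start`, `end`, `name`,
#'   optionally `score` and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  stopifnot(all(c("contig", "start", "end", "name") %in% names(loci)))
  if (nrow(loci) > 0 && any(loci$start >= loci$end)) {
    abort("invalid interval: start must be < end")
  }
  out <- tibble(
    contig = loci$contig,
    start = as.integer(loci$start),
    end = as.integer(loci$end),
    name = loci$name,
    score = if ("score" %in% names(loci)) loci$score else 0L,
    strand = if ("strand" %in% names(loci)) loci$strand else "+"
  )
  if (nrow(out) > 0 && !all(out$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  name = character(), score = integer(), strand = character()))
  }
  readr::read_tsv(path,
    col_names = c("contig", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE)
}

#' Write and read phylogenetic trees in Newick format
#'
#' Thin validating wrappers around [ape::write.tree()] / [ape::read.tree()].
#' Bootstrap supports stored in `node.label` are emitted as internal-node
#' labels. Duplicate leaf labels or negative branch lengths are errors.
#'
#' @param tree An [ape::phylo] tree.
#' @param path File path.
#' @return `path` (writer) or a `phylo` (reader).
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("negative branch lengths")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ape::read.tree(path)
}

#' Read and validate a run configuration file
#'
#' The configuration is a flat YAML key-value file. Unknown keys are errors,
#' so silent typos cannot change a run.
#'
#' @param path Path to a YAML config file.
#' @return A validated pipeline configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), raw, keep.null = TRUE),
                  extra = setdiff(names(raw), names(default_config())))
}
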