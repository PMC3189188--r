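# ---- FASTA ------------------------------------------------------------------

.need_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA input/output")
  }
}

#' Read a pre-aligned FASTA file as a character matrix
#'
#' @param path FASTA file (amino acid or nucleotide, equal-length records).
#' @return Character matrix (taxa x sites).
#' @export
read_alignment_fasta <- function(path) {
  .need_biostrings()
  ss <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) abort("FASTA records are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(as.character(ss), "", fixed = TRUE))
  rownames(m) <- names(ss)
  toupper(m)
}

#' Write one alignment as FASTA
#' @param aln Character matrix (taxa x sites).
#' @param path Output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  .need_biostrings()
  ss <- Biostrings::BStringSet(apply(aln, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a genome set to a directory
#'
#' One FASTA per family (`fam_0001.fasta`, ...) plus `manifest.tsv` listing
#' per family the transferred taxa (empty when vertical).
#'
#' @param gs A `genome_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_families(gs))) {
    write_alignment_fasta(family_alignment(gs, i),
                          file.path(dir, paste0(gs$family_ids[i], ".fasta")))
  }
  tr <- gs$transfers
  manifest <- tibble(
    family = gs$family_ids,
    transferred_taxa = vapply(gs$family_ids, function(f)
      paste(sort(tr$taxon[tr$family == f]), collapse = ","), character(1))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(dir)
}

# ---- TSV dumps --------------------------------------------------------------

#' Write the nontrivial bipartitions of a tree as TSV
#' @param tree A `phylo`.
#' @param path Output file.
#' @export
write_bipartitions_tsv <- function(tree, path) {
  bp <- bipartitions(tree)
  tab <- tibble(
    side_a = vapply(bp$side_a, paste, character(1), collapse = ","),
    side_b = vapply(bp$side_b, paste, character(1), collapse = ","),
    support = bp$support
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Write a quartet tally as TSV
#'
#' One row per (subset, topology) with topology codes `12|34`, `13|24`,
#' `14|23`, `U` and the observed weight.
#'
#' @param tally A `quartet_tally`.
#' @param path Output file.
#' @export
write_quartet_tally_tsv <- function(tally, path) {
  long <- tidyr::pivot_longer(
    dplyr::rename(tibble::as_tibble(tally), `12|34` = "w12.34",
                  `13|24` = "w13.24", `14|23` = "w14.23", U = "unresolved"),
    cols = c("12|34", "13|24", "14|23", "U"),
    names_to = "topology", values_to = "weight"
  )
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Write a square distance matrix as TSV
#' @param d Square matrix with dimnames, or `protein_dist`.
#' @param path Output file.
#' @export
write_distance_tsv <- function(d, path) {
  if (inherits(d, "protein_dist")) d <- d$d
  tab <- tibble::as_tibble(as.data.frame(d), rownames = "taxon")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

# ---- experiment config text form -------------------------------------------

#' Write / read an experiment configuration as key-value text
#'
#' Plain `key<TAB>value` lines covering the scalar fields plus the species
#' tree in newick; [read_experiment_config()] reconstructs the object.
#'
#' @param config An [experiment_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  lines <- c(
    paste0("b\t", config$b),
    paste0("donor\t", config$donor),
    paste0("recipient\t", config$recipient),
    paste0("genes\t", config$genes),
    paste0("len\t", config$len),
    paste0("hgt\t", config$hgt),
    paste0("replicates\t", config$replicates),
    paste0("seed\t", config$seed),
    paste0("model\t", config$model$kind),
    paste0("methods\t", paste(config$methods, collapse = ",")),
    paste0("species_tree\t", write_newick(config$species_tree))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  kv <- readr::read_tsv(path, col_names = c("key", "value"),
                        show_col_types = FALSE, progress = FALSE)
  val <- setNames(kv$value, kv$key)
  experiment_config(
    b = as.numeric(val[["b"]]),
    species_tree = parse_newick(val[["species_tree"]]),
    donor = val[["donor"]], recipient = val[["recipient"]],
    genes = as.integer(val[["genes"]]), len = as.integer(val[["len"]]),
    hgt = as.numeric(val[["hgt"]]), replicates = as.integer(val[["replicates"]]),
    seed = as.integer(val[["seed"]]),
    model = substitution_model(val[["model"]]),
    methods = strsplit(val[["methods"]], ",", fixed = TRUE)[[1]]
  )
}
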