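# Shared conventions: site coordinates are 1-based alignment columns;
# '-' and N (nucleotide) / X (amino acid) are missing for all counting.

#' Missing-data characters for an alphabet
#'
#' @param alphabet Character vector of residue states (no gap).
#' @return Characters treated as missing data.
#' @keywords internal
missing_chars <- function(alphabet) {
  if ("A" %in% alphabet && length(alphabet) == 4) c("-", "N", "?")
  else c("-", "X", "?")
}

#' Read a species-to-phenotype-group table
#'
#' Reads a two-column TSV (`species_id<TAB>group`) assigning every species to
#' the `flying` or `flight_degenerate` phenotype class. The foreground of all
#' downstream scans is the `flight_degenerate` group.
#'
#' @param path Path to a tab-separated file with columns `species_id`, `group`.
#' @return A tibble with columns `species_id` and `group` (factor with levels
#'   `flying`, `flight_degenerate`).
#' @export
read_group_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("species_id", "group") %in% names(df))) {
    abort("label table must have columns 'species_id' and 'group'")
  }
  group_labels(df$species_id, df$group)
}

#' Build a species-group table in memory
#'
#' @param species_id Character vector of species identifiers.
#' @param group Character vector, each `"flying"` or `"flight_degenerate"`.
#' @return A validated tibble of class `species_groups`.
#' @export
group_labels <- function(species_id, group) {
  bad <- setdiff(unique(group), c("flying", "flight_degenerate"))
  if (length(bad) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(species_id)) {
    abort("each species must appear exactly once in the label table")
  }
  if (length(unique(group)) < 2) {
    abort("need at least one species in each phenotype group")
  }
  out <- tibble(species_id = as.character(species_id),
                group = factor(group, levels = c("flying", "flight_degenerate")))
  class(out) <- c("species_groups", class(out))
  out
}

#' Foreground (flight-degenerate) species of a label table or alignment
#'
#' @param x A `species_groups` table or `labeled_alignment`.
#' @return Character vector of flight-degenerate species ids.
#' @export
foreground_species <- function(x) {
  g <- if (inherits(x, "labeled_alignment")) x$groups else x
  g$species_id[g$group == "flight_degenerate"]
}

#' Construct a labeled alignment
#'
#' A labeled alignment couples a site-by-species character matrix with the
#' phenotype group of every species. All counting operations treat `-`,
#' `N`/`X` and `?` as missing data.
#'
#' @param mat Character matrix, rows = species (rownames set), columns = sites.
#' @param groups A `species_groups` table covering every row of `mat`.
#' @param gene_id Gene identifier string.
#' @param alphabet Residue alphabet; defaults to the DNA alphabet
#'   `c("A","C","G","T")` or, if non-nucleotide characters dominate, the
#'   20-letter amino-acid alphabet.
#' @return An object of class `labeled_alignment`.
#' @export
labeled_alignment <- function(mat, groups, gene_id = "gene",
                              alphabet = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  mat[] <- toupper(mat)
  if (is.null(alphabet)) {
    chars <- unique(as.vector(mat))
    chars <- setdiff(chars, c("-", "N", "X", "?"))
    alphabet <- if (all(chars %in% c("A", "C", "G", "T", "U")))
      c("A", "C", "G", "T") else AA_ALPHABET
  }
  unknown <- setdiff(rownames(mat), groups$species_id)
  if (length(unknown) > 0) {
    abort(paste0("species absent from label table: ",
                 paste(unknown, collapse = ", ")), class = "convflight_label_error")
  }
  structure(
    list(gene_id = gene_id, seq = mat,
         groups = groups[match(rownames(mat), groups$species_id), ],
         alphabet = alphabet),
    class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("<labeled_alignment> gene", x$gene_id, "-", nrow(x$seq), "species x",
      ncol(x$seq), "sites;",
      sum(x$groups$group == "flight_degenerate"), "flight-degenerate /",
      sum(x$groups$group == "flying"), "flying\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `labeled_alignment`.
#' @return Integer site count.
#' @export
n_sites <- function(aln) ncol(aln$seq)

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an aligned FASTA file as a labeled alignment
#'
#' @param path Path to a FASTA file of aligned, equal-length records whose
#'   names are species ids present in `labels`.
#' @param labels A `species_groups` table.
#' @param gene_id Gene identifier; defaults to the file name without extension.
#' @inheritParams labeled_alignment
#' @return A `labeled_alignment`.
#' @export
read_alignment <- function(path, labels, gene_id = NULL, alphabet = NULL) {
  gene_id <- gene_id %||% sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1) {
    abort(paste0("FASTA records are not aligned (lengths ",
                 paste(sort(unique(lens)), collapse = ", "), ")"),
          class = "convflight_format_error")
  }
  mat <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  labeled_alignment(mat, labels, gene_id = gene_id, alphabet = alphabet)
}

#' Write a labeled alignment to FASTA
#'
#' @param aln A `labeled_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' Branch lengths missing from the file are replaced by `default_length`
#' with a warning, so that downstream likelihood code always sees finite,
#' non-negative lengths.
#'
#' @param path Newick file path.
#' @param default_length Length substituted for absent branch lengths.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path, default_length = 0.1) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste("Newick parse error:",
                                                 conditionMessage(e)),
                                           class = "convflight_parse_error"))
  if (is.null(tr)) {
    abort("Newick parse error: no tree found", class = "convflight_parse_error")
  }
  if (is.null(tr$edge.length)) {
    warn(paste0("tree has no branch lengths; using default ", default_length))
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warn(paste0("missing branch lengths replaced by default ", default_length))
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(tr$edge.length < 0)) abort("negative branch length in tree")
  tr
}

#' Write a phylogeny to Newick
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Map alignment columns to ungapped coordinates of a reference species
#'
#' Converts 1-based alignment columns to 1-based positions in the ungapped
#' sequence of a named reference species (the convention used to report
#' sites such as "codon 321" in a reference gene). Columns where the
#' reference itself has a gap or missing character get `NA` — they have no
#' coordinate in the reference sequence.
#'
#' @param aln A `labeled_alignment`.
#' @param reference Species id used as the coordinate reference.
#' @return A tibble with columns `column` and `ref_pos`.
#' @export
alignment_to_reference <- function(aln, reference) {
  if (!reference %in% rownames(aln$seq)) {
    abort(paste0("reference species '", reference, "' not in alignment"))
  }
  row <- aln$seq[reference, ]
  present <- !(row %in% missing_chars(aln$alphabet))
  tibble(column = seq_along(row),
         ref_pos = ifelse(present, cumsum(present), NA_integer_))
}

#' Validate that an alignment, tree and label table fit together
#'
#' @param aln A `labeled_alignment`.
#' @param tree An `ape::phylo`.
#' @return `TRUE` invisibly; aborts on mismatch.
#' @export
validate_inputs <- function(aln, tree) {
  if (!setequal(tree$tip.label, rownames(aln$seq))) {
    abort("tree leaf set does not match alignment species set",
          class = "convflight_input_error")
  }
  invisible(TRUE)
}
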