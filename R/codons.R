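# Focal-codon ancestral reconstruction and the genotype -> flight-phenotype
# map for the two lipid-metabolism loci (ATGL codon 321, ACOT7 codon 197).

#' Marginal ancestral reconstruction of one codon column
#'
#' Reconstructs the three nucleotide positions of a codon marginally
#' (per-position posteriors via [marginal_ancestral()]) and combines them
#' into a codon posterior per node as the renormalised product of the three
#' position posteriors. This per-position independence approximation is
#' transparent and exactly testable; a 61-state codon model is deliberately
#' out of scope.
#'
#' @param aln Nucleotide `labeled_alignment`.
#' @param start 1-based alignment column of the codon's first position
#'   (the three columns must be consecutive and in frame).
#' @param tree Rooted `ape::phylo`.
#' @param model Nucleotide `subst_model`.
#' @return Object of class `codon_recon`: tibble `calls` (per internal node:
#'   `node`, `codon`, `pp`), full 64-state posterior matrix in
#'   `posterior` (codons x nodes), and `position_recon`.
#' @export
reconstruct_codon <- function(aln, start, tree, model) {
  if (length(model$alphabet) != 4) abort("reconstruct_codon needs a nucleotide model")
  cols <- start + 0:2
  if (start < 1 || max(cols) > n_sites(aln)) {
    abort("codon columns outside the alignment")
  }
  sub <- labeled_alignment(aln$seq[, cols, drop = FALSE], aln$groups,
                           gene_id = aln$gene_id, alphabet = model$alphabet)
  all_missing <- vapply(1:3, function(j)
    all(sub$seq[, j] %in% missing_chars(model$alphabet)), logical(1))
  if (any(all_missing)) {
    abort(paste0("codon position ", which(all_missing)[1],
                 " has no observed data"),
          class = "convflight_reconstruction_error")
  }
  recon <- marginal_ancestral(sub, tree, model)
  n_tip <- recon$n_tip
  internal <- n_tip + seq_len(tree$Nnode)
  grid <- expand.grid(p1 = 1:4, p2 = 1:4, p3 = 1:4)
  codons <- paste0(model$alphabet[grid$p1], model$alphabet[grid$p2],
                   model$alphabet[grid$p3])
  post <- sapply(internal, function(v) {
    p <- recon$posterior[[v]]
    cp <- p[grid$p1, 1] * p[grid$p2, 2] * p[grid$p3, 3]
    cp / sum(cp)
  })
  rownames(post) <- codons
  colnames(post) <- internal
  calls <- tibble(
    node = internal,
    codon = codons[apply(post, 2, which.max)],
    pp = apply(post, 2, max))
  structure(list(calls = calls, posterior = post,
                 position_recon = recon, tree = tree),
            class = "codon_recon")
}

#' @export
print.codon_recon <- function(x, ...) {
  root <- length(x$tree$tip.label) + 1L
  r <- x$calls[x$calls$node == root, ]
  cat("<codon_recon>", nrow(x$calls), "internal nodes; root codon",
      r$codon, "with PP", signif(r$pp, 4), "\n")
  invisible(x)
}

#' @export
tidy.codon_recon <- function(x, ...) x$calls

translate_codon <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[toupper(codon)])
  if (anyNA(aa)) abort(paste0("untranslatable codon: ", codon))
  aa
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

#' Map an (ATGL, ACOT7) genotype to a flight-phenotype class
#'
#' Translates the two focal codons and applies the fixed genotype map:
#' Ser(ATGL321) + Ala(ACOT7197) -> sustained flyer;
#' Gly + Ala -> non-sustained flyer; Gly + Val -> flightless or weak flyer;
#' anything else (including stop codons, with a warning) -> unclassified.
#'
#' @param atgl_codon Codon string at ATGL residue 321 (e.g. `"AGT"`).
#' @param acot7_codon Codon string at ACOT7 residue 197 (e.g. `"GCG"`).
#' @return One-row tibble: `atgl_aa`, `acot7_aa`, `phenotype_class` (factor
#'   with levels `sustained_flyer`, `non_sustained_flyer`,
#'   `flightless_or_weak`, `unclassified`).
#' @export
genotype_to_phenotype <- function(atgl_codon, acot7_codon) {
  aa1 <- translate_codon(atgl_codon)
  aa2 <- translate_codon(acot7_codon)
  if (aa1 == "*" || aa2 == "*") {
    warn("stop codon in focal position; phenotype unclassified")
  }
  atgl <- if (aa1 == "S") "Ser" else if (aa1 == "G") "Gly" else "other"
  acot <- if (aa2 == "A") "Ala" else if (aa2 == "V") "Val" else "other"
  cls <- if (atgl == "Ser" && acot == "Ala") "sustained_flyer"
    else if (atgl == "Gly" && acot == "Ala") "non_sustained_flyer"
    else if (atgl == "Gly" && acot == "Val") "flightless_or_weak"
    else "unclassified"
  tibble(atgl_aa = atgl, acot7_aa = acot,
         phenotype_class = factor(cls, levels = c(
           "sustained_flyer", "non_sustained_flyer",
           "flightless_or_weak", "unclassified")))
}

#' Ancestral phenotype calls across alternative tree topologies
#'
#' Reconstructs both focal codons at a chosen ancestral node under each
#' supplied topology and reports the phenotype call per tree, summarising
#' agreement. Trees whose leaf set does not match the alignments are
#' skipped with a warning.
#'
#' @param aln_atgl,aln_acot7 Nucleotide `labeled_alignment`s for the two genes.
#' @param start_atgl,start_acot7 First columns of the focal codons.
#' @param trees List of rooted `ape::phylo` trees (e.g. from
#'   [make_topology_variants()]).
#' @param model Nucleotide `subst_model`.
#' @param node Node to report: `"root"` (default) or an internal node id
#'   valid in every tree.
#' @return Object of class `robustness_report`: tibble with one row per
#'   usable tree (`tree`, `atgl_codon`, `atgl_pp`, `acot7_codon`,
#'   `acot7_pp`, `phenotype_class`).
#' @export
robustness_report <- function(aln_atgl, start_atgl, aln_acot7, start_acot7,
                              trees, model, node = "root") {
  rows <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    ok <- setequal(tr$tip.label, rownames(aln_atgl$seq)) &&
      setequal(tr$tip.label, rownames(aln_acot7$seq))
    if (!ok) {
      warn(paste0("tree ", i, " skipped: leaf set does not match alignments"))
      next
    }
    v <- if (identical(node, "root")) length(tr$tip.label) + 1L else as.integer(node)
    r1 <- reconstruct_codon(aln_atgl, start_atgl, tr, model)
    r2 <- reconstruct_codon(aln_acot7, start_acot7, tr, model)
    c1 <- r1$calls[r1$calls$node == v, ]
    c2 <- r2$calls[r2$calls$node == v, ]
    ph <- genotype_to_phenotype(c1$codon, c2$codon)
    rows[[length(rows) + 1]] <- tibble(
      tree = i, atgl_codon = c1$codon, atgl_pp = c1$pp,
      acot7_codon = c2$codon, acot7_pp = c2$pp,
      phenotype_class = ph$phenotype_class)
  }
  out <- bind_rows(rows)
  structure(list(results = out, n_trees = length(trees)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>", nrow(x$results), "of", x$n_trees,
      "trees evaluated\n")
  print(x$results)
  invisible(x)
}

#' @export
tidy.robustness_report <- function(x, ...) x$results

#' @export
glance.robustness_report <- function(x, ...) {
  tb <- table(as.character(x$results$phenotype_class))
  tibble(n_trees = x$n_trees,
         n_evaluated = nrow(x$results),
         modal_class = if (length(tb)) names(which.max(tb)) else NA_character_,
         n_agreeing = if (length(tb)) max(tb) else 0L)
}
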