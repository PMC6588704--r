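# Step 2 of the pipeline: observed vs neutrally expected convergent
# substitutions among foreground branches, with Poisson significance.
# "Convergent" pools parallel (same parent state) and convergent (different
# parent states) changes to the same derived state, per the cited method's
# headline usage.

#' Foreground branch pairs of a tree
#'
#' Foreground branches default to the terminal branches of the
#' flight-degenerate species; every unordered pair is evaluated. Branches
#' are identified by their child node; a pair in which one branch lies on
#' the root path of the other is rejected, since convergence on nested
#' branches is not independent.
#'
#' @param tree Rooted `ape::phylo`.
#' @param foreground Character vector of foreground tip labels, or integer
#'   child-node ids of foreground branches.
#' @return Tibble with columns `node1`, `node2` (child node ids).
#' @export
foreground_pairs <- function(tree, foreground) {
  nodes <- if (is.character(foreground)) {
    i <- match(foreground, tree$tip.label)
    if (anyNA(i)) abort("foreground species missing from tree")
    i
  } else as.integer(foreground)
  if (length(nodes) < 2) {
    return(tibble(node1 = integer(), node2 = integer()))
  }
  anc <- lapply(nodes, function(v) root_path(tree, v))
  pairs <- utils::combn(seq_along(nodes), 2)
  nested <- apply(pairs, 2, function(p) {
    nodes[p[1]] %in% anc[[p[2]]] || nodes[p[2]] %in% anc[[p[1]]]
  })
  if (any(nested)) {
    abort("nested foreground branch pair: one branch is ancestral to the other",
          class = "convflight_pair_error")
  }
  tibble(node1 = nodes[pairs[1, ]], node2 = nodes[pairs[2, ]])
}

# Nodes on the path from v (inclusive) to the root.
root_path <- function(tree, v) {
  path <- v
  repeat {
    e <- which(tree$edge[, 2] == v)
    if (length(e) == 0) break
    v <- tree$edge[e, 1]
    path <- c(path, v)
  }
  path
}

#' Neutrally expected number of convergent substitutions
#'
#' Under the reconstruction's posteriors, the expected number of events in
#' which both branches of a foreground pair independently substitute to the
#' same derived state, summed over sites, pairs and derived states:
#' for each branch the per-site probability of ending in state `d` after a
#' substitution is `sum_{i != d} post(parent = i) P(i -> d | t * r_s)`, with
#' `r_s` the site's posterior-mean relative rate.
#'
#' @param recon An [marginal_ancestral()] reconstruction.
#' @param pairs Tibble from [foreground_pairs()] (or a foreground species
#'   vector, converted internally).
#' @return Non-negative expectation, with attribute `"per_pair"`.
#' @export
expected_convergent_count <- function(recon, pairs) {
  tree <- recon$tree
  model <- recon$model
  if (!is.data.frame(pairs)) pairs <- foreground_pairs(tree, pairs)
  if (nrow(pairs) == 0) return(structure(0, per_pair = numeric(0)))
  k <- length(model$alphabet)
  branch_nodes <- sort(unique(c(pairs$node1, pairs$node2)))
  # per branch: k x sites matrix of P(substitute to d)
  subst_prob <- lapply(branch_nodes, function(v) {
    e <- which(tree$edge[, 2] == v)
    t_b <- tree$edge.length[e]
    par <- tree$edge[e, 1]
    post <- recon$posterior[[par]]
    out <- matrix(0, k, recon$n_sites)
    for (s in seq_len(recon$n_sites)) {
      P <- transition_matrix(model, t_b, recon$site_rate[s])
      out[, s] <- colSums(P * post[, s]) - post[, s] * diag(P)
    }
    out
  })
  names(subst_prob) <- branch_nodes
  per_pair <- vapply(seq_len(nrow(pairs)), function(i) {
    q1 <- subst_prob[[as.character(pairs$node1[i])]]
    q2 <- subst_prob[[as.character(pairs$node2[i])]]
    sum(q1 * q2)
  }, numeric(1))
  structure(sum(per_pair), per_pair = per_pair)
}

#' Per-site convergence expectation for one branch pair
#'
#' The elementary term of [expected_convergent_count()]: given the parent
#' posteriors and branch transition kernels of two branches, the probability
#' that both independently substitute to the same derived state,
#' `sum_d [sum_{i != d} post1_i P1_{id}] [sum_{j != d} post2_j P2_{jd}]`.
#'
#' @param post1,post2 Parent posterior state vectors.
#' @param P1,P2 Row-stochastic transition matrices for the two branches.
#' @return Non-negative per-site expectation.
#' @export
pair_expectation <- function(post1, P1, post2, P2) {
  q1 <- colSums(P1 * post1) - post1 * diag(P1)
  q2 <- colSums(P2 * post2) - post2 * diag(P2)
  sum(q1 * q2)
}

#' Observed number of convergent substitutions
#'
#' Assigns every internal node its maximum-posterior state (leaves keep
#' their observed states; missing leaves are skipped); a branch substitutes
#' when child and parent states differ, and a site counts once for every
#' foreground pair whose two branches both substitute to the same derived
#' state.
#'
#' @inheritParams expected_convergent_count
#' @return Integer count with attribute `"per_pair"`.
#' @export
observed_convergent_count <- function(recon, pairs) {
  tree <- recon$tree
  if (!is.data.frame(pairs)) pairs <- foreground_pairs(tree, pairs)
  if (nrow(pairs) == 0) return(structure(0L, per_pair = integer(0)))
  node_state <- recon$map_state
  node_state[seq_len(recon$n_tip), ] <- recon$leaf_idx  # observed, NA = missing
  state_of <- function(v) node_state[v, ]
  per_pair <- vapply(seq_len(nrow(pairs)), function(i) {
    v1 <- pairs$node1[i]; v2 <- pairs$node2[i]
    p1 <- tree$edge[tree$edge[, 2] == v1, 1]
    p2 <- tree$edge[tree$edge[, 2] == v2, 1]
    c1 <- state_of(v1); c2 <- state_of(v2)
    a1 <- state_of(p1); a2 <- state_of(p2)
    sum(!is.na(c1) & !is.na(c2) & c1 == c2 & c1 != a1 & c2 != a2)
  }, integer(1))
  structure(sum(per_pair), per_pair = per_pair)
}

#' Poisson tail significance of an observed convergence count
#'
#' `P(X >= observed)` for `X ~ Poisson(expected)`; an observed count of 0
#' always gives 1, and a positive count against a zero expectation gives 0
#' with a warning.
#'
#' @param observed Non-negative integer count.
#' @param expected Non-negative expectation.
#' @return Probability in `[0, 1]`.
#' @export
poisson_significance <- function(observed, expected) {
  if (observed < 0 || expected < 0) {
    abort("observed and expected must be non-negative",
          class = "convflight_domain_error")
  }
  if (observed == 0) return(1)
  if (expected == 0) {
    warn("positive observed count with zero expectation: p = 0")
    return(0)
  }
  ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Confirm candidate genes against the neutral convergence expectation
#'
#' For each gene carrying candidate sites, reconstructs ancestral states
#' under an empirical amino-acid (or supplied) model, counts observed and
#' neutrally expected convergent substitutions over all foreground branch
#' pairs, and retains the gene when the Poisson tail probability falls below
#' `alpha`.
#'
#' @param candidates Candidate tibble from [scan_alignment()]/[scan_genes()]
#'   (only `gene_id` is used), or a character vector of gene ids.
#' @param alignments Named list of `labeled_alignment` objects (names or
#'   `gene_id`s must cover the candidate genes). For the amino-acid test
#'   these should be protein alignments.
#' @param tree Rooted `ape::phylo` shared by all genes.
#' @param model A `subst_model`, or `NULL` to pick one from the alignment
#'   alphabet: JTT with gene-specific (+F) frequencies for amino acids, a
#'   frequency-matched one-rate (F81-style) model for nucleotides.
#' @param alpha Poisson significance level (default 0.01).
#' @param gamma_shape Discrete-gamma shape; `NULL` fits it per gene by
#'   maximum likelihood.
#' @param n_cat Number of gamma categories.
#' @param optimize_scale If `TRUE`, a global tree-scale factor is fitted per
#'   gene before reconstruction.
#' @return Object of class `conv_null_test` wrapping a tibble with columns
#'   `gene_id`, `observed`, `expected`, `p_poisson`, `pairs`, `retained`.
#' @export
confirm_candidates <- function(candidates, alignments, tree, model = NULL,
                               alpha = 0.01, gamma_shape = NULL, n_cat = 4L,
                               optimize_scale = FALSE) {
  genes <- if (is.character(candidates)) unique(candidates)
           else unique(candidates$gene_id)
  ids <- vapply(alignments, function(a) a$gene_id, character(1))
  if (is.null(names(alignments))) names(alignments) <- ids
  res <- lapply(genes, function(g) {
    aln <- alignments[[g]] %||% alignments[[match(g, ids)]]
    if (is.null(aln)) abort(paste0("no alignment for candidate gene ", g))
    m <- model %||% if (length(aln$alphabet) == 4) {
      model_gtr(freq = observed_frequencies(aln),
                gamma_shape = gamma_shape %||% 1, n_cat = n_cat)
    } else {
      model_jtt(freq = observed_frequencies(aln),
                gamma_shape = gamma_shape %||% 1, n_cat = n_cat)
    }
    tr <- tree
    if (optimize_scale) tr <- fit_tree_scale(aln, tr, m)$tree
    if (is.null(gamma_shape) && is.null(model)) {
      m <- fit_gamma_shape(aln, tr, m, n_cat = n_cat)$model
    }
    fg <- foreground_species(aln)
    pairs <- foreground_pairs(tr, fg)
    recon <- marginal_ancestral(aln, tr, m)
    obs <- observed_convergent_count(recon, pairs)
    exp_ <- expected_convergent_count(recon, pairs)
    tibble(gene_id = g, observed = as.integer(obs),
           expected = as.numeric(exp_),
           p_poisson = poisson_significance(as.integer(obs), as.numeric(exp_)),
           pairs = nrow(pairs))
  })
  out <- bind_rows(res) |>
    mutate(retained = .data$p_poisson < alpha)
  structure(list(results = out, alpha = alpha), class = "conv_null_test")
}

#' @export
print.conv_null_test <- function(x, ...) {
  cat("<conv_null_test> alpha =", x$alpha, "-", sum(x$results$retained),
      "of", nrow(x$results), "genes retained\n")
  print(x$results)
  invisible(x)
}

#' @export
tidy.conv_null_test <- function(x, ...) x$results

#' @export
glance.conv_null_test <- function(x, ...) {
  tibble(n_genes = nrow(x$results),
         n_retained = sum(x$results$retained),
         alpha = x$alpha,
         min_p = if (nrow(x$results)) min(x$results$p_poisson) else NA_real_)
}

#' Plot observed vs expected convergent substitutions per gene
#'
#' @param object A `conv_null_test`.
#' @param ... Unused.
#' @return A ggplot with the identity line; retained genes highlighted.
#' @export
autoplot.conv_null_test <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$expected, y = .data$observed,
                                 colour = .data$retained)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expected convergent substitutions (neutral)",
                  y = "observed convergent substitutions")
}
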