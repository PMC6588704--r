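# Alignment simulation along a tree under a reversible CTMC with
# discrete-gamma site rates, plus planted convergent substitutions in
# foreground species, and NNI topology variants for robustness runs.

#' Describe sites to plant with a convergent derived state
#'
#' @param site 1-based alignment columns (distinct).
#' @param state Derived state planted at each site.
#' @param carriers List (or single vector, recycled) of foreground species
#'   receiving the derived state.
#' @return A tibble with columns `site`, `state`, `carriers`.
#' @export
plant_spec <- function(site, state, carriers) {
  if (!is.list(carriers)) carriers <- list(carriers)
  tibble(site = as.integer(site), state = toupper(state),
         carriers = rep(carriers, length.out = length(site)))
}

#' Simulate a labeled alignment with optional planted convergence
#'
#' The root sequence is drawn from the model's stationary frequencies; each
#' site is assigned one of the discrete-gamma rate categories uniformly at
#' random and evolves down every branch by the transition kernel
#' `exp(Q * t * r)`. Planted sites are then overwritten with the derived
#' state in the listed carrier species (which must be foreground), and the
#' truth table records the simulated ancestral state at each planted site.
#' If the root happens to draw the derived state at a planted site, the root
#' state is redrawn among the remaining states so the plant is genuinely
#' derived. Uniform random missingness (as `N`/`X`) can be added; planted
#' carrier cells are never masked, so the truth table always matches the
#' emitted alignment.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param model A `subst_model`.
#' @param labels A `species_groups` table covering the tree's tips.
#' @param sites Number of alignment columns.
#' @param planted Optional [plant_spec()] tibble.
#' @param missing_fraction Fraction of (site, species) cells masked as missing.
#' @param seed Integer seed; identical inputs give identical output.
#' @param gene_id Gene identifier for the resulting alignment.
#' @return A list with elements `alignment` (a `labeled_alignment`) and
#'   `truth` (tibble: `site`, `ancestral`, `derived`, `carriers`).
#' @export
simulate_alignment <- function(tree, model, labels, sites,
                               planted = NULL, missing_fraction = 0,
                               seed = 1L, gene_id = "sim") {
  stopifnot(ape::is.rooted(tree), sites >= 1)
  if (missing_fraction < 0 || missing_fraction > 1) {
    abort("missing_fraction must be in [0, 1]")
  }
  if (!is.null(planted)) {
    if (anyDuplicated(planted$site)) abort("planted sites must be distinct")
    if (any(planted$site < 1 | planted$site > sites)) {
      abort("planted sites must lie in 1..sites")
    }
    fg <- foreground_species(labels)
    extra <- setdiff(unlist(planted$carriers), fg)
    if (length(extra) > 0) {
      abort(paste0("carriers must be foreground species; not foreground: ",
                   paste(extra, collapse = ", ")))
    }
    if (any(!planted$state %in% model$alphabet)) {
      abort("planted derived state not in model alphabet")
    }
  }
  set.seed(seed)
  k <- length(model$alphabet)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cat_of_site <- sample.int(length(model$rates), sites, replace = TRUE)
  states <- matrix(NA_integer_, n_node, sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(k, sites, replace = TRUE, prob = model$freq)
  if (!is.null(planted)) {
    # redraw root where it coincides with the planted derived state
    for (r in seq_len(nrow(planted))) {
      s <- planted$site[r]
      d <- match(planted$state[r], model$alphabet)
      if (states[root, s] == d) {
        p <- model$freq
        p[d] <- 0
        states[root, s] <- sample.int(k, 1, prob = p / sum(p))
      }
    }
  }
  # parent-before-child traversal
  edges <- reorder(tree, "postorder")$edge
  lens <- reorder(tree, "postorder")$edge.length
  ord <- rev(seq_len(nrow(edges)))
  kernels <- function(t) lapply(model$rates, function(r) transition_matrix(model, t, r))
  for (e in ord) {
    par <- edges[e, 1]; chd <- edges[e, 2]
    Ps <- kernels(lens[e])
    if (any(vapply(Ps, function(P) any(!is.finite(P)), logical(1)))) {
      abort("non-stochastic transition kernel", class = "convflight_model_error")
    }
    child_state <- integer(sites)
    for (cc in seq_along(model$rates)) {
      P <- Ps[[cc]]
      for (s in seq_len(k)) {
        idx <- which(cat_of_site == cc & states[par, ] == s)
        if (length(idx) > 0) {
          child_state[idx] <- sample.int(k, length(idx), replace = TRUE,
                                         prob = P[s, ])
        }
      }
    }
    states[chd, ] <- child_state
  }
  mat <- matrix(model$alphabet[states[seq_len(n_tip), , drop = FALSE]],
                n_tip, sites)
  rownames(mat) <- tree$tip.label
  truth <- tibble(site = integer(), ancestral = character(),
                  derived = character(), carriers = list())
  protected <- matrix(FALSE, n_tip, sites, dimnames = list(tree$tip.label, NULL))
  if (!is.null(planted)) {
    for (r in seq_len(nrow(planted))) {
      s <- planted$site[r]
      carr <- planted$carriers[[r]]
      mat[carr, s] <- planted$state[r]
      protected[carr, s] <- TRUE
      truth <- bind_rows(truth, tibble(
        site = planted$site[r],
        ancestral = model$alphabet[states[root, s]],
        derived = planted$state[r],
        carriers = list(carr)))
    }
  }
  if (missing_fraction > 0) {
    miss_char <- if (length(model$alphabet) == 4) "N" else "X"
    mask <- matrix(runif(n_tip * sites) < missing_fraction, n_tip, sites)
    mask[protected] <- FALSE
    mat[mask] <- miss_char
  }
  list(alignment = labeled_alignment(mat, labels, gene_id = gene_id,
                                     alphabet = model$alphabet),
       truth = truth)
}

#' Generate topology variants by NNI around weak internal branches
#'
#' For each listed internal branch the tree may keep its arrangement or take
#' either of the branch's two nearest-neighbour-interchange rearrangements;
#' combinations over all weak branches are enumerated, duplicates (by
#' unrooted topology) dropped, and `k` distinct trees returned with the
#' original always first. This emulates generating alternative resolutions
#' of poorly supported branches.
#'
#' @param tree Rooted binary `ape::phylo`.
#' @param weak_edges Indices into `tree$edge` rows whose child is an internal
#'   node (the branches considered unresolved).
#' @param k Number of distinct topologies wanted (including the original).
#' @param seed Seed controlling which combinations are kept when more than
#'   `k` exist.
#' @return List of `phylo` trees, length `min(k, n_distinct)`; warns when
#'   fewer distinct topologies exist than requested.
#' @export
make_topology_variants <- function(tree, weak_edges, k, seed = 1L) {
  stopifnot(k >= 1)
  n_tip <- length(tree$tip.label)
  if (length(weak_edges) == 0) {
    if (k > 1) warn("no weak branches: only the original topology exists")
    return(list(tree))
  }
  if (any(tree$edge[weak_edges, 2] <= n_tip)) {
    abort("weak_edges must be internal branches (child is an internal node)")
  }
  choices <- expand.grid(rep(list(0:2), length(weak_edges)))
  choices <- choices[order(rowSums(choices != 0)), , drop = FALSE]
  cand <- lapply(seq_len(nrow(choices)), function(i) {
    tr <- tree
    for (j in seq_along(weak_edges)) {
      mv <- choices[i, j]
      if (mv > 0) tr <- nni_at_edge(tr, weak_edges[j], mv)
    }
    tr
  })
  keep <- list(cand[[1]])
  for (tr in cand[-1]) {
    dup <- any(vapply(keep, function(x)
      phangorn::RF.dist(ape::unroot(x), ape::unroot(tr)) == 0, logical(1)))
    if (!dup) keep <- c(keep, list(tr))
  }
  if (length(keep) < k) {
    warn(paste0("only ", length(keep), " distinct topologies exist (requested ",
                k, ")"))
    return(keep)
  }
  if (length(keep) > k) {
    set.seed(seed)
    keep <- c(keep[1], keep[1 + sample(length(keep) - 1, k - 1)])
  }
  keep
}

# One NNI rearrangement around internal edge e of a rooted binary tree:
# swaps the edge's sibling subtree with the first (which = 1) or second
# (which = 2) child subtree of the edge's lower node.
nni_at_edge <- function(tree, e, which = 1) {
  edge <- tree$edge
  u <- edge[e, 1]; v <- edge[e, 2]
  ch_rows <- which(edge[, 1] == v)
  sib_rows <- setdiff(which(edge[, 1] == u), e)
  if (length(ch_rows) != 2 || length(sib_rows) != 1) {
    abort("NNI requires a binary tree around the chosen edge")
  }
  c_row <- ch_rows[which]
  s_row <- sib_rows[1]
  edge[s_row, 1] <- v
  edge[c_row, 1] <- u
  tree$edge <- edge
  reorder(tree, "cladewise")
}
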