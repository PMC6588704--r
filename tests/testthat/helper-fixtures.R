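# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own pruning/transition code paths: transition kernels come from
# Matrix::expm and likelihoods from exhaustive enumeration over ancestral
# state assignments, so they can validate the implementation.

two_state_model <- function(freq = c(0.5, 0.5), gamma_shape = NULL) {
  model_binary(freq = freq, gamma_shape = gamma_shape)
}

make_labels <- function(species, n_fg) {
  group_labels(species, c(rep("flight_degenerate", n_fg),
                          rep("flying", length(species) - n_fg)))
}

aln_from_strings <- function(seqs, labels, alphabet = NULL, gene_id = "g") {
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  labeled_alignment(mat, labels, gene_id = gene_id, alphabet = alphabet)
}

# Phylogenetically scattered foreground: greedy max-min patristic distance,
# so no two foreground tips are sisters (mirrors the scattered distribution
# of flight-degenerate species across the avian tree).
scatter_foreground <- function(tree, n_fg) {
  d <- ape::cophenetic.phylo(tree)
  sel <- rownames(d)[which.max(rowSums(d))[1]]
  while (length(sel) < n_fg) {
    rest <- setdiff(rownames(d), sel)
    mind <- vapply(rest, function(t) min(d[t, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)[1]])
  }
  sort(sel)
}

labels_for_tree <- function(tree, fg) {
  group_labels(tree$tip.label,
               ifelse(tree$tip.label %in% fg, "flight_degenerate", "flying"))
}

# Independent transition kernel: matrix exponential via Matrix::expm.
oracle_kernel <- function(model, t, rate = 1) {
  as.matrix(Matrix::expm(model$Q * t * rate))
}

# Exhaustive-enumeration site likelihood on a small rooted tree (any number
# of states, one rate category). tip_states: named vector of state indices
# (NA = missing).
oracle_site_lik <- function(tree, model, tip_states, rate = 1) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  k <- length(model$alphabet)
  internal <- (n_tip + 1):n_node
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) oracle_kernel(model, tree$edge.length[e], rate))
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(internal)))
  obs <- tip_states[tree$tip.label]
  total <- 0
  for (i in seq_len(nrow(grid))) {
    assign_ <- unlist(grid[i, ])
    state_of <- function(v) {
      if (v <= n_tip) obs[v] else assign_[v - n_tip]
    }
    pr <- model$freq[assign_[1]]  # node n_tip+1 is the root
    for (e in seq_len(nrow(tree$edge))) {
      par <- state_of(tree$edge[e, 1])
      chd <- state_of(tree$edge[e, 2])
      if (is.na(chd)) next      # missing tip: marginalise by summing later
      pr <- pr * Ps[[e]][par, chd]
    }
    # handle missing tips by explicit marginalisation
    miss <- which(is.na(obs))
    if (length(miss) > 0) {
      for (v in miss) {
        e <- which(tree$edge[, 2] == v)
        par <- state_of(tree$edge[e, 1])
        pr <- pr * sum(Ps[[e]][par, ])
      }
    }
    total <- total + pr
  }
  total
}

# Gamma-mixture oracle likelihood (equal-weight categories).
oracle_site_lik_mix <- function(tree, model, tip_states) {
  mean(vapply(model$rates,
              function(r) oracle_site_lik(tree, model, tip_states, r),
              numeric(1)))
}

# Brute-force marginal posterior at one internal node.
oracle_posterior <- function(tree, model, tip_states, node, rate = 1) {
  n_tip <- length(tree$tip.label)
  k <- length(model$alphabet)
  num <- vapply(seq_len(k), function(s) {
    oracle_site_lik_conditioned(tree, model, tip_states, node, s, rate)
  }, numeric(1))
  num / sum(num)
}

oracle_site_lik_conditioned <- function(tree, model, tip_states, node, state,
                                        rate = 1) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  k <- length(model$alphabet)
  internal <- (n_tip + 1):n_node
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) oracle_kernel(model, tree$edge.length[e], rate))
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(internal)))
  grid <- grid[grid[, node - n_tip] == state, , drop = FALSE]
  obs <- tip_states[tree$tip.label]
  total <- 0
  for (i in seq_len(nrow(grid))) {
    assign_ <- unlist(grid[i, ])
    state_of <- function(v) if (v <= n_tip) obs[v] else assign_[v - n_tip]
    pr <- model$freq[assign_[1]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- state_of(tree$edge[e, 1])
      chd <- state_of(tree$edge[e, 2])
      if (is.na(chd)) {
        pr <- pr * sum(Ps[[e]][par, ])
      } else {
        pr <- pr * Ps[[e]][par, chd]
      }
    }
    total <- total + pr
  }
  total
}

# Brute-force two-sided Fisher p by full table enumeration.
oracle_fisher <- function(a, fg_t, b, bg_t) {
  m <- a + b
  probs <- vapply(0:m, function(k) {
    if (k > fg_t || (m - k) > bg_t) return(0)
    choose(fg_t, k) * choose(bg_t, m - k) / choose(fg_t + bg_t, m)
  }, numeric(1))
  d_obs <- probs[a + 1]
  sum(probs[probs <= d_obs * (1 + 1e-7)])
}

# A reproducible random rooted binary tree with moderate branch lengths.
random_tree <- function(n_tip, seed, min_len = 0.05, max_len = 0.3) {
  set.seed(seed)
  tr <- ape::rtree(n_tip, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr
}
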