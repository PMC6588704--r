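# Felsenstein pruning and marginal ancestral reconstruction under a
# reversible model with discrete-gamma rate categories. All passes are
# column-scaled to avoid underflow; likelihoods are kept in log space.

# Encode an alignment as a state-index matrix aligned to the tree's tips.
encode_alignment <- function(aln, tree, model) {
  validate_inputs(aln, tree)
  m <- aln$seq[tree$tip.label, , drop = FALSE]
  idx <- match(m, model$alphabet)
  dim(idx) <- dim(m)
  idx[m %in% missing_chars(model$alphabet)] <- NA_integer_
  bad <- is.na(idx) & !(m %in% missing_chars(model$alphabet))
  if (any(bad)) {
    abort(paste0("characters outside model alphabet: ",
                 paste(unique(m[bad]), collapse = ", ")),
          class = "convflight_input_error")
  }
  idx
}

# Lower (pruning) pass for one rate category. Returns per-node scaled
# conditionals, per-node accumulated log scalers, per-site log-likelihood,
# and the child->parent messages needed by the outside pass.
peel_category <- function(idx, tree, model, rate) {
  k <- length(model$alphabet)
  n_tip <- nrow(idx)
  n_sites <- ncol(idx)
  n_node <- n_tip + tree$Nnode
  po <- reorder(tree, "postorder")
  edges <- po$edge
  lens <- po$edge.length
  L <- vector("list", n_node)
  logsc <- matrix(0, n_node, n_sites)
  msg <- vector("list", n_node)      # message from node (as child) to parent
  Pmat <- vector("list", n_node)     # kernel on the branch above each node
  for (tip in seq_len(n_tip)) {
    Li <- matrix(0, k, n_sites)
    obs <- idx[tip, ]
    known <- !is.na(obs)
    Li[cbind(obs[known], which(known))] <- 1
    Li[, !known] <- 1
    L[[tip]] <- Li
  }
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; chd <- edges[e, 2]
    P <- transition_matrix(model, lens[e], rate)
    Pmat[[chd]] <- P
    M <- P %*% L[[chd]]
    msg[[chd]] <- M
    if (is.null(L[[par]])) {
      L[[par]] <- M
      logsc[par, ] <- logsc[chd, ]
    } else {
      L[[par]] <- L[[par]] * M
      logsc[par, ] <- logsc[par, ] + logsc[chd, ]
    }
    # rescale the parent's partial product as it grows
    cm <- apply(L[[par]], 2, max)
    cm[cm == 0] <- 1
    L[[par]] <- sweep(L[[par]], 2, cm, "/")
    logsc[par, ] <- logsc[par, ] + log(cm)
  }
  root <- n_tip + 1L
  site_loglik <- log(colSums(model$freq * L[[root]])) + logsc[root, ]
  list(L = L, logsc = logsc, msg = msg, P = Pmat,
       site_loglik = site_loglik, edges = edges)
}

#' Per-site log-likelihood by Felsenstein pruning
#'
#' Computes per-site log-likelihoods of an alignment on a rooted tree under
#' a reversible substitution model, averaging over the model's equal-weight
#' discrete-gamma rate categories.
#'
#' @param aln A `labeled_alignment` (leaf set must match the tree).
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param model A `subst_model`.
#' @return Numeric vector of per-site log-likelihoods, with attribute
#'   `"total"` (their sum) and `"by_category"` (sites x categories matrix of
#'   per-category log-likelihoods).
#' @export
prune_likelihood <- function(aln, tree, model) {
  idx <- encode_alignment(aln, tree, model)
  percat <- vapply(model$rates,
                   function(r) peel_category(idx, tree, model, r)$site_loglik,
                   numeric(ncol(idx)))
  percat <- matrix(percat, ncol = length(model$rates))
  mx <- apply(percat, 1, max)
  ll <- mx + log(rowMeans(exp(percat - mx)))
  attr(ll, "total") <- sum(ll)
  attr(ll, "by_category") <- percat
  ll
}

#' Fit a single tree-scale factor by maximum likelihood
#'
#' Maximises the pruning likelihood over a global multiplier of all branch
#' lengths (golden-section/parabolic search), a light-weight alternative to
#' full per-branch optimisation when branch lengths come from an external
#' tree whose overall rate may not match the gene.
#'
#' @inheritParams prune_likelihood
#' @param interval Search interval for the scale factor.
#' @return List with `scale`, the rescaled `tree`, and `loglik`.
#' @export
fit_tree_scale <- function(aln, tree, model, interval = c(1e-3, 30)) {
  f <- function(s) {
    tr <- tree
    tr$edge.length <- tr$edge.length * s
    -attr(prune_likelihood(aln, tr, model), "total")
  }
  opt <- optimize(f, interval)
  tree$edge.length <- tree$edge.length * opt$minimum
  list(scale = opt$minimum, tree = tree, loglik = -opt$objective)
}

#' Fit the discrete-gamma shape by maximum likelihood
#'
#' @inheritParams prune_likelihood
#' @param n_cat Number of discrete categories.
#' @param interval Search interval for the shape.
#' @return List with `shape`, the refitted `model`, and `loglik`.
#' @export
fit_gamma_shape <- function(aln, tree, model, n_cat = 4L,
                            interval = c(0.05, 50)) {
  rebuild <- function(shape) {
    m <- model
    m$gamma_shape <- shape
    m$rates <- phangorn::discrete.gamma(shape, n_cat)
    m
  }
  f <- function(shape) -attr(prune_likelihood(aln, tree, rebuild(shape)), "total")
  opt <- optimize(f, interval)
  list(shape = opt$minimum, model = rebuild(opt$minimum),
       loglik = -opt$objective)
}

#' Marginal ancestral reconstruction
#'
#' Computes, for every node and site, the marginal posterior distribution
#' over states by an inside-outside pass per rate category, then mixes the
#' categories weighted by each category's per-site likelihood. Also returns
#' the posterior-mean relative rate of every site and maximum-posterior
#' state calls (ties broken by alphabet order and flagged).
#'
#' @inheritParams prune_likelihood
#' @return Object of class `ancestral_recon`: list with `posterior` (list of
#'   state x site matrices, one per node; leaves included), `map_state`
#'   (node x site matrix of state indices), `tie` (logical matrix of
#'   posterior ties), `site_rate` (posterior-mean relative rate per site),
#'   `site_loglik`, plus the `tree`, `model` and alignment dimensions.
#' @export
marginal_ancestral <- function(aln, tree, model) {
  idx <- encode_alignment(aln, tree, model)
  k <- length(model$alphabet)
  n_tip <- nrow(idx)
  n_sites <- ncol(idx)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  ncat <- length(model$rates)
  peels <- lapply(model$rates, function(r) peel_category(idx, tree, model, r))
  percat <- vapply(peels, `[[`, numeric(n_sites), "site_loglik")
  percat <- matrix(percat, ncol = ncat)
  mx <- apply(percat, 1, max)
  w <- exp(percat - mx)
  w <- w / rowSums(w)                       # site x category posterior weights
  site_rate <- as.numeric(w %*% model$rates)
  site_loglik <- mx + log(rowMeans(exp(percat - mx)))

  posterior <- lapply(seq_len(n_node), function(i) matrix(0, k, n_sites))
  for (cc in seq_len(ncat)) {
    pc <- peels[[cc]]
    edges <- pc$edges
    U <- vector("list", n_node)
    U[[root]] <- matrix(model$freq, k, n_sites)
    # parent-before-child traversal of the postorder edge list, reversed
    children_of <- split(seq_len(nrow(edges)), edges[, 1])
    for (e in rev(seq_len(nrow(edges)))) {
      par <- edges[e, 1]; chd <- edges[e, 2]
      sibs <- setdiff(children_of[[as.character(par)]], e)
      prodM <- U[[par]]
      for (se in sibs) prodM <- prodM * pc$msg[[edges[se, 2]]]
      Uv <- t(pc$P[[chd]]) %*% prodM
      cm <- apply(Uv, 2, max)
      cm[cm == 0] <- 1
      U[[chd]] <- sweep(Uv, 2, cm, "/")
    }
    for (v in seq_len(n_node)) {
      F_ <- U[[v]] * pc$L[[v]]
      tot <- colSums(F_)
      tot[tot == 0] <- 1
      F_ <- sweep(F_, 2, tot, "/")
      posterior[[v]] <- posterior[[v]] + F_ * rep(w[, cc], each = k)
    }
  }
  map_state <- matrix(0L, n_node, n_sites)
  tie <- matrix(FALSE, n_node, n_sites)
  for (v in seq_len(n_node)) {
    p <- posterior[[v]]
    map_state[v, ] <- apply(p, 2, which.max)  # first max = alphabet order
    tie[v, ] <- apply(p, 2, function(col) sum(col >= max(col) - 1e-12) > 1)
  }
  structure(
    list(posterior = posterior, map_state = map_state, tie = tie,
         site_rate = site_rate, site_loglik = site_loglik,
         tree = tree, model = model, n_tip = n_tip, n_sites = n_sites,
         leaf_idx = idx),
    class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("<ancestral_recon>", x$n_tip, "tips,", x$tree$Nnode, "internal nodes,",
      x$n_sites, "sites; total log-likelihood",
      signif(sum(x$site_loglik), 8), "\n")
  invisible(x)
}

#' Tidy an ancestral reconstruction into a long tibble
#'
#' @param x An `ancestral_recon`.
#' @param nodes Node numbers to include (default: internal nodes).
#' @param ... Unused.
#' @return Tibble with columns `node`, `site`, `state`, `posterior`,
#'   `map` (is this the maximum-posterior state).
#' @export
tidy.ancestral_recon <- function(x, nodes = NULL, ...) {
  nodes <- nodes %||% (x$n_tip + seq_len(x$tree$Nnode))
  bind_rows(lapply(nodes, function(v) {
    p <- x$posterior[[v]]
    tibble(node = v,
           site = rep(seq_len(x$n_sites), each = length(x$model$alphabet)),
           state = rep(x$model$alphabet, x$n_sites),
           posterior = as.vector(p)) |>
      group_by(.data$site) |>
      mutate(map = .data$posterior == max(.data$posterior)) |>
      ungroup()
  }))
}
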