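# Reversible substitution models with discrete-gamma rate heterogeneity.
# Q is always rescaled to one expected substitution per unit time at
# stationarity, so branch lengths are in expected substitutions per site.

#' Construct a reversible substitution model
#'
#' Builds a continuous-time Markov model from symmetric exchangeabilities and
#' stationary frequencies, normalised so that branch lengths are expected
#' substitutions per site. Rate heterogeneity across sites uses the standard
#' discrete-gamma approximation: `n_cat` equal-weight categories whose rates
#' are the means of the gamma quantile slices (mean rate 1).
#'
#' @param alphabet Character vector of states.
#' @param exchangeability Symmetric non-negative matrix of exchange rates
#'   (diagonal ignored), or `NULL` for all-equal exchangeabilities.
#' @param freq Stationary frequencies (positive, summing to 1); default
#'   uniform.
#' @param gamma_shape Shape of the gamma rate distribution, or `NULL` for a
#'   single rate category.
#' @param n_cat Number of discrete gamma categories (default 4).
#' @return An object of class `subst_model` with the normalised rate matrix
#'   `Q`, frequencies `freq`, category rates `rates` and a cached spectral
#'   decomposition used by [transition_matrix()].
#' @export
subst_model <- function(alphabet, exchangeability = NULL, freq = NULL,
                        gamma_shape = NULL, n_cat = 4L) {
  k <- length(alphabet)
  if (is.null(exchangeability)) {
    exchangeability <- matrix(1, k, k)
  }
  stopifnot(nrow(exchangeability) == k, ncol(exchangeability) == k)
  if (any(exchangeability[upper.tri(exchangeability)] < 0)) {
    abort("exchangeabilities must be non-negative", class = "convflight_model_error")
  }
  freq <- freq %||% rep(1 / k, k)
  if (any(freq <= 0) || abs(sum(freq) - 1) > 1e-8) {
    abort("frequencies must be positive and sum to 1",
          class = "convflight_model_error")
  }
  freq <- freq / sum(freq)
  R <- (exchangeability + t(exchangeability)) / 2
  diag(R) <- 0
  Q <- R %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))          # expected rate at stationarity
  if (mu <= 0) abort("degenerate rate matrix", class = "convflight_model_error")
  Q <- Q / mu
  # reversible Q: symmetrise with sqrt(pi) for a stable eigendecomposition
  sp <- sqrt(freq)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (is.null(gamma_shape)) {
    rates <- 1
  } else {
    rates <- phangorn::discrete.gamma(gamma_shape, n_cat)
  }
  structure(
    list(alphabet = alphabet, Q = Q, freq = freq,
         gamma_shape = gamma_shape, rates = rates,
         eig = list(values = eig$values,
                    vectors = eig$vectors, sp = sp)),
    class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model>", length(x$alphabet), "states;",
      length(x$rates), "rate categor",
      if (length(x$rates) == 1) "y" else "ies",
      if (!is.null(x$gamma_shape)) paste0("(gamma shape ", signif(x$gamma_shape, 4), ")"),
      "\n")
  invisible(x)
}

#' Transition probability matrix exp(Q t r)
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site at rate 1).
#' @param rate Relative rate multiplier.
#' @return Row-stochastic transition matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  tt <- t * rate
  if (tt < 0) abort("negative evolutionary time", class = "convflight_model_error")
  e <- model$eig
  P <- e$vectors %*% (exp(e$values * tt) * t(e$vectors))
  P <- (1 / e$sp) * P * rep(e$sp, each = length(e$sp))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Jukes-Cantor nucleotide model
#' @inheritParams subst_model
#' @return A `subst_model` over `A,C,G,T`.
#' @export
model_jc <- function(gamma_shape = NULL, n_cat = 4L) {
  subst_model(c("A", "C", "G", "T"), gamma_shape = gamma_shape, n_cat = n_cat)
}

#' General time-reversible nucleotide model
#'
#' @param rates Six exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @param freq Stationary base frequencies (A, C, G, T).
#' @inheritParams subst_model
#' @return A `subst_model`.
#' @export
model_gtr <- function(rates = rep(1, 6), freq = rep(0.25, 4),
                      gamma_shape = NULL, n_cat = 4L) {
  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- rates
  subst_model(c("A", "C", "G", "T"), R, freq,
              gamma_shape = gamma_shape, n_cat = n_cat)
}

#' JTT amino-acid model, optionally with observed (+F) frequencies
#'
#' Uses the Jones-Taylor-Thornton empirical exchangeability matrix as bundled
#' with phangorn. With `freq = NULL` the JTT stationary frequencies are used;
#' supplying the frequencies observed in a gene gives the "+F" variant.
#'
#' @param freq Amino-acid frequencies in the order
#'   `A R N D C Q E G H I L K M F P S T W Y V`, or `NULL` for JTT defaults.
#' @inheritParams subst_model
#' @return A `subst_model` over the 20 amino acids.
#' @export
model_jtt <- function(freq = NULL, gamma_shape = NULL, n_cat = 4L) {
  jtt <- get(".JTT", envir = environment(phangorn::pml))
  R <- matrix(0, 20, 20)
  R[lower.tri(R)] <- jtt$Q
  subst_model(AA_ALPHABET, R, freq %||% unname(jtt$bf),
              gamma_shape = gamma_shape, n_cat = n_cat)
}

#' Two-state symmetric model (mainly for exact small-case checks)
#' @inheritParams subst_model
#' @return A `subst_model` over states `0`, `1`.
#' @export
model_binary <- function(freq = c(0.5, 0.5), gamma_shape = NULL, n_cat = 4L) {
  subst_model(c("0", "1"), freq = freq, gamma_shape = gamma_shape, n_cat = n_cat)
}

#' Observed residue frequencies of an alignment (for "+F" models)
#'
#' Missing characters are ignored; a small pseudo-count keeps every state's
#' frequency positive so the rate matrix stays irreducible.
#'
#' @param aln A `labeled_alignment`.
#' @param pseudo Pseudo-count added to each state.
#' @return Frequency vector over `aln$alphabet`.
#' @export
observed_frequencies <- function(aln, pseudo = 0.5) {
  counts <- table(factor(as.vector(aln$seq), levels = aln$alphabet))
  f <- as.numeric(counts) + pseudo
  f / sum(f)
}
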