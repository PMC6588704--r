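# Step 1 of the convergence pipeline: per-site two-group frequency spectrum,
# foreground-sharing rule and Fisher's exact test.

#' Per-site two-group frequency spectrum
#'
#' Tallies, for every alignment column and residue state, how many foreground
#' (flight-degenerate) and background (flying) species carry that state.
#' Missing characters are excluded from both the counts and the per-site
#' denominators. The summed (foreground, background) cell tallies give the
#' two-dimensional frequency spectrum used to visualise group-specific
#' fixation.
#'
#' @param aln A `labeled_alignment`.
#' @return A tibble of class `site_spectrum` with columns `site`, `state`,
#'   `fg_count`, `bg_count`, `fg_total`, `bg_total` (totals are non-missing
#'   species at that site). Rows with zero counts in both groups are dropped.
#' @export
site_spectrum <- function(aln) {
  if (n_sites(aln) == 0) abort("alignment has no sites")
  fg <- aln$groups$group == "flight_degenerate"
  miss <- missing_chars(aln$alphabet)
  m <- aln$seq
  ok <- !(m %in% miss)
  dim(ok) <- dim(m)
  fg_tot <- colSums(ok[fg, , drop = FALSE])
  bg_tot <- colSums(ok[!fg, , drop = FALSE])
  per_state <- lapply(aln$alphabet, function(s) {
    is_s <- m == s
    dim(is_s) <- dim(m)
    tibble(site = seq_len(ncol(m)), state = s,
           fg_count = colSums(is_s[fg, , drop = FALSE]),
           bg_count = colSums(is_s[!fg, , drop = FALSE]))
  })
  out <- bind_rows(per_state) |>
    mutate(fg_total = fg_tot[.data$site], bg_total = bg_tot[.data$site]) |>
    filter(.data$fg_count > 0 | .data$bg_count > 0) |>
    arrange(.data$site, .data$state)
  class(out) <- c("site_spectrum", class(out))
  out
}

#' Two-dimensional frequency-spectrum histogram
#'
#' Collapses a [site_spectrum()] into counts of (foreground carriers,
#' background carriers) cells across all sites and states.
#'
#' @param spectrum A `site_spectrum`.
#' @return Tibble with columns `fg_count`, `bg_count`, `n_loci`.
#' @export
spectrum_histogram <- function(spectrum) {
  spectrum |>
    dplyr::count(.data$fg_count, .data$bg_count, name = "n_loci")
}

#' Plot the two-dimensional frequency spectrum
#'
#' @param object A `site_spectrum`.
#' @param ... Unused.
#' @return A ggplot: foreground vs background carrier counts, tiles coloured
#'   by the (log10) number of loci.
#' @export
autoplot.site_spectrum <- function(object, ...) {
  spectrum_histogram(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$fg_count, y = .data$bg_count,
                                 fill = log10(.data$n_loci))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 loci") +
    ggplot2::labs(x = "carriers among flight-degenerate species",
                  y = "carriers among flying species")
}

#' Two-sided Fisher's exact test for one site
#'
#' Exact two-sided p-value for the 2x2 table
#' `[[fg_carriers, fg_total - fg_carriers], [bg_carriers, bg_total - bg_carriers]]`,
#' computed by hypergeometric enumeration: the sum of the probabilities of
#' all tables with the observed margins whose point probability does not
#' exceed that of the observed table. Vectorised over its arguments.
#'
#' @param fg_carriers,fg_total Carrier count and non-missing total in the
#'   foreground group.
#' @param bg_carriers,bg_total Same for the background group.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_site_test <- function(fg_carriers, fg_total, bg_carriers, bg_total) {
  n <- max(length(fg_carriers), length(bg_carriers))
  a <- rep_len(as.integer(fg_carriers), n)
  fg_t <- rep_len(as.integer(fg_total), n)
  b <- rep_len(as.integer(bg_carriers), n)
  bg_t <- rep_len(as.integer(bg_total), n)
  if (any(a < 0 | b < 0 | fg_t < 1 | bg_t < 1)) {
    abort("counts must be non-negative with totals >= 1",
          class = "convflight_domain_error")
  }
  if (any(a > fg_t | b > bg_t)) {
    abort("carriers cannot exceed totals", class = "convflight_domain_error")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]                       # total carriers
    lo <- max(0L, m - bg_t[i])
    hi <- min(m, fg_t[i])
    kk <- lo:hi
    d <- dhyper(kk, fg_t[i], bg_t[i], m)
    d_obs <- d[match(a[i], kk)]
    min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Scan an alignment for convergent candidate sites
#'
#' For each column the candidate state is the state with the largest number
#' of foreground carriers (ties broken by alphabet order and flagged). A site
#' is reported when the candidate state is shared by at least `min_shared`
#' foreground species and the two-group frequency difference is significant
#' by Fisher's exact test at level `alpha`. Species with missing data at a
#' site are excluded from that site's table, but the sharing threshold still
#' counts carriers against the full foreground size.
#'
#' @param aln A `labeled_alignment`.
#' @param min_shared Minimum foreground carriers (default 7, matching an
#'   8-species foreground; use 10 for a ~16-species replication design).
#' @param alpha Significance level for the Fisher test (default 0.001).
#' @return Tibble of candidate sites: `gene_id`, `site`, `state`,
#'   `fg_carriers`, `fg_total`, `bg_carriers`, `bg_total`, `p_fisher`,
#'   `tie_flag`.
#' @export
scan_alignment <- function(aln, min_shared = 7L, alpha = 1e-3) {
  n_fg <- sum(aln$groups$group == "flight_degenerate")
  if (min_shared > n_fg) {
    abort("min_shared exceeds the number of foreground species")
  }
  spec <- site_spectrum(aln)
  cand <- spec |>
    group_by(.data$site) |>
    arrange(.data$state, .by_group = TRUE) |>
    summarise(
      state = .data$state[which.max(.data$fg_count)],
      tie_flag = sum(.data$fg_count == max(.data$fg_count)) > 1,
      fg_carriers = max(.data$fg_count),
      bg_carriers = .data$bg_count[which.max(.data$fg_count)],
      fg_total = .data$fg_total[1], bg_total = .data$bg_total[1],
      .groups = "drop") |>
    filter(.data$fg_carriers >= min_shared,
           .data$fg_total >= 1, .data$bg_total >= 1)
  if (nrow(cand) == 0) {
    return(tibble(gene_id = character(), site = integer(), state = character(),
                  fg_carriers = integer(), fg_total = integer(),
                  bg_carriers = integer(), bg_total = integer(),
                  p_fisher = numeric(), tie_flag = logical()))
  }
  cand |>
    mutate(p_fisher = fisher_site_test(.data$fg_carriers, .data$fg_total,
                                       .data$bg_carriers, .data$bg_total),
           gene_id = aln$gene_id) |>
    filter(.data$p_fisher < alpha) |>
    select("gene_id", "site", "state", "fg_carriers", "fg_total",
           "bg_carriers", "bg_total", "p_fisher", "tie_flag")
}

#' Scan a set of gene alignments
#'
#' @param alignments List of `labeled_alignment` objects.
#' @inheritParams scan_alignment
#' @return Row-bound candidate table across genes.
#' @export
scan_genes <- function(alignments, min_shared = 7L, alpha = 1e-3) {
  bind_rows(lapply(alignments, scan_alignment,
                   min_shared = min_shared, alpha = alpha))
}
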