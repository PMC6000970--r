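#' Tidy an AMOVA result
#'
#' @param x A `pvp_amova` object.
#' @param ... Unused.
#' @return Tibble of the hierarchical levels (label, df, SS, MS, est_var,
#'   pct).
#' @export
tidy.pvp_amova <- function(x, ...) x$levels

#' @rdname tidy.pvp_amova
#' @export
glance.pvp_amova <- function(x, ...) {
  tibble(
    phi_CT = x$phi$value[x$phi$statistic == "Phi_CT"],
    phi_IS = x$phi$value[x$phi$statistic == "Phi_IS"],
    phi_IT = x$phi$value[x$phi$statistic == "Phi_IT"],
    p_among_groups = x$p_values$p[x$p_values$test == "among_groups"],
    p_among_individuals =
      x$p_values$p[x$p_values$test == "among_individuals"],
    n_perm = x$n_perm
  )
}

#' Tidy an admixture fit (long Q matrix)
#'
#' @param x A `pvp_admixture` object.
#' @param ... Unused.
#' @return Tibble with sample_id, cluster, q.
#' @export
tidy.pvp_admixture <- function(x, ...) {
  as_tibble(x$Q, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cluster", values_to = "q")
}

#' @rdname tidy.pvp_admixture
#' @export
glance.pvp_admixture <- function(x, ...) {
  tibble(K = x$K, lnPD = x$lnPD_per_run[x$chosen_run],
         n_runs = length(x$lnPD_per_run), chosen_run = x$chosen_run,
         n_burnin = x$n_burnin, n_iter = x$n_iter, alpha = x$alpha)
}

#' Tidy a Mantel result
#'
#' @param x A `pvp_mantel` object.
#' @param ... Unused.
#' @export
tidy.pvp_mantel <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm)
}

#' Tidy a PCoA (per-axis variance)
#'
#' @param x A `pvp_pcoa` object.
#' @param ... Unused.
#' @return Tibble with axis, eigenvalue, pct_variance.
#' @export
tidy.pvp_pcoa <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         pct_variance = x$pct_variance)
}

#' Tidy a 2D-LSA result
#'
#' @param x A `pvp_lsa` object.
#' @param ... Unused.
#' @export
tidy.pvp_lsa <- function(x, ...) x$per_individual

#' @rdname tidy.pvp_lsa
#' @export
glance.pvp_lsa <- function(x, ...) {
  tibble(n_individuals = nrow(x$consistency),
         n_consistent = sum(x$consistency$consistent),
         alpha = x$alpha, n_perm = x$n_perm)
}

#' Tidy a Gst result
#'
#' @param x A `pvp_gst` object.
#' @param ... Unused.
#' @export
tidy.pvp_gst <- function(x, ...) {
  tibble(gst = x$gst, p = x$p, nm = gene_flow_nm(x$gst), n_perm = x$n_perm)
}
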