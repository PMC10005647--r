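# Composite site lability: aggregation of per-site metabolic lability rate
# constants into one score. The per-site constants come from the user (e.g.
# an upstream P450 regioselectivity predictor); only the aggregation lives
# here.

#' Composite site lability score
#'
#' `CSL = k_total / (k_total + k_w)` with `k_total` the sum of the per-site
#' lability rate constants and `k_w` the water-formation rate constant.
#' Bounded in \[0, 1\]; monotone non-decreasing in every site constant and
#' non-increasing in `k_w`. Values near 1 indicate high metabolic lability.
#'
#' @param sites A [site_lability_set()].
#' @return The CSL score.
#' @export
csl <- function(sites) {
  stopifnot(inherits(sites, "site_lability_set"))
  k_total <- sum(sites$site_ks)
  k_total / (k_total + sites$k_w)
}

#' Per-site lability contributions
#'
#' Fractional contribution of each site, `k_i / (k_total + k_w)`, sorted
#' descending. Contributions sum exactly to the CSL score, so the table
#' decomposes the composite score by site.
#'
#' @param sites A [site_lability_set()].
#' @return A data frame with `site`, `k`, and `contribution`, plus the total
#'   `csl` as an attribute.
#' @export
lability_report <- function(sites) {
  stopifnot(inherits(sites, "site_lability_set"))
  denom <- sum(sites$site_ks) + sites$k_w
  contrib <- sites$site_ks / denom
  ord <- order(contrib, decreasing = TRUE)
  out <- data.frame(site = names(sites$site_ks)[ord],
                    k = unname(sites$site_ks[ord]),
                    contribution = unname(contrib[ord]))
  attr(out, "csl") <- csl(sites)
  out
}
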