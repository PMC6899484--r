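# Cochran's Q for the whole network and its decomposition into
# within-design heterogeneity and between-design inconsistency.

#' Within-design heterogeneity statistic
#'
#' Sum over designs and trials of the squared standardized deviation of each
#' trial estimate from its design's pooled estimate; multi-arm trials
#' contribute the quadratic form with their block covariance. Degrees of
#' freedom: `(n_c - 1)` times the contrast dimension, summed over designs.
#'
#' @param network an `nma_network`.
#' @return list with `q_het`, `df_het` and `per_design` contributions.
#' @export
q_heterogeneity <- function(network) {
  q <- 0
  df <- 0L
  per_design <- stats::setNames(numeric(length(network$designs)),
                                names(network$designs))
  for (lab in names(network$designs)) {
    d <- network$designs[[lab]]
    p <- pool_design_direct(network, lab)
    qc <- 0
    for (sid in d$studies) {
      cs <- study_canonical(network, d, sid)
      r <- cs$y - p$theta
      qc <- qc + drop(t(r) %*% solve_spd(cs$S) %*% r)
    }
    per_design[lab] <- qc
    q <- q + qc
    df <- df + (d$n_trials - 1L) * length(d$alts)
  }
  list(q_het = q, df_het = df, per_design = per_design)
}

#' Between-design inconsistency statistic
#'
#' Quadratic form of the deviation of each design's pooled direct estimate
#' from its fitted network value, weighted by the inverse design covariance:
#' `Q_inc = sum_c (theta_c - X_c beta)' V_c^{-1} (theta_c - X_c beta)`.
#' Degrees of freedom: design-level contrast rows minus the rank of the
#' design matrix (`T - 1` for a connected network).
#'
#' @param fit an `nma_fit` (or an augmented fit from design detachment, in
#'   which case detached designs contribute exactly zero).
#' @return list with `q_inc`, `df_inc` and `per_design` map.
#' @export
q_inconsistency <- function(fit) {
  base <- fit$base %||% fit
  per_design <- stats::setNames(numeric(length(base$row_index)),
                                names(base$row_index))
  # for augmented (detached) fits the network value of every design row is
  # taken from the basic parameters, so the detached design's own
  # contribution is measured against the indirect evidence
  resid <- base$y - (fit$fitted_basic %||% fit$fitted)
  for (lab in names(base$row_index)) {
    idx <- base$row_index[[lab]]
    r <- resid[idx]
    Wc <- base$W[idx, idx, drop = FALSE]
    per_design[lab] <- drop(t(r) %*% Wc %*% r)
  }
  df <- nrow(base$X) - mat_rank(base$X)
  if (!is.null(fit$base)) {
    df <- nrow(base$X) - mat_rank(fit$X)
  }
  list(q_inc = sum(per_design), df_inc = as.integer(df),
       per_design = per_design)
}

#' Decompose Cochran's Q for a network
#'
#' Computes the total Q (trial estimates against fitted network values), the
#' within-design heterogeneity component and the between-design inconsistency
#' component, with degrees of freedom and upper-tail chi-squared p-values.
#' The identity `Q = Q_het + Q_inc` holds exactly for the two-stage
#' fixed-effect model.
#'
#' @param network an `nma_network`.
#' @param fit optional pre-computed `nma_fit`.
#' @return a `q_decomposition` object.
#' @examples
#' decompose_q(lung_network())
#' @export
decompose_q <- function(network, fit = NULL) {
  fit <- fit %||% nma_fit(network)
  het <- q_heterogeneity(network)
  inc <- q_inconsistency(fit)

  # total Q evaluated independently at the trial level
  q_total <- 0
  for (lab in names(network$designs)) {
    d <- network$designs[[lab]]
    idx <- fit$row_index[[lab]]
    theta_net <- fit$fitted[idx]
    for (sid in d$studies) {
      cs <- study_canonical(network, d, sid)
      r <- cs$y - theta_net
      q_total <- q_total + drop(t(r) %*% solve_spd(cs$S) %*% r)
    }
  }
  df_total <- het$df_het + inc$df_inc

  pval <- function(q, df) {
    if (df <= 0) NA_real_ else stats::pchisq(q, df, lower.tail = FALSE)
  }
  structure(
    list(q_total = q_total, q_het = het$q_het, q_inc = inc$q_inc,
         df_total = df_total, df_het = het$df_het, df_inc = inc$df_inc,
         p_total = pval(q_total, df_total),
         p_het = pval(het$q_het, het$df_het),
         p_inc = pval(inc$q_inc, inc$df_inc),
         per_design_q_inc = inc$per_design,
         per_design_q_het = het$per_design),
    class = "q_decomposition"
  )
}

#' @export
print.q_decomposition <- function(x, ...) {
  fmt <- function(q, df, p) {
    sprintf("%8.3f  %3d  %s", q, df,
            if (is.na(p)) "    --" else sprintf("%6.4f", p))
  }
  cat("Cochran's Q decomposition\n")
  cat("                          Q   df       p\n")
  cat("  total          ", fmt(x$q_total, x$df_total, x$p_total), "\n")
  cat("  heterogeneity  ", fmt(x$q_het, x$df_het, x$p_het), "\n")
  cat("  inconsistency  ", fmt(x$q_inc, x$df_inc, x$p_inc), "\n")
  invisible(x)
}

#' @export
as.data.frame.q_decomposition <- function(x, ...) {
  data.frame(
    statistic = c("Q_total", "Q_het", "Q_inc"),
    value = c(x$q_total, x$q_het, x$q_inc),
    df = c(x$df_total, x$df_het, x$df_inc),
    p = c(x$p_total, x$p_het, x$p_inc)
  )
}
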