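# Closed-form net heat statistics for the two network topologies where they
# are analytically tractable: the three-treatment loop and the equal-variance
# radial network with k indirect pathways.

#' Inputs of the three-treatment closed forms
#'
#' For a two-arm triangle with treatments A, B, C and comparison of interest
#' AC, the indirect estimate is composed through B:
#' `theta_ind = theta_ab + theta_bc` with variance `s2_ab + s2_bc`.
#'
#' @param theta_ab,theta_ac,theta_bc direct estimates (alt-minus-ref along
#'   A->B, A->C, B->C).
#' @param s2_ab,s2_ac,s2_bc direct variances (all positive).
#' @return a `triangle_inputs` list.
#' @export
triangle_inputs <- function(theta_ab, theta_ac, theta_bc,
                            s2_ab, s2_ac, s2_bc) {
  stopifnot(s2_ab > 0, s2_ac > 0, s2_bc > 0)
  structure(
    list(theta_dir = theta_ac, theta_ind = theta_ab + theta_bc,
         s2_ac = s2_ac, s2_ab = s2_ab, s2_bc = s2_bc),
    class = "triangle_inputs"
  )
}

#' Off-diagonal net heat entry of a triangle
#'
#' Change in the AC design's inconsistency contribution when one of the
#' other two designs is detached. Detaching either AB or BC removes the only
#' indirect pathway, so the detached contribution vanishes and the entry
#' equals the baseline contribution:
#' `(1/s2_ac) * (s2_ac / (s2_ac + s2_ab + s2_bc))^2 * (dir - ind)^2`.
#' Always nonnegative.
#'
#' @param inputs a `triangle_inputs`.
#' @return scalar.
#' @export
triangle_qdiff_offdiag <- function(inputs) {
  s_sum <- inputs$s2_ac + inputs$s2_ab + inputs$s2_bc
  (1 / inputs$s2_ac) * (inputs$s2_ac / s_sum)^2 *
    (inputs$theta_dir - inputs$theta_ind)^2
}

#' Diagonal net heat difference of a triangle
#'
#' Change in the AC design's inconsistency contribution when AC itself is
#' detached (the remaining evidence for AC is then purely indirect):
#' `(1/s2_ac) * (dir - ind)^2 * ((s2_ac / (s2_ac + s2_ab + s2_bc))^2 - 1)`.
#' Always nonpositive.
#'
#' @param inputs a `triangle_inputs`.
#' @return scalar.
#' @export
triangle_qdiff_diag <- function(inputs) {
  s_sum <- inputs$s2_ac + inputs$s2_ab + inputs$s2_bc
  (1 / inputs$s2_ac) * (inputs$theta_dir - inputs$theta_ind)^2 *
    ((inputs$s2_ac / s_sum)^2 - 1)
}

#' Equal-variance radial network specification
#'
#' Two hub treatments are compared directly and through `k` spoke
#' treatments; every design has the same variance `s2`, so each of the `k`
#' indirect pathways carries variance `2 * s2` and weight half that of the
#' direct comparison.
#'
#' @param k number of indirect pathways (loops), `k >= 1`.
#' @param s2 common design-level variance.
#' @param theta_dir direct estimate for the hub comparison.
#' @param theta_ind numeric vector of the `k` indirect pathway estimates.
#' @return a `radial_spec` list.
#' @export
radial_spec <- function(k, s2, theta_dir, theta_ind) {
  stopifnot(k >= 1, s2 > 0, length(theta_ind) == k)
  structure(list(k = k, s2 = s2, theta_dir = theta_dir,
                 theta_ind = as.numeric(theta_ind)),
            class = "radial_spec")
}

#' Closed-form net heat entry for the radial network
#'
#' Exact change in the hub design's inconsistency contribution when one
#' design is detached. For an indirect pathway `d` the network estimate
#' drops that pathway and the entry is
#' `(2/s2) * (net_d - net) * (dir - (net_d + net)/2)` where `net` is the
#' precision-weighted network estimate over the direct design (weight
#' `1/s2`) and all pathways (weight `1/(2 s2)` each). Detaching the direct
#' design itself (`d = 0`) leaves only indirect evidence and gives
#' `-(1/s2) * 4 (k+1)/(k+2)^2 * (dir - mean(ind))^2`. At `k = 1` both
#' reduce to the triangle closed forms.
#'
#' @param spec a `radial_spec`.
#' @param d pathway index in `1..k`, or `0` to detach the hub's direct
#'   design.
#' @return scalar.
#' @export
radial_qdiff <- function(spec, d) {
  k <- spec$k
  if (d == 0) {
    return(-(1 / spec$s2) * 4 * (k + 1) / (k + 2)^2 *
             (spec$theta_dir - mean(spec$theta_ind))^2)
  }
  stopifnot(d >= 1, d <= k)
  theta_net <- (2 * spec$theta_dir + sum(spec$theta_ind)) / (k + 2)
  theta_net_d <- (2 * spec$theta_dir + sum(spec$theta_ind[-d])) / (k + 1)
  (2 / spec$s2) * (theta_net_d - theta_net) *
    (spec$theta_dir - (theta_net_d + theta_net) / 2)
}

#' Large-k approximation of the radial net heat entry
#'
#' Factorizes the entry as a scaled product `P1 * P2 / s2` where
#' `P1 = mean(ind[-d]) - ind[d]` contrasts pathway `d` against the other
#' pathways and `P2 = (2/k) * (dir - mean(ind))` is a shrinking multiple of
#' the direct-versus-indirect disagreement. `P2` is what makes the entry
#' collapse as loops are added even when pathway `d` stays deviant.
#'
#' @param spec a `radial_spec` with `k >= 2`.
#' @param d pathway index in `1..k`.
#' @return list with `p1`, `p2`, `q_diff_approx`, `q_diff_exact` and
#'   `rel_error`.
#' @export
radial_qdiff_approx <- function(spec, d) {
  stopifnot(spec$k >= 2, d >= 1, d <= spec$k)
  p1 <- mean(spec$theta_ind[-d]) - spec$theta_ind[d]
  p2 <- (2 / spec$k) * (spec$theta_dir - mean(spec$theta_ind))
  approx <- p1 * p2 / spec$s2
  exact <- radial_qdiff(spec, d)
  list(p1 = p1, p2 = p2, q_diff_approx = approx, q_diff_exact = exact,
       rel_error = if (exact == 0) NA_real_ else abs(approx - exact) / abs(exact))
}

#' Materialize a radial specification as an evidence network
#'
#' One single-trial design per edge: the hub comparison `A:B` with estimate
#' `theta_dir`, and for every spoke `X_i` the designs `A:X_i` (estimate
#' `theta_ind[i]`) and `B:X_i` (estimate 0), all with standard error
#' `sqrt(s2)`. The indirect pathway estimate for B-vs-A through `X_i` is
#' then exactly `theta_ind[i]` with variance `2 * s2`.
#'
#' @param spec a `radial_spec`.
#' @return an `nma_network`.
#' @export
radial_network <- function(spec) {
  k <- spec$k
  spokes <- sprintf("X%02d", seq_len(k))
  se <- sqrt(spec$s2)
  rows <- list(data.frame(study_id = "d_AB", treat_ref = "A",
                          treat_alt = "B", effect = spec$theta_dir, se = se))
  for (i in seq_len(k)) {
    rows[[length(rows) + 1]] <- data.frame(
      study_id = paste0("d_A_", spokes[i]), treat_ref = "A",
      treat_alt = spokes[i], effect = spec$theta_ind[i], se = se)
    rows[[length(rows) + 1]] <- data.frame(
      study_id = paste0("d_B_", spokes[i]), treat_ref = "B",
      treat_alt = spokes[i], effect = 0, se = se)
  }
  nma_network(do.call(rbind, rows))
}
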