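# Formal inconsistency tests: Bucher's adjusted indirect comparison for
# three-treatment loops and frequentist node-splitting.

#' Enumerate three-treatment loops
#'
#' All 3-cycles of the evidence graph (treatments as nodes, one edge per
#' treatment pair with direct evidence), each reported once with treatments
#' in sorted order.
#'
#' @param network an `nma_network`.
#' @return list of character triples.
#' @export
enumerate_triangles <- function(network) {
  g <- igraph::simplify(evidence_graph(network))
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(list())
  m <- matrix(igraph::V(g)$name[tri], nrow = 3)
  loops <- apply(m, 2, function(v) sort(v), simplify = FALSE)
  loops[!duplicated(vapply(loops, paste, character(1), collapse = ":"))]
}

# pooled two-arm direct evidence for the ordered comparison alt - ref;
# NULL when no two-arm design compares exactly these treatments
two_arm_direct <- function(network, ref, alt) {
  lab <- design_label(c(ref, alt))
  d <- network$designs[[lab]]
  if (is.null(d) || length(d$treatments) != 2) return(NULL)
  p <- pool_design_direct(network, lab)
  sgn <- if (p$ref == ref) 1 else -1
  list(estimate = sgn * unname(p$theta[1]), var = unname(p$cov[1, 1]))
}

#' Bucher loop inconsistency test
#'
#' In a loop of three treatments the direct estimate of one comparison is
#' compared with the indirect estimate composed through the third treatment;
#' the inconsistency estimate is `omega = direct - indirect` with variance
#' equal to the sum of the three direct variances, and `z = omega /
#' sqrt(var)` is referred to the standard normal distribution. Only two-arm
#' direct evidence enters the test (inconsistency cannot arise within a
#' single randomized multi-arm design).
#'
#' @param network an `nma_network`.
#' @param loop character vector of three treatments.
#' @param comparison optional length-2 vector `c(ref, alt)` selecting the
#'   tested edge; default: the two lexicographically first treatments of the
#'   loop. `z^2` does not depend on this choice.
#' @return a `loop_test` with `omega`, `var_omega`, `z`, `p`.
#' @examples
#' bucher_test(lung_network(), c("RT", "SeqCT", "ConCT"),
#'             comparison = c("RT", "ConCT"))
#' @export
bucher_test <- function(network, loop, comparison = NULL) {
  loop <- sort(unique(loop))
  if (length(loop) != 3) stop("loop must contain three distinct treatments")
  if (is.null(comparison)) comparison <- loop[1:2]
  if (!all(comparison %in% loop)) {
    stop("comparison must be an edge of the loop")
  }
  ref <- comparison[1]; alt <- comparison[2]
  third <- setdiff(loop, comparison)
  dir <- two_arm_direct(network, ref, alt)
  leg1 <- two_arm_direct(network, ref, third)   # third - ref
  leg2 <- two_arm_direct(network, third, alt)   # alt - third
  if (is.null(dir) || is.null(leg1) || is.null(leg2)) {
    miss <- c(if (is.null(dir)) paste(alt, "vs", ref),
              if (is.null(leg1)) paste(third, "vs", ref),
              if (is.null(leg2)) paste(alt, "vs", third))
    stop("no two-arm direct evidence for edge(s): ",
         paste(miss, collapse = "; "))
  }
  indirect <- leg1$estimate + leg2$estimate
  var_ind <- leg1$var + leg2$var
  omega <- dir$estimate - indirect
  var_omega <- dir$var + var_ind
  z <- omega / sqrt(var_omega)
  structure(
    list(loop = loop, comparison = c(ref = ref, alt = alt),
         direct = dir$estimate, var_direct = dir$var,
         indirect = indirect, var_indirect = var_ind,
         omega = omega, var_omega = var_omega,
         z = z, p = 2 * stats::pnorm(-abs(z))),
    class = "loop_test"
  )
}

#' @export
print.loop_test <- function(x, ...) {
  cat(sprintf("Bucher loop test: loop {%s}, comparison %s vs %s\n",
              paste(x$loop, collapse = ", "),
              x$comparison["alt"], x$comparison["ref"]))
  cat(sprintf("  direct %.4f, indirect %.4f\n", x$direct, x$indirect))
  cat(sprintf("  omega = %.4f (SE %.4f), z = %.3f, p = %.4f\n",
              x$omega, sqrt(x$var_omega), x$z, x$p))
  invisible(x)
}

#' Bucher tests for every three-treatment loop
#'
#' @param network an `nma_network`.
#' @return data frame with one row per testable loop; loops lacking two-arm
#'   direct evidence on some edge are skipped with a message.
#' @export
bucher_all <- function(network) {
  loops <- enumerate_triangles(network)
  rows <- list()
  for (loop in loops) {
    res <- tryCatch(bucher_test(network, loop), error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping loop {", paste(loop, collapse = ", "), "}: ",
              conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      loop = paste(loop, collapse = ":"),
      comparison = paste(res$comparison["alt"], "vs", res$comparison["ref"]),
      omega = res$omega, se_omega = sqrt(res$var_omega),
      z = res$z, p = res$p, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(loop = character(0), comparison = character(0),
                      omega = numeric(0), se_omega = numeric(0),
                      z = numeric(0), p = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Node-splitting: direct versus indirect evidence for one comparison
#'
#' The direct estimate pools the design-level evidence of every design
#' containing both treatments. The indirect estimate comes from refitting
#' the network with all those designs detached (design-matrix augmentation),
#' so it uses exactly the remaining evidence and is independent of the
#' direct part. The difference `direct - indirect` is tested with a Wald
#' z-statistic.
#'
#' @param network an `nma_network`.
#' @param comparison length-2 character vector `c(ref, alt)`; estimates are
#'   on the `alt`-minus-`ref` scale.
#' @param fit optional pre-computed `nma_fit`.
#' @return a `node_split` object.
#' @examples
#' node_split(lung_network(), c("ConCT", "SeqCT"))
#' @export
node_split <- function(network, comparison, fit = NULL) {
  stopifnot(length(comparison) == 2)
  ref <- comparison[1]; alt <- comparison[2]
  fit <- fit %||% nma_fit(network)
  dir <- direct_evidence(fit, ref, alt)
  if (is.null(dir)) {
    stop("comparison not splittable: no direct evidence for ",
         alt, " vs ", ref)
  }
  direct_designs <- names(Filter(function(p) all(c(ref, alt) %in% p$treatments),
                                 fit$pooled))
  if (length(direct_designs) == length(fit$pooled)) {
    stop("comparison not splittable: no indirect evidence remains for ",
         alt, " vs ", ref)
  }
  af <- augmented_fit(fit, direct_designs)
  L <- contrast_vector(fit, ref, alt)
  # identifiable iff L lies in the range of the augmented normal equations
  p <- length(L)
  Ap <- af$A[seq_len(p), seq_len(p), drop = FALSE] -
    af$A[seq_len(p), -seq_len(p), drop = FALSE] %*%
    pinv(af$A[-seq_len(p), -seq_len(p), drop = FALSE]) %*%
    af$A[-seq_len(p), seq_len(p), drop = FALSE]
  proj <- Ap %*% pinv(Ap) %*% L
  if (max(abs(proj - L)) > 1e-6 * max(1, max(abs(L)))) {
    stop("comparison not splittable: no indirect path connects ",
         ref, " and ", alt)
  }
  ind_est <- drop(crossprod(L, af$basic_params))
  ind_se <- sqrt(drop(t(L) %*% af$cov_params %*% L))
  diff <- dir$estimate - ind_est
  se_diff <- sqrt(dir$se^2 + ind_se^2)
  z <- diff / se_diff
  structure(
    list(comparison = c(ref = ref, alt = alt),
         direct = dir$estimate, se_direct = dir$se,
         indirect = ind_est, se_indirect = ind_se,
         difference = diff, se_difference = se_diff,
         z = z, p = 2 * stats::pnorm(-abs(z)),
         detached_designs = direct_designs),
    class = "node_split"
  )
}

#' @export
print.node_split <- function(x, ...) {
  cat(sprintf("Node split: %s vs %s\n", x$comparison["alt"],
              x$comparison["ref"]))
  cat(sprintf("  direct    %8.4f (SE %.4f)\n", x$direct, x$se_direct))
  cat(sprintf("  indirect  %8.4f (SE %.4f)\n", x$indirect, x$se_indirect))
  cat(sprintf("  difference %7.4f (SE %.4f), z = %.3f, p = %.4f\n",
              x$difference, x$se_difference, x$z, x$p))
  invisible(x)
}

#' Node-splitting for every splittable comparison
#'
#' Applies [node_split()] to each treatment pair with direct evidence and at
#' least one independent indirect path; unsplittable comparisons are skipped
#' with a message.
#'
#' @param network an `nma_network`.
#' @return data frame shaped like the usual side-splitting report: direct
#'   and indirect estimates with standard errors, their difference, and the
#'   two-sided p-value.
#' @export
node_split_all <- function(network) {
  fit <- nma_fit(network)
  prs <- utils::combn(network$treatments, 2)
  rows <- list()
  for (j in seq_len(ncol(prs))) {
    cmp <- prs[, j]
    if (is.null(direct_evidence(fit, cmp[1], cmp[2]))) next
    res <- tryCatch(node_split(network, cmp, fit = fit),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", cmp[2], " vs ", cmp[1], ": ",
              conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste(cmp[2], "vs", cmp[1]),
      direct = res$direct, se_direct = res$se_direct,
      indirect = res$indirect, se_indirect = res$se_indirect,
      difference = res$difference, se_difference = res$se_difference,
      z = res$z, p = res$p, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(comparison = character(0), direct = numeric(0),
                      se_direct = numeric(0), indirect = numeric(0),
                      se_indirect = numeric(0), difference = numeric(0),
                      se_difference = numeric(0), z = numeric(0),
                      p = numeric(0)))
  }
  do.call(rbind, rows)
}
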