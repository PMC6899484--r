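# Generalized least squares fit of the fixed-effect NMA on design-level
# pooled estimates, with the hat matrix used by the net heat diagnostics.

#' Fit the fixed-effect network meta-analysis by generalized least squares
#'
#' Two-stage model: trials are first pooled within each design by
#' inverse-variance weighting ([pool_design_direct()]); the pooled design
#' estimates are then regressed on the basic parameters (every treatment
#' versus the network reference) with weights equal to the inverse of the
#' block-diagonal design-level covariance. Under consistency every contrast
#' is a difference of basic parameters, so the fit borrows strength across
#' the whole evidence graph.
#'
#' @param network an `nma_network`.
#' @param reference network reference treatment (default: lexicographically
#'   first label). Estimates of treatment contrasts are invariant to this
#'   choice.
#' @return an `nma_fit` with components
#'   \describe{
#'     \item{basic_params}{estimates of the `T - 1` basic contrasts}
#'     \item{cov_params}{their covariance}
#'     \item{X, W}{design matrix and weight matrix of the regression}
#'     \item{hat}{hat matrix `X (X'WX)^+ X'W` (idempotent)}
#'     \item{fitted}{network estimate for every design-level contrast row}
#'     \item{pooled}{list of `design_estimate` objects}
#'   }
#' @examples
#' fit <- nma_fit(lung_network())
#' fit
#' @export
nma_fit <- function(network, reference = NULL) {
  X <- build_design_matrix(network, reference)
  row_map <- attr(X, "row_map")
  pooled <- lapply(names(network$designs),
                   function(lab) pool_design_direct(network, lab))
  names(pooled) <- names(network$designs)
  # stacking order of rows follows build_design_matrix (= design order)
  y <- unlist(lapply(pooled, function(p) unname(p$theta)), use.names = FALSE)
  Vblocks <- lapply(pooled, function(p) p$cov)
  V <- block_diag(Vblocks)
  W <- block_diag(lapply(Vblocks, solve_spd))
  A <- t(X) %*% W %*% X
  if (mat_rank(A) < ncol(X)) {
    stop("design-level weight system is singular; network evidence does not ",
         "identify all basic parameters")
  }
  Ainv <- pinv(A)
  beta <- drop(Ainv %*% t(X) %*% W %*% y)
  names(beta) <- colnames(X)
  H <- X %*% Ainv %*% t(X) %*% W
  fitted <- drop(X %*% beta)

  row_index <- split(seq_len(nrow(X)), row_map$design)
  structure(
    list(network = network, reference = attr(X, "reference"),
         basic_params = beta, cov_params = Ainv,
         X = X, W = W, V = V, y = y, hat = H, fitted = fitted,
         row_map = row_map, row_index = row_index, pooled = pooled),
    class = "nma_fit"
  )
}

#' Network estimate of a treatment contrast
#'
#' @param fit an `nma_fit`.
#' @param ref,alt treatment labels; the estimate is `alt` minus `ref`.
#' @return list with `estimate` and `se`.
#' @export
network_estimate <- function(fit, ref, alt) {
  L <- contrast_vector(fit, ref, alt)
  list(estimate = drop(crossprod(L, fit$basic_params)),
       se = sqrt(drop(t(L) %*% fit$cov_params %*% L)))
}

# basic-parameter coefficient vector of the contrast alt - ref
contrast_vector <- function(fit, ref, alt) {
  trts <- fit$network$treatments
  if (!all(c(ref, alt) %in% trts)) {
    stop("unknown treatment in contrast: ", ref, " / ", alt)
  }
  L <- stats::setNames(rep(0, length(fit$basic_params)),
                       names(fit$basic_params))
  if (alt != fit$reference) L[alt] <- 1
  if (ref != fit$reference) L[ref] <- L[ref] - 1
  L
}

# direct (pooled design-level) evidence on a comparison, combined by
# inverse variance across every design containing both treatments
direct_evidence <- function(fit, ref, alt) {
  ests <- numeric(0)
  vars <- numeric(0)
  for (p in fit$pooled) {
    if (all(c(ref, alt) %in% p$treatments)) {
      m <- stats::setNames(rep(0, length(p$alts)), p$alts)
      if (alt != p$ref) m[alt] <- 1
      if (ref != p$ref) m[ref] <- m[ref] - 1
      ests <- c(ests, drop(crossprod(m, p$theta)))
      vars <- c(vars, drop(t(m) %*% p$cov %*% m))
    }
  }
  if (length(ests) == 0) return(NULL)
  w <- 1 / vars
  list(estimate = sum(w * ests) / sum(w), se = sqrt(1 / sum(w)),
       n_designs = length(ests))
}

#' Comparison summary table
#'
#' For every treatment pair: the pooled direct evidence (if any), the network
#' estimate, and the implied indirect evidence obtained by removing the
#' direct information from the network estimate on the precision scale
#' (`1/v_ind = 1/v_net - 1/v_dir`). Pairs whose network precision does not
#' exceed the direct precision report no indirect component.
#'
#' @param fit an `nma_fit`.
#' @return data frame with columns `comparison`, `direct`, `direct_se`,
#'   `indirect`, `indirect_se`, `network`, `network_se`.
#' @export
comparison_table <- function(fit) {
  trts <- fit$network$treatments
  prs <- utils::combn(trts, 2)
  out <- data.frame(comparison = character(0))
  rows <- list()
  for (j in seq_len(ncol(prs))) {
    ref <- prs[1, j]; alt <- prs[2, j]
    netw <- network_estimate(fit, ref, alt)
    dir <- direct_evidence(fit, ref, alt)
    ind_est <- ind_se <- NA_real_
    if (is.null(dir)) {
      ind_est <- netw$estimate
      ind_se <- netw$se
      dir_est <- dir_se <- NA_real_
    } else {
      dir_est <- dir$estimate; dir_se <- dir$se
      w_net <- 1 / netw$se^2
      w_dir <- 1 / dir$se^2
      if (w_net - w_dir > 1e-12 * w_net) {
        w_ind <- w_net - w_dir
        ind_est <- (netw$estimate * w_net - dir$estimate * w_dir) / w_ind
        ind_se <- sqrt(1 / w_ind)
      }
    }
    rows[[j]] <- data.frame(
      comparison = paste(alt, "vs", ref),
      direct = dir_est, direct_se = dir_se,
      indirect = ind_est, indirect_se = ind_se,
      network = netw$estimate, network_se = netw$se,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' @export
print.nma_fit <- function(x, digits = 4, ...) {
  cat("Fixed-effect NMA fit (GLS, reference:", x$reference, ")\n")
  cat("Basic parameters (vs", x$reference, "):\n")
  se <- sqrt(diag(x$cov_params))
  for (i in seq_along(x$basic_params)) {
    cat(sprintf("  %s: %.*f (SE %.*f)\n", names(x$basic_params)[i],
                digits, x$basic_params[i], digits, se[i]))
  }
  invisible(x)
}

# Refit the GLS after augmenting the design matrix with one indicator
# column per contrast row of each design in `detach`. Those rows are then
# fitted exactly, which removes their information from the basic parameters
# while keeping the residual bookkeeping of every other design intact.
augmented_fit <- function(fit, detach) {
  detach <- unique(detach)
  missing <- setdiff(detach, names(fit$network$designs))
  if (length(missing) > 0) {
    stop("cannot detach unknown design(s): ", paste(missing, collapse = ", "))
  }
  rows <- unlist(fit$row_index[detach], use.names = FALSE)
  D <- matrix(0, nrow(fit$X), length(rows))
  D[cbind(rows, seq_along(rows))] <- 1
  Xa <- cbind(fit$X, D)
  A <- t(Xa) %*% fit$W %*% Xa
  Ainv <- pinv(A)
  beta <- drop(Ainv %*% t(Xa) %*% fit$W %*% fit$y)
  fitted <- drop(Xa %*% beta)
  p <- ncol(fit$X)
  # network estimates from the basic parameters only: for the detached
  # design's own rows this is the indirect evidence, while `fitted` (with
  # the indicator columns) reproduces those rows exactly
  fitted_basic <- drop(fit$X %*% beta[seq_len(p)])
  list(detached = detach, X = Xa, A = A, Ainv = Ainv,
       beta_full = beta,
       basic_params = stats::setNames(beta[seq_len(p)], colnames(fit$X)),
       cov_params = Ainv[seq_len(p), seq_len(p), drop = FALSE],
       fitted = fitted, fitted_basic = fitted_basic, base = fit)
}
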