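# Radial-network simulation with one inflated design: generator and the
# loop-escalation study showing how the net heat statistic masks
# inconsistency as treatment loops are added.

#' Simulation configuration
#'
#' Defaults encode the stated world of the loop-escalation study: six trials
#' per design; per-trial true treatment effects drawn from a normal
#' distribution with standard deviation 0.2 around mean 0, except the
#' inflated design (the hub-spoke comparison A:C) whose mean is 2; per-trial
#' standard errors drawn as the absolute value of a standard normal deviate,
#' redrawn while below `se_floor` to keep weight matrices well conditioned.
#'
#' The observed trial effects are the drawn true effects themselves — no
#' sampling noise is layered on top — so effect dispersion is deliberately
#' decoupled from the claimed standard errors (`sampling = "direct"`). Set
#' `sampling = "calibrated"` to instead draw observed effects as design mean
#' plus `N(0, se^2)` noise, which makes all Q statistics and node-split
#' z-statistics exactly calibrated and is used for null sanity checks.
#'
#' @param trials_per_design trials simulated for every design.
#' @param base_effect_mean mean of the consistent designs' effects.
#' @param inflated_effect_mean mean for the inflated design A:C.
#' @param effect_sd standard deviation of the per-trial true effects.
#' @param se_floor lower bound for simulated standard errors (redraw below).
#' @param max_loops largest number of treatment loops in the escalation.
#' @param replicates number of replicates per loop count.
#' @param sampling `"direct"` (effects are the draws) or `"calibrated"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(trials_per_design = 6,
                       base_effect_mean = 0,
                       inflated_effect_mean = 2,
                       effect_sd = 0.2,
                       se_floor = 0.05,
                       max_loops = 10,
                       replicates = 100,
                       sampling = c("direct", "calibrated")) {
  sampling <- match.arg(sampling)
  stopifnot(trials_per_design >= 1, effect_sd >= 0, se_floor > 0,
            max_loops >= 1, replicates >= 1)
  structure(list(trials_per_design = trials_per_design,
                 base_effect_mean = base_effect_mean,
                 inflated_effect_mean = inflated_effect_mean,
                 effect_sd = effect_sd, se_floor = se_floor,
                 max_loops = max_loops, replicates = replicates,
                 sampling = sampling),
            class = "sim_config")
}

# positive standard errors: |N(0,1)| truncated below the floor
draw_se <- function(n, floor) {
  out <- abs(stats::rnorm(n))
  while (any(out < floor)) {
    bad <- out < floor
    out[bad] <- abs(stats::rnorm(sum(bad)))
  }
  out
}

# deterministic per-(k, replicate) substream below 2^31, collision-free for
# k <= 20 and replicate < 1e5
substream_seed <- function(seed, k, replicate) {
  (as.integer(seed) %% 1000L) * 2000000L + k * 100000L + replicate
}

#' Generate one radial network with an inflated design
#'
#' Builds the evidence network with `k` treatment loops: the triangle
#' A, B, C plus spoke treatments `X1 .. X(k-1)`, each connected to both A
#' and B. Every design gets `trials_per_design` trials; design A:C is the
#' inflated one. Deterministic given `seed`.
#'
#' @param config a `sim_config`.
#' @param k number of treatment loops, `k >= 1`.
#' @param seed integer seed.
#' @return an `nma_network`.
#' @examples
#' net <- simulate_radial_network(sim_config(), k = 1, seed = 42)
#' net
#' @export
simulate_radial_network <- function(config, k, seed) {
  stopifnot(inherits(config, "sim_config"), k >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  spokes <- if (k > 1) sprintf("X%02d", seq_len(k - 1)) else character(0)
  design_pairs <- c(
    list(c("A", "B"), c("A", "C"), c("B", "C")),
    unlist(lapply(spokes, function(s) list(c("A", s), c("B", s))),
           recursive = FALSE)
  )
  n <- config$trials_per_design
  ids <- refs <- alts <- character(0)
  effs <- ses <- numeric(0)
  for (pair in design_pairs) {
    inflated <- identical(pair, c("A", "C"))
    mu <- if (inflated) config$inflated_effect_mean else config$base_effect_mean
    se <- draw_se(n, config$se_floor)
    eff <- switch(config$sampling,
      direct = stats::rnorm(n, mu, config$effect_sd),
      calibrated = mu + se * stats::rnorm(n)
    )
    ids <- c(ids, sprintf("t_%s_%s_%02d", pair[1], pair[2], seq_len(n)))
    refs <- c(refs, rep(pair[1], n))
    alts <- c(alts, rep(pair[2], n))
    effs <- c(effs, eff)
    ses <- c(ses, se)
  }
  nma_network(data.frame(study_id = ids, treat_ref = refs, treat_alt = alts,
                         effect = effs, se = ses, stringsAsFactors = FALSE))
}

#' Loop-escalation study
#'
#' For each number of loops `k = 1 .. max_loops` and each replicate, a fresh
#' radial network is generated (all effects re-simulated) and the following
#' are computed with `c = A:B` and `d = A:C`: the net heat quantities
#' `Q_c^inc`, `Q_c(d)^inc` and their difference `Q_c,d^diff`; the node-split
#' difference and p-value for the A-B comparison; and the squared Bucher
#' z-statistic for the A, B, C loop (the within-loop inconsistency measure
#' unaffected by network size).
#'
#' @param config a `sim_config`.
#' @param seed master integer seed; each `(k, replicate)` cell uses an
#'   independently derived substream.
#' @return a `loop_escalation` data frame with columns `k`, `replicate`,
#'   `q_diff`, `q_inc`, `q_inc_detached`, `nodesplit_diff`, `nodesplit_p`,
#'   `bucher_z2` and the configuration as an attribute.
#' @export
run_loop_escalation <- function(config = sim_config(), seed = 1) {
  rows <- vector("list", config$max_loops * config$replicates)
  i <- 0L
  for (k in seq_len(config$max_loops)) {
    for (r in seq_len(config$replicates)) {
      net <- simulate_radial_network(config, k,
                                     substream_seed(seed, k, r))
      fit <- nma_fit(net)
      qinc <- q_inconsistency(fit)$per_design
      af <- augmented_fit(fit, "A:C")
      qdet <- q_inconsistency(af)$per_design
      ns <- node_split(net, c("A", "B"), fit = fit)
      bt <- bucher_test(net, c("A", "B", "C"))
      i <- i + 1L
      rows[[i]] <- data.frame(
        k = k, replicate = r,
        q_diff = qinc[["A:B"]] - qdet[["A:B"]],
        q_inc = qinc[["A:B"]],
        q_inc_detached = qdet[["A:B"]],
        nodesplit_diff = ns$difference,
        nodesplit_p = ns$p,
        bucher_z2 = bt$z^2
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("loop_escalation", class(out))
  out
}

#' Summarize a loop-escalation run
#'
#' Median and quartiles of `Q_c,d^diff` and of the within-loop Bucher
#' statistic by number of loops.
#'
#' @param object a `loop_escalation` data frame.
#' @param ... unused.
#' @return data frame with one row per `k`.
#' @export
summary.loop_escalation <- function(object, ...) {
  ks <- sort(unique(object$k))
  do.call(rbind, lapply(ks, function(kk) {
    sub <- object[object$k == kk, ]
    data.frame(
      k = kk,
      q_diff_median = stats::median(sub$q_diff),
      q_diff_q1 = stats::quantile(sub$q_diff, 0.25, names = FALSE),
      q_diff_q3 = stats::quantile(sub$q_diff, 0.75, names = FALSE),
      q_inc_median = stats::median(sub$q_inc),
      bucher_z2_median = stats::median(sub$bucher_z2),
      nodesplit_reject = mean(sub$nodesplit_p < 0.05)
    )
  }))
}

#' Plot the loop-escalation trajectory
#'
#' Median `Q_c,d^diff` against the number of treatment loops, with the
#' interquartile band across replicates and the conventional display
#' threshold 8 as a reference line.
#'
#' @param x a `loop_escalation` data frame.
#' @param path optional output image path (png or svg).
#' @param log_scale plot the Q axis on a log scale (default TRUE; the
#'   statistic spans orders of magnitude).
#' @param ... unused.
#' @return invisibly, the summary table.
#' @export
plot.loop_escalation <- function(x, path = NULL, log_scale = TRUE, ...) {
  s <- summary(x)
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "svg") grDevices::svg(path, width = 7, height = 5)
    else grDevices::png(path, width = 800, height = 560, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ylim <- range(c(s$q_diff_q1, s$q_diff_q3, 8))
  if (log_scale) ylim[1] <- max(ylim[1], 1e-3)
  graphics::plot(s$k, pmax(s$q_diff_median, if (log_scale) 1e-3 else -Inf),
                 type = "n", log = if (log_scale) "y" else "",
                 xlab = "treatment loops k",
                 ylab = expression(Q[list(c, d)]^diff), ylim = ylim)
  graphics::polygon(c(s$k, rev(s$k)),
                    c(pmax(s$q_diff_q1, if (log_scale) 1e-3 else -Inf),
                      rev(s$q_diff_q3)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(s$k, s$q_diff_median, type = "b", pch = 19)
  graphics::abline(h = 8, lty = 2, col = "red3")
  graphics::legend("topright", bty = "n",
                   legend = c("median", "interquartile band",
                              "display threshold 8"),
                   lty = c(1, NA, 2), pch = c(19, 15, NA),
                   col = c("black", grDevices::grey(0.85), "red3"))
  invisible(s)
}
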