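# Net heat matrix: per-design inconsistency contributions before and after
# detaching each eligible design, plus hat-matrix information contributions
# and the heat-plot rendering.

#' Designs eligible for the net heat plot
#'
#' A design is eligible when it takes part in at least one treatment loop and
#' its removal does not split the evidence network: deleting its edges from
#' the evidence multigraph must leave a connected graph that still contains
#' every treatment of the design. Bridge designs and pendant designs are
#' therefore excluded.
#'
#' @param network an `nma_network`.
#' @return character vector of design labels (possibly empty, with a
#'   warning).
#' @export
eligible_designs <- function(network) {
  g <- evidence_graph(network)
  out <- character(0)
  for (lab in names(network$designs)) {
    g2 <- igraph::delete_edges(g, which(igraph::E(g)$design == lab))
    g2 <- igraph::delete_vertices(g2, which(igraph::degree(g2) == 0))
    trts <- network$designs[[lab]]$treatments
    if (igraph::vcount(g2) == 0) next
    if (!all(trts %in% igraph::V(g2)$name)) next
    if (!igraph::is_connected(g2)) next
    out <- c(out, lab)
  }
  if (length(out) == 0) {
    warning("no design lies in a treatment loop; net heat plot undefined",
            call. = FALSE)
  }
  out
}

#' Detach one design from a fitted network
#'
#' Augments the design matrix with one indicator column per contrast of the
#' detached design (a `1` on that design's rows, `0` elsewhere) and refits
#' the generalized least squares model. The detached design is then fitted
#' exactly — its residuals are zero — so the remaining inconsistency
#' `Q_c(d)^inc` can be read off for every other design.
#'
#' @param fit an `nma_fit`.
#' @param design label of the design to detach (must be eligible).
#' @return augmented fit (list with `basic_params`, `fitted`, `detached`,
#'   and the baseline fit in `$base`).
#' @export
detach_design <- function(fit, design) {
  elig <- eligible_designs(fit$network)
  if (!design %in% elig) {
    stop("design '", design, "' is not eligible for detachment ",
         "(bridge or outside every loop)")
  }
  augmented_fit(fit, design)
}

#' Net heat matrix
#'
#' For every eligible design `d` the model is refitted with `d` detached and
#' the per-design inconsistency contributions recomputed. Off-diagonal
#' entries are `Q_{c,d}^diff = Q_c^inc - Q_c(d)^inc`, the drop in design
#' `c`'s inconsistency contribution caused by detaching design `d`; the
#' diagonal carries the baseline contribution `Q_c^inc` (the display
#' convention of the net heat plot). The full detached table `Q_c(d)^inc`
#' and the design-aggregated absolute hat-matrix contributions are returned
#' alongside.
#'
#' Rows and columns are ordered by descending diagonal `Q_c^inc`, ties
#' broken lexicographically.
#'
#' @param network an `nma_network`.
#' @param fit optional pre-computed `nma_fit`.
#' @return a `net_heat` object with matrices `q_diff`, `q_inc_detached`,
#'   `hat_abs`, the vector `q_inc` of baseline contributions and
#'   `designs_included`.
#' @examples
#' nh <- net_heat(lung_network())
#' nh$q_diff
#' @export
net_heat <- function(network, fit = NULL) {
  fit <- fit %||% nma_fit(network)
  elig <- eligible_designs(network)
  if (length(elig) == 0) {
    return(structure(list(designs_included = character(0),
                          q_diff = matrix(numeric(0), 0, 0),
                          q_inc_detached = matrix(numeric(0), 0, 0),
                          hat_abs = matrix(numeric(0), 0, 0),
                          q_inc = numeric(0), fit = fit),
                     class = "net_heat"))
  }
  base_inc <- q_inconsistency(fit)$per_design
  qdet <- matrix(NA_real_, length(elig), length(elig),
                 dimnames = list(elig, elig))
  for (d in elig) {
    af <- augmented_fit(fit, d)
    qdet[, d] <- q_inconsistency(af)$per_design[elig]
  }
  qdiff <- base_inc[elig] - qdet
  diag(qdiff) <- base_inc[elig]

  # hat-matrix information contributions, aggregated over each design's rows
  hat_abs <- matrix(0, length(elig), length(elig),
                    dimnames = list(elig, elig))
  for (c_ in elig) {
    for (d_ in elig) {
      hat_abs[c_, d_] <- sum(abs(fit$hat[fit$row_index[[c_]],
                                         fit$row_index[[d_]]]))
    }
  }

  ord <- order(-diag(qdiff), elig)
  structure(
    list(designs_included = elig[ord],
         q_diff = qdiff[ord, ord, drop = FALSE],
         q_inc_detached = qdet[ord, ord, drop = FALSE],
         hat_abs = hat_abs[ord, ord, drop = FALSE],
         q_inc = base_inc[elig][ord],
         fit = fit),
    class = "net_heat"
  )
}

#' Hat-matrix contributions of the baseline fit
#'
#' Absolute values of the hat matrix of the design-level regression,
#' aggregated over each design's contrast rows and restricted to eligible
#' designs. Entry `(c, d)` measures how much statistical information the
#' direct evidence of design `d` contributes to the network estimate of
#' design `c`.
#'
#' @param fit an `nma_fit`.
#' @return square matrix over eligible designs.
#' @export
hat_contributions <- function(fit) {
  net_heat(fit$network, fit)$hat_abs
}

#' @export
print.net_heat <- function(x, digits = 3, ...) {
  cat("Net heat matrix (", length(x$designs_included), "eligible designs )\n")
  if (length(x$designs_included) > 0) {
    cat("Diagonal = Q_c^inc; off-diagonal = Q_c,d^diff\n")
    print(round(x$q_diff, digits))
  }
  invisible(x)
}

#' Long-format table of a net heat matrix
#'
#' @param x a `net_heat` object.
#' @param ... unused.
#' @return data frame with columns `row_design`, `col_design`, `q_diff`,
#'   `q_inc_detached`, `hat_abs`.
#' @export
as.data.frame.net_heat <- function(x, ...) {
  if (length(x$designs_included) == 0) {
    return(data.frame(row_design = character(0), col_design = character(0),
                      q_diff = numeric(0), q_inc_detached = numeric(0),
                      hat_abs = numeric(0)))
  }
  grid <- expand.grid(row_design = x$designs_included,
                      col_design = x$designs_included,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$q_diff <- x$q_diff[cbind(grid$row_design, grid$col_design)]
  grid$q_inc_detached <- x$q_inc_detached[cbind(grid$row_design,
                                                grid$col_design)]
  grid$hat_abs <- x$hat_abs[cbind(grid$row_design, grid$col_design)]
  grid
}

# two-sided color ramp: blue (negative) -> white (zero) -> yellow -> red,
# anchored at +/- clip
netheat_color <- function(v, clip = 8) {
  v <- max(-clip, min(clip, v))
  if (v >= 0) {
    t <- v / clip
    # white -> yellow -> red
    if (t <= 0.5) {
      u <- t / 0.5
      grDevices::rgb(1, 1 - 0.15 * u, 1 - u)
    } else {
      u <- (t - 0.5) / 0.5
      grDevices::rgb(1, 0.85 * (1 - u), 0)
    }
  } else {
    t <- -v / clip
    grDevices::rgb(1 - t, 1 - t, 1)
  }
}

#' Render the net heat plot
#'
#' Cells are colored by `Q_c,d^diff` on a two-sided scale (white/yellow/red
#' for positive values, white/blue for negative), with color intensity
#' clipped at an absolute value of `clip` (default 8, the conventional
#' display threshold). Grey squares inside each cell have area proportional
#' to the absolute hat-matrix contribution.
#'
#' @param x a `net_heat` object.
#' @param path optional output file; extension selects `png` or `svg`
#'   device. `NULL` draws on the active device.
#' @param clip color-saturation threshold for `|Q_c,d^diff|`.
#' @param ... unused.
#' @return invisibly, the input.
#' @export
plot.net_heat <- function(x, path = NULL, clip = 8, ...) {
  n <- length(x$designs_included)
  if (n == 0) stop("empty net heat matrix; nothing to plot")
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "svg") grDevices::svg(path, width = 7, height = 7)
    else grDevices::png(path, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(1, 8, 8, 1))
  # restore par before any device opened above is closed
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::plot(NULL, xlim = c(0, n), ylim = c(0, n), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  hmax <- max(x$hat_abs, 1e-12)
  for (i in seq_len(n)) {      # row (top to bottom)
    for (j in seq_len(n)) {    # column
      v <- x$q_diff[i, j]
      graphics::rect(j - 1, n - i, j, n - i + 1,
                     col = netheat_color(v, clip), border = "grey40")
      side <- 0.85 * sqrt(x$hat_abs[i, j] / hmax)
      if (side > 0) {
        cx <- j - 0.5; cy <- n - i + 0.5
        graphics::rect(cx - side / 2, cy - side / 2,
                       cx + side / 2, cy + side / 2,
                       col = grDevices::grey(0.45, alpha = 0.55),
                       border = NA)
      }
    }
  }
  graphics::axis(3, at = seq_len(n) - 0.5, labels = x$designs_included,
                 las = 2, tick = FALSE, cex.axis = 0.8)
  graphics::axis(2, at = n - seq_len(n) + 0.5, labels = x$designs_included,
                 las = 2, tick = FALSE, cex.axis = 0.8)
  invisible(x)
}

#' Write a net heat matrix and plot to files
#'
#' @param x a `net_heat` object.
#' @param out_matrix path of the long-format CSV (columns `row_design`,
#'   `col_design`, `q_diff`, `q_inc_detached`, `hat_abs`).
#' @param out_plot optional image path (png or svg).
#' @return invisibly, the long-format data frame.
#' @export
render_net_heat <- function(x, out_matrix, out_plot = NULL) {
  stopifnot(inherits(x, "net_heat"))
  df <- as.data.frame(x)
  write_atomic_csv(df, out_matrix)
  if (!is.null(out_plot)) plot(x, path = out_plot)
  invisible(df)
}
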