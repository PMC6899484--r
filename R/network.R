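# Contrast-based evidence network: loading, design inference, within-design
# pooling and the design matrix of the two-stage fixed-effect NMA model.

DESIGN_SEP <- ":"

design_label <- function(treatments) {
  paste(sort(unique(treatments)), collapse = DESIGN_SEP)
}

#' Build an evidence network from contrast-level summary data
#'
#' Takes one row per trial contrast (study id, reference and alternative
#' treatment, effect estimate on the analysis scale, standard error) and
#' groups trials into *designs*: two trials belong to the same design exactly
#' when their studies compare the same set of treatments. Multi-arm studies
#' contribute `t - 1` contrasts against a single trial-level reference arm and
#' repeat their `study_id`; the optional `shared_arm_variance` column gives
#' the covariance induced by the shared arm.
#'
#' The effect sign convention is alternative-minus-reference throughout the
#' package.
#'
#' @param data data frame with columns `study_id`, `treat_ref`, `treat_alt`,
#'   `effect`, `se` and optionally `shared_arm_variance` (may be `NA`).
#' @return an object of class `nma_network`.
#' @examples
#' net <- nma_network(data.frame(
#'   study_id = c("s1", "s2", "s3"),
#'   treat_ref = c("A", "A", "B"),
#'   treat_alt = c("B", "C", "C"),
#'   effect = c(0.1, 0.3, 0.15),
#'   se = c(0.1, 0.1, 0.1)
#' ))
#' net
#' @seealso [read_contrasts()] to load the same schema from CSV,
#'   [nma_fit()] for the model fit.
#' @export
nma_network <- function(data) {
  required <- c("study_id", "treat_ref", "treat_alt", "effect", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"shared_arm_variance" %in% names(data)) {
    data$shared_arm_variance <- NA_real_
  }
  data$study_id <- as.character(data$study_id)
  data$treat_ref <- as.character(data$treat_ref)
  data$treat_alt <- as.character(data$treat_alt)
  data$effect <- as.numeric(data$effect)
  data$se <- as.numeric(data$se)
  data$shared_arm_variance <- as.numeric(data$shared_arm_variance)

  if (nrow(data) == 0) stop("no contrast rows supplied")
  bad_se <- which(!is.finite(data$se) | data$se <= 0)
  if (length(bad_se) > 0) {
    stop("nonpositive or missing standard error in row(s): ",
         paste(bad_se, collapse = ", "))
  }
  if (any(!is.finite(data$effect))) {
    stop("missing effect estimate in row(s): ",
         paste(which(!is.finite(data$effect)), collapse = ", "))
  }
  if (any(data$treat_ref == data$treat_alt)) {
    stop("treat_ref equals treat_alt in row(s): ",
         paste(which(data$treat_ref == data$treat_alt), collapse = ", "))
  }
  all_trts <- c(data$treat_ref, data$treat_alt)
  if (any(grepl(DESIGN_SEP, all_trts, fixed = TRUE))) {
    stop("treatment labels must not contain '", DESIGN_SEP, "'")
  }

  pair_key <- paste(data$study_id,
                    pmin(data$treat_ref, data$treat_alt),
                    pmax(data$treat_ref, data$treat_alt))
  if (anyDuplicated(pair_key)) {
    stop("duplicate (study, comparison) row(s): ",
         paste(which(duplicated(pair_key)), collapse = ", "))
  }

  # per-study validation: one reference arm, coherent shared-arm variance
  by_study <- split(seq_len(nrow(data)), data$study_id)
  for (sid in names(by_study)) {
    rows <- by_study[[sid]]
    if (length(rows) > 1) {
      if (length(unique(data$treat_ref[rows])) != 1) {
        stop("multi-arm study '", sid,
             "' must report all contrasts against one reference arm")
      }
      sav <- data$shared_arm_variance[rows]
      sav <- sav[!is.na(sav)]
      if (length(sav) > 0) {
        if (length(unique(sav)) > 1) {
          stop("study '", sid, "' has conflicting shared_arm_variance values")
        }
        if (sav[1] < 0 || sav[1] >= min(data$se[rows]^2)) {
          stop("shared_arm_variance of study '", sid,
               "' must lie in [0, min(se^2))")
        }
      }
    }
  }

  study_design <- vapply(by_study, function(rows) {
    design_label(c(data$treat_ref[rows], data$treat_alt[rows]))
  }, character(1))
  data$design <- study_design[data$study_id]

  treatments <- sort(unique(all_trts))
  designs <- list()
  for (lab in sort(unique(data$design))) {
    trts <- strsplit(lab, DESIGN_SEP, fixed = TRUE)[[1]]
    studies <- sort(unique(data$study_id[data$design == lab]))
    # a t-arm study must carry all t-1 contrasts so the design dimension
    # is well defined
    for (sid in studies) {
      rows <- by_study[[sid]]
      if (length(rows) != length(trts) - 1) {
        stop("study '", sid, "' reports ", length(rows),
             " contrast(s) but its design ", lab, " needs ",
             length(trts) - 1)
      }
    }
    designs[[lab]] <- list(
      label = lab,
      treatments = trts,
      ref = trts[1],
      alts = trts[-1],
      studies = studies,
      n_trials = length(studies)
    )
  }

  net <- structure(
    list(contrasts = data, treatments = treatments, designs = designs,
         study_rows = by_study),
    class = "nma_network"
  )
  comps <- igraph::components(evidence_graph(net))
  if (comps$no > 1) {
    parts <- split(names(comps$membership), comps$membership)
    stop("network is disconnected; components: ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                      character(1)),
               collapse = " "))
  }
  net
}

#' Read a contrast-level CSV and build the network
#'
#' Expects a UTF-8 comma-separated file with header columns `study_id`,
#' `treat_ref`, `treat_alt`, `effect`, `se` and optionally
#' `shared_arm_variance` (blank allowed). Lines starting with `#` are
#' treated as comments.
#'
#' @param path file path.
#' @return an `nma_network`.
#' @export
read_contrasts <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  data <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  nma_network(data)
}

# Multigraph of the evidence structure: one edge per treatment pair within
# each design, edge attribute `design` carries the design label.
evidence_graph <- function(network) {
  edges <- character(0)
  dlab <- character(0)
  for (d in network$designs) {
    prs <- utils::combn(d$treatments, 2)
    edges <- c(edges, as.vector(prs))
    dlab <- c(dlab, rep(d$label, ncol(prs)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)],
               design = dlab),
    directed = FALSE,
    vertices = data.frame(name = network$treatments)
  )
  g
}

#' @export
print.nma_network <- function(x, ...) {
  n_multi <- sum(vapply(x$designs, function(d) length(d$treatments) > 2,
                        logical(1)))
  cat("Evidence network:", length(x$treatments), "treatments,",
      length(x$designs), "designs,",
      length(unique(x$contrasts$study_id)), "studies\n")
  cat("Treatments:", paste(x$treatments, collapse = ", "), "\n")
  if (n_multi > 0) cat("Multi-arm designs:", n_multi, "\n")
  invisible(x)
}

# Canonicalize one study's contrasts onto the design basis
# (alts-vs-design-reference, alternatives in sorted order). Returns the
# transformed estimate vector and covariance block.
study_canonical <- function(network, design, study_id) {
  idx <- network$study_rows[[study_id]]
  cc <- network$contrasts
  if (length(idx) == 1L && length(design$alts) == 1L) {
    # two-arm study: at most a sign flip onto the canonical orientation
    sgn <- if (cc$treat_alt[idx] == design$alts) 1 else -1
    return(list(y = sgn * cc$effect[idx],
                S = matrix(cc$se[idx]^2, 1L, 1L)))
  }
  r_s <- cc$treat_ref[idx[1]]
  alts_s <- cc$treat_alt[idx]
  y_s <- cc$effect[idx]
  names(y_s) <- alts_s
  se2 <- cc$se[idx]^2
  S <- diag(se2, nrow = length(idx))
  if (length(idx) > 1) {
    sav <- cc$shared_arm_variance[idx]
    sav <- sav[!is.na(sav)]
    if (length(sav) == 0) {
      sav <- min(se2) / 2
      warning("study '", study_id, "': no shared_arm_variance given; ",
              "using half the smallest contrast variance (", signif(sav, 4),
              ")", call. = FALSE)
    } else {
      sav <- sav[1]
    }
    S[upper.tri(S)] <- sav
    S[lower.tri(S)] <- sav
  }
  # transformation to contrasts (a_j - ref_d) for a_j in design$alts:
  #   a - r_d = (a - r_s) - (r_d - r_s), with (r_s - r_s) = 0
  Tm <- matrix(0, length(design$alts), length(idx),
               dimnames = list(design$alts, alts_s))
  for (a in design$alts) {
    if (a != r_s) Tm[a, a] <- 1
    if (design$ref != r_s) Tm[a, design$ref] <- Tm[a, design$ref] - 1
  }
  list(y = drop(Tm %*% y_s), S = Tm %*% S %*% t(Tm))
}

#' Pool the direct evidence of one design
#'
#' Fixed-effect inverse-variance pooling of all trials of a design onto the
#' canonical contrast basis (each non-reference treatment versus the
#' lexicographically first treatment of the design). Multi-arm designs are
#' pooled as vectors with their block covariances.
#'
#' @param network an `nma_network`.
#' @param design design label (e.g. `"A:B"`) or character vector of its
#'   treatments.
#' @return a `design_estimate`: pooled estimate vector `theta`, covariance
#'   `cov`, and the comparison map.
#' @export
pool_design_direct <- function(network, design) {
  lab <- if (length(design) > 1) design_label(design) else design
  d <- network$designs[[lab]]
  if (is.null(d)) stop("design '", lab, "' not in network")
  Wsum <- matrix(0, length(d$alts), length(d$alts))
  wy <- rep(0, length(d$alts))
  for (sid in d$studies) {
    cs <- study_canonical(network, d, sid)
    Wi <- solve_spd(cs$S)
    Wsum <- Wsum + Wi
    wy <- wy + drop(Wi %*% cs$y)
  }
  cov <- solve_spd(Wsum)
  theta <- drop(cov %*% wy)
  names(theta) <- d$alts
  dimnames(cov) <- list(d$alts, d$alts)
  structure(
    list(design = lab, treatments = d$treatments, ref = d$ref, alts = d$alts,
         comparisons = data.frame(ref = d$ref, alt = d$alts),
         theta = theta, cov = cov, n_trials = d$n_trials),
    class = "design_estimate"
  )
}

#' @export
print.design_estimate <- function(x, ...) {
  cat("Design", x$design, "(", x$n_trials, "trial(s) )\n")
  for (i in seq_along(x$alts)) {
    cat(sprintf("  %s vs %s: %.4f (SE %.4f)\n", x$alts[i], x$ref,
                x$theta[i], sqrt(x$cov[i, i])))
  }
  invisible(x)
}

#' Design matrix of the design-level NMA regression
#'
#' One row per design-level contrast (alternative versus design reference),
#' one column per basic parameter (every treatment versus the network
#' reference). Entries lie in `{-1, 0, 1}`.
#'
#' @param network an `nma_network`.
#' @param reference network reference treatment; defaults to the first label
#'   in lexicographic order.
#' @return matrix with attributes `row_map` (data frame with columns
#'   `design`, `ref`, `alt`) and `reference`.
#' @export
build_design_matrix <- function(network, reference = NULL) {
  reference <- reference %||% network$treatments[1]
  if (!reference %in% network$treatments) {
    stop("reference '", reference, "' not a network treatment")
  }
  basics <- setdiff(network$treatments, reference)
  rows <- do.call(rbind, lapply(network$designs, function(d) {
    data.frame(design = d$label, ref = d$ref, alt = d$alts,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  X <- matrix(0, nrow(rows), length(basics),
              dimnames = list(paste0(rows$design, "|", rows$alt, "-", rows$ref),
                              basics))
  for (i in seq_len(nrow(rows))) {
    if (rows$alt[i] != reference) X[i, rows$alt[i]] <- 1
    if (rows$ref[i] != reference) X[i, rows$ref[i]] <- X[i, rows$ref[i]] - 1
  }
  attr(X, "row_map") <- rows
  attr(X, "reference") <- reference
  X
}
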