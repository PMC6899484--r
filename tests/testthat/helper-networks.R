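# Builders for small synthetic networks used across the test files.

# two-arm triangle A,B,C from design-level values (one trial per design)
triangle_network <- function(theta_ab, theta_ac, theta_bc,
                             se_ab = 0.1, se_ac = 0.1, se_bc = 0.1) {
  nma_network(data.frame(
    study_id = c("sAB", "sAC", "sBC"),
    treat_ref = c("A", "A", "B"),
    treat_alt = c("B", "C", "C"),
    effect = c(theta_ab, theta_ac, theta_bc),
    se = c(se_ab, se_ac, se_bc)
  ))
}

random_triangle_values <- function() {
  list(theta = stats::rnorm(3, 0, 1),
       s2 = stats::runif(3, 0.005, 0.25))
}

# exactly consistent random network over `t` treatments: every pair gets a
# single-trial design whose effect is a difference of true basic parameters
consistent_network <- function(t = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trts <- LETTERS[seq_len(t)]
  basic <- c(0, stats::rnorm(t - 1))
  names(basic) <- trts
  prs <- utils::combn(trts, 2)
  nma_network(data.frame(
    study_id = paste0("s", seq_len(ncol(prs))),
    treat_ref = prs[1, ],
    treat_alt = prs[2, ],
    effect = basic[prs[2, ]] - basic[prs[1, ]],
    se = stats::runif(ncol(prs), 0.05, 0.3)
  ))
}

# random (generally inconsistent) complete network with several trials per
# design
random_network <- function(t = 4, trials = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trts <- LETTERS[seq_len(t)]
  prs <- utils::combn(trts, 2)
  rows <- list()
  for (j in seq_len(ncol(prs))) {
    for (i in seq_len(trials)) {
      rows[[length(rows) + 1]] <- data.frame(
        study_id = sprintf("s%d_%d", j, i),
        treat_ref = prs[1, j], treat_alt = prs[2, j],
        effect = stats::rnorm(1), se = stats::runif(1, 0.1, 0.5)
      )
    }
  }
  nma_network(do.call(rbind, rows))
}
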