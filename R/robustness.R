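# Monte Carlo robustness of the least-cost rankings. Each simulation draws
# one benefit and one cost deviate per program from N(0, sd), applies the
# implied multiplicative shock (floored at zero) to that program in every
# package containing it, re-solves the least-cost problem at every target
# level, and tabulates how often each package is optimal within
# quantile-spaced bins of achieved coverage.

#' Draw benefit and cost shocks
#'
#' One benefit deviate and one cost deviate per program per simulation,
#' independent `N(0, sd)`; a program's deviate is shared by every package
#' containing it within a simulation and is constant across the 10 years.
#' Multipliers `1 + delta` are floored at zero (a > 10-sigma event at the
#' default sd).
#'
#' @param n_sims Number of simulations (default 480).
#' @param program_ids Character vector of program ids.
#' @param sd Shock standard deviation (default 0.1).
#' @param seed Integer seed.
#' @return List of class `"shock_draws"` with matrices `benefit_delta`,
#'   `cost_delta`, `benefit_mult`, `cost_mult` (rows = simulations, columns
#'   = programs) and the number of floored multipliers `n_floored`.
#' @export
draw_shocks <- function(n_sims = 480L, program_ids, sd = 0.1, seed = 1L) {
  stopifnot(n_sims >= 1L, sd >= 0, length(program_ids) >= 1L)
  with_seed(seed, {
    k <- length(program_ids)
    bd <- matrix(rnorm(n_sims * k, 0, sd), n_sims, k,
                 dimnames = list(NULL, program_ids))
    cd <- matrix(rnorm(n_sims * k, 0, sd), n_sims, k,
                 dimnames = list(NULL, program_ids))
    bm <- pmax(1 + bd, 0)
    cm <- pmax(1 + cd, 0)
    n_floored <- sum(1 + bd < 0) + sum(1 + cd < 0)
    if (n_floored > 0) {
      message(n_floored, " shock multiplier(s) floored at 0")
    }
    structure(
      list(benefit_delta = bd, cost_delta = cd,
           benefit_mult = bm, cost_mult = cm, sd = sd,
           n_floored = n_floored),
      class = "shock_draws"
    )
  })
}

#' Perturb package evaluations with one shock draw
#'
#' Package costs are re-summed from the per-program discounted costs scaled
#' by their cost multipliers (costs are additive). Package coverage is
#' non-additive, so the perturbed discounted coverage is the central package
#' coverage scaled by the coverage-weighted mean of the member programs'
#' benefit multipliers, where each member's weight is its share of the
#' package's single-program coverage sum; single-program packages reduce to
#' exact scaling.
#'
#' @param evaluations Central evaluation data frame (columns `id`, `dcov`,
#'   `dcost`, `n_programs`).
#' @param membership 0/1 matrix, packages x programs.
#' @param program_dcov,program_dcost Named per-program single-program
#'   discounted coverage and discounted cost.
#' @param benefit_mult,cost_mult Named per-program multipliers for one
#'   simulation.
#' @return The evaluation data frame with perturbed `dcov` and `dcost`.
#' @export
perturb_evaluations <- function(evaluations, membership,
                                program_dcov, program_dcost,
                                benefit_mult, cost_mult) {
  ids <- colnames(membership)
  if (!all(ids %in% names(benefit_mult)) ||
      !all(ids %in% names(cost_mult))) {
    stop("shock draw does not cover all programs", call. = FALSE)
  }
  bw <- membership * rep(program_dcov[ids], each = nrow(membership))
  denom <- rowSums(bw)
  # If no member has standalone coverage, fall back to equal weights.
  flat <- denom <= 0
  if (any(flat)) {
    bw[flat, ] <- membership[flat, , drop = FALSE]
    denom[flat] <- rowSums(membership[flat, , drop = FALSE])
  }
  cov_scale <- as.vector((bw %*% benefit_mult[ids]) / denom)
  out <- evaluations
  out$dcov <- evaluations$dcov * cov_scale
  out$dcost <- as.vector(
    membership %*% (program_dcost[ids] * cost_mult[ids])
  )
  out
}

#' Run the full set of robustness simulations
#'
#' For every shock draw and every target level, records the least-cost
#' package, its achieved coverage and its cost.
#'
#' @param evaluations Central evaluation data frame.
#' @param membership Packages x programs 0/1 matrix.
#' @param program_dcov,program_dcost Per-program standalone discounted
#'   coverage / cost (named).
#' @param draws A [draw_shocks()] object.
#' @param grid A [build_target_grid()] object or numeric target vector.
#' @return Data frame with columns `sim`, `target`, `package_id`,
#'   `coverage`, `cost`, `feasible`; one row per (simulation, target).
#' @export
run_simulations <- function(evaluations, membership, program_dcov,
                            program_dcost, draws, grid) {
  targets <- if (inherits(grid, "target_grid")) grid$levels else grid
  n_sims <- nrow(draws$benefit_mult)
  out <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    pert <- perturb_evaluations(
      evaluations, membership, program_dcov, program_dcost,
      draws$benefit_mult[s, ], draws$cost_mult[s, ]
    )
    idx <- solve_targets(pert$dcov, pert$dcost, pert$n_programs, pert$id,
                         targets)
    out[[s]] <- data.frame(
      sim = s,
      target = targets,
      package_id = ifelse(is.na(idx), NA_character_, pert$id[idx]),
      coverage = ifelse(is.na(idx), NA_real_, pert$dcov[idx]),
      cost = ifelse(is.na(idx), NA_real_, pert$dcost[idx]),
      feasible = !is.na(idx),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Frequency of optimality within quantile-spaced coverage bins
#'
#' Divides the realized range of achieved optimal coverage (pooled over all
#' simulations and targets) into quantile-spaced bins and, within each bin,
#' ranks packages by how often they were the optimal solution.
#'
#' @param runs Output of [run_simulations()].
#' @param n_bins Number of bins (default 20).
#' @param top Number of top-ranked packages to keep per bin (default 2;
#'   `Inf` keeps all).
#' @return List of class `"bin_frequencies"` with `edges` (bin boundaries)
#'   and `table`, a data frame `bin`, `bin_lo`, `bin_hi`, `rank`,
#'   `package_id`, `frequency` where frequencies within a bin sum to 1 over
#'   all packages (the kept rows hold the top ranks).
#' @export
bin_frequencies <- function(runs, n_bins = 20L, top = 2L) {
  ok <- runs$feasible & !is.na(runs$coverage)
  cov <- runs$coverage[ok]
  pkg <- runs$package_id[ok]
  if (length(cov) == 0L) stop("no feasible simulation records", call. = FALSE)
  if (n_bins > length(unique(cov))) {
    stop("n_bins exceeds the number of distinct coverage records",
         call. = FALSE)
  }
  edges <- quantile(cov, probs = seq(0, 1, length.out = n_bins + 1L),
                    names = FALSE, type = 7)
  bin <- findInterval(cov, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    tab <- sort(table(pkg[sel]) / sum(sel), decreasing = TRUE)
    keep <- seq_len(min(length(tab), top))
    data.frame(
      bin = b, bin_lo = edges[b], bin_hi = edges[b + 1L],
      rank = keep, package_id = names(tab)[keep],
      frequency = as.numeric(tab[keep]),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(edges = edges, table = do.call(rbind, rows), n_bins = n_bins),
    class = "bin_frequencies"
  )
}
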