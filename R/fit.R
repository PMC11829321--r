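# Model fitting: joins the survey-based adequacy engine, the demography
# projection, the cost model and the enumerative optimizer into one fit,
# returned as a classed object with the usual modelling methods.

#' Fit the least-cost vitamin A planning model
#'
#' Evaluates every feasible program package against a household survey over
#' the planning horizon and solves the least-cost selection problem across a
#' grid of effective-coverage targets.
#'
#' The pipeline: (1) assign VAS receipt to children once, by region-specific
#' coverage; (2) compute per-region child inadequacy prevalence for every
#' fortification combination with and without VAS; (3) project child
#' populations; (4) build each package's annual effective-coverage stream,
#' honouring benefit start years (current oil and VAS from year 1, improved
#' oil from year 2, bouillon from year 3), and its annual cost stream under
#' the chosen stakeholder perspective; (5) discount (costs with exponent
#' `t - 1`, benefits with exponent `t`) and solve for each target.
#'
#' @param survey Survey table, one row per child (see
#'   [generate_households()]).
#' @param regions Macro-region table (see [burkina_regions()]).
#' @param programs Program menu (default [generate_programs()] on the
#'   region ids).
#' @param cost_profiles Per-program cost profiles (default
#'   [generate_cost_profiles()]).
#' @param horizon Planning horizon in years (default 10).
#' @param rate Annual discount rate for both benefits and costs (default
#'   0.03).
#' @param n_targets Number of coverage targets (default 40, from ~1% of the
#'   inadequate pool in ~2.5 percentage-point steps).
#' @param perspective Cost perspective: `"gov_industry"` (default, net of
#'   premix), `"gov"`, or `"all"`.
#' @param seed Integer seed controlling the VAS receipt assignment.
#' @param cost_offset,benefit_offset Discount exponent offsets (defaults 1
#'   and 0: costs `(1+r)^(t-1)`, benefits `(1+r)^t`); set both equal to
#'   harmonize the conventions.
#' @param projection `"geometric"` (default) or `"linear"` population
#'   interpolation.
#' @return An object of class `"va_fit"`: a list with the package
#'   `evaluations` (id, members, discounted coverage and cost, cost per
#'   child), the least-cost `frontier`, the target `grid`, the discounted
#'   `inadequate_pool`, per-region `baseline_prev`, per-program standalone
#'   statistics, and the streams and matrices needed by [simulate.va_fit()].
#' @examples
#' \donttest{
#' bundle <- generate_bundle(synthetic_config(seed = 1, n_households_per_region = 60))
#' fit <- va_optimize(bundle$survey, bundle$regions)
#' summary(fit)
#' }
#' @export
va_optimize <- function(survey, regions,
                        programs = generate_programs(regions$region_id),
                        cost_profiles = generate_cost_profiles(regions),
                        horizon = 10L, rate = 0.03, n_targets = 40L,
                        perspective = c("gov_industry", "gov", "all"),
                        seed = 1L, cost_offset = 1, benefit_offset = 0,
                        projection = c("geometric", "linear")) {
  perspective <- match.arg(perspective)
  projection <- match.arg(projection)
  regions <- validate_regions(regions)
  programs <- validate_programs(programs)
  cost_profiles <- validate_cost_profiles(cost_profiles)
  cl <- match.call()

  pop_mat <- project_populations(regions, horizon, projection)
  national_index <- population_index(colSums(pop_mat))
  region_index <- lapply(
    setNames(seq_len(nrow(regions)), regions$region_id),
    function(i) population_index(pop_mat[i, ])
  )
  index_for <- function(id) {
    scope <- programs$scope[programs$id == id]
    if (scope == "national") national_index else region_index[[scope]]
  }

  vas_flags <- assign_vas(survey, regions, derive_seed(seed, 1L))
  ptab <- prevalence_table(survey, programs, vas_flags,
                           regions = regions$region_id)

  # Discounted pool of inadequate children (benefit convention), the
  # denominator for target percentages.
  inadequate_by_year <- as.vector(ptab$baseline %*% pop_mat)
  pool <- discounted_sum(inadequate_by_year, rate, benefit_offset)
  grid <- build_target_grid(pool, n_targets)

  oil_ids <- programs$id[programs$kind == "LSFF" & programs$vehicle == "oil"]
  cube_ids <- programs$id[programs$kind == "LSFF" &
                            programs$vehicle == "cube"]
  vas_scopes <- programs$scope[programs$kind == "VAS"]
  packages <- enumerate_packages(oil_ids, cube_ids, vas_scopes)

  # Per-program standalone streams (robustness weights + cost additivity).
  prog_ids <- programs$id
  program_cost <- vapply(prog_ids, function(id) {
    stream <- program_cost_stream(cost_profiles, id, index_for(id),
                                  perspective, horizon)
    discounted_sum(stream, rate, cost_offset)
  }, numeric(1))
  program_cov <- vapply(prog_ids, function(id) {
    p <- programs[programs$id == id, ]
    pkg <- list(
      oil = if (p$vehicle == "oil") id else NA_character_,
      cube = if (p$vehicle == "cube") id else NA_character_,
      vas_regions = if (p$kind == "VAS") p$scope else character(0)
    )
    ef <- coverage_stream(pkg, ptab, pop_mat, programs, horizon)
    discounted_sum(ef, rate, benefit_offset)
  }, numeric(1))

  n_pkg <- length(packages)
  membership <- matrix(0, n_pkg, length(prog_ids),
                       dimnames = list(NULL, prog_ids))
  coverage_streams <- matrix(0, n_pkg, horizon)
  cost_streams <- matrix(0, n_pkg, horizon)
  ids <- character(n_pkg)
  n_programs <- integer(n_pkg)
  oil <- cube <- vas_str <- character(n_pkg)
  for (k in seq_len(n_pkg)) {
    pkg <- packages[[k]]
    ids[k] <- pkg$id
    n_programs[k] <- pkg$n_programs
    oil[k] <- if (is.na(pkg$oil)) "" else pkg$oil
    cube[k] <- if (is.na(pkg$cube)) "" else pkg$cube
    vas_str[k] <- paste(pkg$vas_regions, collapse = ",")
    membership[k, pkg$programs] <- 1
    coverage_streams[k, ] <- coverage_stream(pkg, ptab, pop_mat, programs,
                                             horizon)
    cost_streams[k, ] <- package_cost_stream(pkg$programs, cost_profiles,
                                             index_for, perspective, horizon)
  }
  rownames(membership) <- rownames(coverage_streams) <-
    rownames(cost_streams) <- ids

  disc_b <- (1 + rate)^(seq_len(horizon) - benefit_offset)
  disc_c <- (1 + rate)^(seq_len(horizon) - cost_offset)
  dcov <- as.vector(coverage_streams %*% (1 / disc_b))
  dcost <- as.vector(cost_streams %*% (1 / disc_c))
  evaluations <- data.frame(
    id = ids, oil = oil, cube = cube, vas_regions = vas_str,
    n_programs = n_programs, dcov = dcov, dcost = dcost,
    cost_per_child = ifelse(dcov > 0, dcost / dcov, NA_real_),
    stringsAsFactors = FALSE
  )

  fit <- list(
    call = cl,
    regions = regions,
    programs = programs,
    cost_profiles = cost_profiles,
    perspective = perspective,
    horizon = horizon,
    rate = rate,
    cost_offset = cost_offset,
    benefit_offset = benefit_offset,
    seed = seed,
    pop_mat = pop_mat,
    baseline_prev = ptab$baseline,
    prevalence = ptab,
    vas_flags = vas_flags,
    inadequate_pool = pool,
    grid = grid,
    evaluations = evaluations,
    membership = membership,
    coverage_streams = coverage_streams,
    cost_streams = cost_streams,
    program_dcov = program_cov,
    program_dcost = program_cost,
    frontier = NULL
  )
  fit$frontier <- frontier(evaluations, grid)
  class(fit) <- "va_fit"
  fit
}

#' @export
print.va_fit <- function(x, ...) {
  cat("Least-cost vitamin A planning model\n")
  cat(sprintf("  %d packages over a %d-year horizon, discount rate %.1f%%\n",
              nrow(x$evaluations), x$horizon, 100 * x$rate))
  cat(sprintf("  perspective: %s\n", x$perspective))
  cat(sprintf("  discounted pool of inadequate children: %.1f million\n",
              x$inadequate_pool / 1e6))
  feas <- x$frontier$feasible
  cat(sprintf("  frontier: %d of %d targets feasible (max coverage %.1f%% of pool)\n",
              sum(feas), length(feas),
              100 * max(x$evaluations$dcov) / x$inadequate_pool))
  invisible(x)
}

#' Summarize a fitted planning model
#'
#' Produces the reporting table for the least-cost frontier: package label,
#' VAS regions, children effectively covered (millions, discounted), the
#' percentage of the inadequate pool that represents, total discounted cost
#' (millions of USD), and cost per child covered (USD). Rounding happens
#' only here, at the reporting layer.
#'
#' @param object A `"va_fit"` object.
#' @param collapse Keep only the first grid row for each distinct optimal
#'   package (default `TRUE`, mirroring a scenario-per-row table).
#' @param ... Unused.
#' @return A data frame of class `"summary.va_fit"`.
#' @export
summary.va_fit <- function(object, collapse = TRUE, ...) {
  out <- table3_analogue(object$frontier, object$inadequate_pool,
                         collapse = collapse)
  attr(out, "perspective") <- object$perspective
  attr(out, "rate") <- object$rate
  class(out) <- c("summary.va_fit", "data.frame")
  out
}

#' @export
print.summary.va_fit <- function(x, ...) {
  cat(sprintf("Economically optimal packages (%s perspective, r = %.0f%%)\n\n",
              attr(x, "perspective"), 100 * attr(x, "rate")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Reporting table for a least-cost frontier
#'
#' @param frontier_df A [frontier()] result.
#' @param pool Discounted pool of inadequate children (denominator for the
#'   percentage column).
#' @param collapse Keep one row per distinct optimal package.
#' @return Data frame with columns `package_id`, `vas_regions`,
#'   `children_covered_millions`, `pct_of_inadequate`, `total_cost_musd`,
#'   `cost_per_child_usd`; cost per child is recomputed from the unrounded
#'   cost and coverage, and reported as `NA` for zero coverage.
#' @export
table3_analogue <- function(frontier_df, pool, collapse = TRUE) {
  f <- frontier_df[frontier_df$feasible, , drop = FALSE]
  if (collapse && nrow(f) > 1L) {
    f <- f[!duplicated(f$package_id), , drop = FALSE]
  }
  vas <- sub("^.*VAS\\(([^)]*)\\).*$", "\\1", f$package_id)
  vas[!grepl("VAS\\(", f$package_id)] <- ""
  data.frame(
    package_id = f$package_id,
    vas_regions = vas,
    children_covered_millions = round(f$achieved_coverage / 1e6, 1),
    pct_of_inadequate = round(100 * f$achieved_coverage / pool, 1),
    total_cost_musd = round(f$discounted_cost / 1e6, 1),
    cost_per_child_usd = ifelse(
      f$achieved_coverage > 0,
      round(f$discounted_cost / f$achieved_coverage, 1),
      NA_real_
    ),
    stringsAsFactors = FALSE
  )
}

#' Least-cost package for new coverage targets
#'
#' @param object A `"va_fit"` object.
#' @param target Numeric vector of coverage targets (discounted children);
#'   defaults to the fitted grid.
#' @param ... Unused.
#' @return A [frontier()]-style data frame, one row per target.
#' @export
predict.va_fit <- function(object, target = NULL, ...) {
  if (is.null(target)) return(object$frontier)
  frontier(object$evaluations, target)
}

#' Plot the least-cost frontier
#'
#' Total discounted cost (solid, left axis) and cost per child covered
#' (dashed, right axis) against achieved effective coverage, for the
#' feasible targets.
#'
#' @param x A `"va_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.va_fit <- function(x, ...) {
  f <- x$frontier[x$frontier$feasible, , drop = FALSE]
  if (nrow(f) == 0L) stop("no feasible frontier points to plot", call. = FALSE)
  cov_m <- f$achieved_coverage / 1e6
  cost_m <- f$discounted_cost / 1e6
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  plot(cov_m, cost_m, type = "s", lwd = 2,
       xlab = "Children effectively covered (millions, discounted)",
       ylab = "Total cost (millions USD, discounted)", ...)
  points(cov_m, cost_m, pch = 16, cex = 0.6)
  cpc <- f$cost_per_child
  usable <- is.finite(cpc)
  if (any(usable)) {
    scale <- max(cost_m) / max(cpc[usable])
    lines(cov_m[usable], cpc[usable] * scale, lty = 2)
    axis(4, at = pretty(cpc[usable]) * scale, labels = pretty(cpc[usable]))
    mtext("Cost per child covered (USD)", side = 4, line = 2.5)
    legend("topleft", lty = c(1, 2), lwd = c(2, 1),
           legend = c("total cost", "cost per child"), bty = "n")
  }
  invisible(x)
}

#' Monte Carlo robustness simulations for a fitted model
#'
#' Applies independent `N(0, sd)` proportional shocks to each program's
#' benefits and costs, re-solves the least-cost problem at every target in
#' each of `nsim` simulations, and summarizes how often each package remains
#' optimal within quantile-spaced coverage bins.
#'
#' @param object A `"va_fit"` object.
#' @param nsim Number of simulations (default 480).
#' @param seed Integer seed for the shock draws.
#' @param sd Shock standard deviation (default 0.1).
#' @param n_bins Number of quantile-spaced coverage bins (default 20).
#' @param ... Unused.
#' @return Object of class `"va_sim"`: list with the shock `draws`, the
#'   per-(simulation, target) solution `runs`, and the `bins`
#'   frequency-of-optimality table.
#' @export
simulate.va_fit <- function(object, nsim = 480L, seed = 1L, sd = 0.1,
                            n_bins = 20L, ...) {
  draws <- draw_shocks(nsim, colnames(object$membership), sd, seed)
  runs <- run_simulations(object$evaluations, object$membership,
                          object$program_dcov, object$program_dcost,
                          draws, object$grid)
  bins <- bin_frequencies(runs, n_bins)
  structure(
    list(draws = draws, runs = runs, bins = bins, nsim = nsim, sd = sd,
         seed = seed),
    class = "va_sim"
  )
}

#' @export
print.va_sim <- function(x, ...) {
  cat(sprintf("Robustness run: %d simulations, shock sd %.2f\n",
              x$nsim, x$sd))
  top1 <- x$bins$table[x$bins$table$rank == 1L, , drop = FALSE]
  cat(sprintf("  top choice stays optimal in %.0f%% of records on average\n",
              100 * mean(top1$frequency)))
  cat(sprintf("  %d of %d solution records feasible\n",
              sum(x$runs$feasible), nrow(x$runs)))
  invisible(x)
}

#' @export
summary.va_sim <- function(object, ...) {
  object$bins$table
}
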