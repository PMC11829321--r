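# Least-cost package selection. The feasible set is finite — at most one oil
# program, at most one cube program, any subset of macro-regional VAS
# programs, not all empty — so the optimizer enumerates every package,
# evaluates its discounted 10-year benefit and cost, and solves the
# constrained minimization for each coverage target by exhaustive search.
# Benefits are non-additive across programs (each package is evaluated
# jointly against the household survey); costs are additive.

#' Enumerate all feasible program packages
#'
#' Builds every non-empty combination of at most one oil program, at most one
#' cube program, and any subset of macro-regional VAS programs, each with a
#' canonical deterministic id. With the standard menu (2 oils, 2 cubes, 5
#' regions) this yields `3 * 3 * 2^5 - 1 = 287` packages, 8 of which are
#' national-only.
#'
#' @param oil_options Character vector of oil program ids, or a count (then
#'   generic labels `oil1`, ... are used).
#' @param cube_options Character vector of cube program ids, or a count.
#' @param vas_regions Character vector of macro-region ids with a VAS
#'   option, or a count.
#' @return List of package objects; each is a list with elements `oil`
#'   (id or `NA`), `cube` (id or `NA`), `vas_regions` (character, possibly
#'   empty), `programs` (member program ids, VAS members as `vas_<region>`),
#'   `n_programs`, and canonical `id`.
#' @examples
#' length(enumerate_packages())                 # 287
#' length(enumerate_packages(2, 2, 0))          # 8
#' @export
enumerate_packages <- function(oil_options = c("oil_current", "oil_improved"),
                               cube_options = c("cube_15", "cube_30"),
                               vas_regions = c("O", "C", "N", "E", "W")) {
  as_labels <- function(x, prefix) {
    if (is.numeric(x) && length(x) == 1L) {
      if (x < 0) stop("option counts must be non-negative", call. = FALSE)
      if (x == 0) character(0) else paste0(prefix, seq_len(x))
    } else {
      as.character(x)
    }
  }
  oil_options <- as_labels(oil_options, "oil")
  cube_options <- as_labels(cube_options, "cube")
  vas_regions <- as_labels(vas_regions, "R")

  vas_subsets <- list(character(0))
  for (r in vas_regions) {
    vas_subsets <- c(vas_subsets, lapply(vas_subsets, function(s) c(s, r)))
  }
  packages <- list()
  for (oil in c(NA_character_, oil_options)) {
    for (cube in c(NA_character_, cube_options)) {
      for (vas in vas_subsets) {
        if (is.na(oil) && is.na(cube) && length(vas) == 0L) next
        vas <- sort(vas)
        members <- c(
          if (!is.na(oil)) oil,
          if (!is.na(cube)) cube,
          if (length(vas)) paste0("vas_", vas)
        )
        id <- paste(c(
          if (!is.na(oil)) oil,
          if (!is.na(cube)) cube,
          if (length(vas)) paste0("VAS(", paste(vas, collapse = ","), ")")
        ), collapse = "+")
        packages[[length(packages) + 1L]] <- list(
          oil = oil, cube = cube, vas_regions = vas,
          programs = members, n_programs = length(members), id = id
        )
      }
    }
  }
  packages
}

#' Discounted sum of an annual stream
#'
#' Computes `sum(values[t] / (1 + rate)^(t - offset))` for `t = 1, ...`.
#' The model's cost streams are discounted with `offset = 1` (exponent
#' `t - 1`, first year undiscounted) and benefit streams with `offset = 0`
#' (exponent `t`), as specified; setting both to the same offset harmonizes
#' the conventions.
#'
#' @param values Numeric vector of annual values (year 1 first).
#' @param rate Discount rate (> -1), default 0.03 per year.
#' @param offset 1 for the cost convention, 0 for the benefit convention.
#' @return The discounted scalar sum.
#' @examples
#' discounted_sum(rep(100, 10), 0)             # plain sum
#' discounted_sum(c(5, 0, 0), 0.03, offset = 0)  # 5 / 1.03
#' @export
discounted_sum <- function(values, rate = 0.03, offset = 1) {
  if (rate <= -1) stop("rate must exceed -1", call. = FALSE)
  stopifnot(offset %in% c(0, 1))
  t <- seq_along(values)
  sum(values / (1 + rate)^(t - offset))
}

#' Build the grid of coverage targets
#'
#' Target level k is `pool * (start + step * (k - 1))`: the grid begins at
#' about 1% of the discounted pool of vitamin A-inadequate children and rises
#' in increments of about 2.5 percentage points of that pool.
#'
#' @param inadequate_pool Discounted 10-year sum of inadequate children
#'   (> 0); the denominator for percentage reporting.
#' @param n_levels Number of targets (default 40).
#' @param start,step First level and increment as fractions of the pool.
#' @return List of class `"target_grid"` with elements `levels` (strictly
#'   increasing numeric vector), `pct_of_pool`, and `inadequate_pool`.
#' @export
build_target_grid <- function(inadequate_pool, n_levels = 40L,
                              start = 0.01, step = 0.025) {
  if (!is.finite(inadequate_pool) || inadequate_pool <= 0) {
    stop("inadequate_pool must be strictly positive", call. = FALSE)
  }
  stopifnot(n_levels >= 1L, step > 0)
  pct <- start + step * (seq_len(n_levels) - 1)
  structure(
    list(levels = inadequate_pool * pct, pct_of_pool = pct,
         inadequate_pool = inadequate_pool),
    class = "target_grid"
  )
}

#' Least-cost package for one coverage target
#'
#' Among packages whose discounted coverage meets the target, returns the one
#' with minimum discounted cost. Ties are broken deterministically: higher
#' coverage, then fewer member programs, then canonical id. If no package
#' meets the target the result is marked infeasible.
#'
#' @param evaluations Data frame with columns `id`, `dcov` (discounted
#'   children covered), `dcost` (discounted USD), `n_programs`.
#' @param target Coverage target (discounted children).
#' @return One-row data frame: `target`, `package_id`, `discounted_cost`,
#'   `achieved_coverage`, `n_programs`, `feasible`.
#' @export
least_cost_package <- function(evaluations, target) {
  if (nrow(evaluations) == 0L) stop("empty evaluation list", call. = FALSE)
  ok <- evaluations$dcov >= target
  if (!any(ok)) {
    return(data.frame(
      target = target, package_id = NA_character_,
      discounted_cost = NA_real_, achieved_coverage = NA_real_,
      n_programs = NA_integer_, feasible = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  cand <- evaluations[ok, , drop = FALSE]
  ord <- order(cand$dcost, -cand$dcov, cand$n_programs, cand$id)
  best <- cand[ord[1], , drop = FALSE]
  data.frame(
    target = target, package_id = best$id,
    discounted_cost = best$dcost, achieved_coverage = best$dcov,
    n_programs = as.integer(best$n_programs), feasible = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Least-cost frontier over a target grid
#'
#' Solves the least-cost problem at every grid level. Over feasible levels
#' the optimal discounted cost is non-decreasing in the target.
#'
#' @param evaluations As in [least_cost_package()].
#' @param grid A [build_target_grid()] object (or numeric vector of
#'   targets).
#' @return Data frame with one row per target level, the columns of
#'   [least_cost_package()] plus `target_pct_of_pool` when a grid object is
#'   supplied, and `cost_per_child` (`NA` where coverage is zero or the
#'   level is infeasible).
#' @export
frontier <- function(evaluations, grid) {
  targets <- if (inherits(grid, "target_grid")) grid$levels else grid
  out <- do.call(rbind, lapply(targets, function(tg) {
    least_cost_package(evaluations, tg)
  }))
  if (inherits(grid, "target_grid")) {
    out$target_pct_of_pool <- grid$pct_of_pool
  }
  out$cost_per_child <- ifelse(
    out$feasible & out$achieved_coverage > 0,
    out$discounted_cost / out$achieved_coverage,
    NA_real_
  )
  rownames(out) <- NULL
  out
}

# Fast solver used by the Monte Carlo loop: orders packages by the
# deterministic tie-break, keeps the running coverage maximum, and for each
# target picks the first (cheapest) package meeting it. Equivalent to
# least_cost_package() at every level.
solve_targets <- function(dcov, dcost, n_programs, ids, targets) {
  ord <- order(dcost, -dcov, n_programs, ids)
  cov_sorted <- dcov[ord]
  run_max <- cummax(cov_sorted)
  idx <- vapply(targets, function(tg) {
    hit <- run_max >= tg
    if (!any(hit)) NA_integer_ else ord[which.max(hit)]
  }, integer(1))
  idx
}
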