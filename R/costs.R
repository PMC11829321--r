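# 10-year per-stakeholder cost streams. Each program's profile lists startup
# components (paid uniformly across the startup years) and operational
# components (paid from the year after startup through year 10), any of
# which may scale with the relevant child-population index. Package costs are
# linearly additive across member programs. Three stakeholder perspectives
# are supported; the default analysis perspective is government + industry,
# net of premix costs.

PERSPECTIVES <- list(
  gov = "government",
  gov_industry = c("government", "industry"),
  all = c("government", "industry", "premix")
)

#' Stakeholders included in a cost perspective
#'
#' @param perspective `"gov"`, `"gov_industry"` (default analysis
#'   perspective, net of premix) or `"all"`.
#' @return Character vector of stakeholder labels.
#' @export
perspective_stakeholders <- function(perspective = c("gov_industry", "gov",
                                                     "all")) {
  perspective <- match.arg(perspective)
  PERSPECTIVES[[perspective]]
}

#' Validate a cost-profile table
#'
#' @param profiles Data frame with columns `program_id`, `stakeholder`,
#'   `phase`, `annual_cost_usd`, `population_scaled`, `startup_years`.
#' @return The validated table.
#' @export
validate_cost_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  needed <- c("program_id", "stakeholder", "phase", "annual_cost_usd",
              "population_scaled", "startup_years")
  missing <- setdiff(needed, names(profiles))
  if (length(missing)) {
    stop("cost profile table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(profiles$annual_cost_usd < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (!all(profiles$phase %in% c("startup", "operational"))) {
    stop("phase must be 'startup' or 'operational'", call. = FALSE)
  }
  if (!all(profiles$stakeholder %in% c("government", "industry", "premix"))) {
    stop("stakeholder must be government, industry or premix", call. = FALSE)
  }
  agg <- tapply(profiles$startup_years, profiles$program_id,
                function(x) length(unique(x)))
  if (any(agg != 1L)) {
    stop("startup_years must be constant within a program", call. = FALSE)
  }
  if (any(profiles$phase == "startup" & profiles$startup_years == 0L)) {
    stop("startup components require startup_years > 0", call. = FALSE)
  }
  profiles
}

#' Annual cost stream of one program
#'
#' Years 1 to `startup_years` carry the program's startup components; the
#' remaining years carry its operational components, with
#' population-scaled components multiplied by the population index for the
#' year. Only components belonging to the chosen perspective's stakeholders
#' are summed.
#'
#' @param profiles Cost-profile table (all programs or one).
#' @param program_id Program whose stream to build.
#' @param population_index Per-year index relative to year 1 (element 1 must
#'   be 1); national child-population index for national programs, regional
#'   for VAS.
#' @param perspective Cost perspective (see [perspective_stakeholders()]).
#' @param horizon Number of years (default 10).
#' @return Numeric vector of annual USD costs, length `horizon`.
#' @export
program_cost_stream <- function(profiles, program_id, population_index,
                                perspective = "gov_industry",
                                horizon = 10L) {
  profiles <- validate_cost_profiles(profiles)
  rows <- profiles[profiles$program_id == program_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no cost profile for program ", program_id, call. = FALSE)
  }
  stopifnot(length(population_index) >= horizon)
  if (abs(population_index[1] - 1) > 1e-9) {
    stop("population_index[1] must equal 1", call. = FALSE)
  }
  stakeholders <- perspective_stakeholders(perspective)
  su <- rows$startup_years[1]
  stream <- numeric(horizon)
  for (k in seq_len(nrow(rows))) {
    if (!rows$stakeholder[k] %in% stakeholders) next
    years <- if (rows$phase[k] == "startup") {
      seq_len(min(su, horizon))
    } else if (su < horizon) {
      (su + 1L):horizon
    } else {
      integer(0)
    }
    if (!length(years)) next
    amt <- rep(rows$annual_cost_usd[k], length(years))
    if (rows$population_scaled[k]) amt <- amt * population_index[years]
    stream[years] <- stream[years] + amt
  }
  stream
}

#' Annual cost stream of a program package
#'
#' Costs are linearly additive across programs: the package stream is the
#' year-wise sum of its member programs' streams, each scaled by its own
#' population index (national for LSFF, regional for VAS).
#'
#' @param program_ids Character vector of member program ids.
#' @param profiles Cost-profile table.
#' @param index_for A function `f(program_id)` returning that program's
#'   population index vector, or a single numeric index used for all.
#' @inheritParams program_cost_stream
#' @return Numeric vector of annual USD costs, length `horizon`.
#' @export
package_cost_stream <- function(program_ids, profiles, index_for,
                                perspective = "gov_industry",
                                horizon = 10L) {
  if (is.numeric(index_for)) {
    idx_vec <- index_for
    index_for <- function(id) idx_vec
  }
  stream <- numeric(horizon)
  for (id in program_ids) {
    stream <- stream + program_cost_stream(profiles, id, index_for(id),
                                           perspective, horizon)
  }
  stream
}

#' Read / write a cost-profile table
#'
#' CSV layout: `program_id`, `stakeholder`, `phase`, `annual_cost_usd`,
#' `population_scaled` (0/1), `startup_years`.
#'
#' @param path File path.
#' @return `read_cost_profiles()` returns the validated table;
#'   `write_cost_profiles()` returns `path` invisibly.
#' @export
read_cost_profiles <- function(path) {
  validate_cost_profiles(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cost_profiles
#' @param profiles Table to write.
#' @export
write_cost_profiles <- function(profiles, path) {
  write.csv(validate_cost_profiles(profiles), path, row.names = FALSE)
  invisible(path)
}
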