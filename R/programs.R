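# Program menu: the national large-scale food fortification (LSFF) options
# and the macro-regional vitamin A supplementation (VAS) options a planner
# can combine into packages.

#' Generate the standard vitamin A program menu
#'
#' Returns the nine programs available to planners: four national LSFF
#' programs (two edible-oil variants, two bouillon-cube fortification levels)
#' and one VAS program per macro-region.
#'
#' Parameters: the current oil program reaches 39% compliance at 85% of the
#' 17.5 mg/kg national standard; the improved oil program reaches 75%
#' compliance at the full standard, after a 1-year start-up (benefits begin in
#' year 2). The bouillon programs deliver 15% or 30% of the adult Codex NRV
#' in 2.5 g of cube (48 and 96 mg vitamin A per kg) at 75% compliance, after a
#' 2-year start-up (benefits begin in year 3). VAS is modelled as a daily
#' equivalent intake of 167 µg RAE for covered children, with no start-up.
#'
#' @param vas_regions Character vector of macro-region ids that get a VAS
#'   program (default the five regions of [burkina_regions()]).
#' @return Data frame with one row per program and columns `id`, `label`,
#'   `kind` (`"LSFF"`/`"VAS"`), `scope` (`"national"` or a region id),
#'   `vehicle` (`"oil"`, `"cube"`, or `"none"`), `fortification_mg_kg`,
#'   `compliance`, `relative_level`, `vas_daily_equiv_ugRAE`,
#'   `startup_years`, `first_benefit_year`.
#' @examples
#' generate_programs()
#' @export
generate_programs <- function(vas_regions = c("O", "C", "N", "E", "W")) {
  lsff <- data.frame(
    id = c("oil_current", "oil_improved", "cube_15", "cube_30"),
    label = c("Oil current", "Oil improved", "Cube 15%", "Cube 30%"),
    kind = "LSFF",
    scope = "national",
    vehicle = c("oil", "oil", "cube", "cube"),
    fortification_mg_kg = c(17.5, 17.5, 48, 96),
    compliance = c(0.39, 0.75, 0.75, 0.75),
    relative_level = c(0.85, 1.00, 1.00, 1.00),
    vas_daily_equiv_ugRAE = 0,
    startup_years = c(0L, 1L, 2L, 2L),
    first_benefit_year = c(1L, 2L, 3L, 3L),
    stringsAsFactors = FALSE
  )
  vas <- data.frame(
    id = paste0("vas_", vas_regions),
    label = paste("VAS in", vas_regions),
    kind = "VAS",
    scope = vas_regions,
    vehicle = "none",
    fortification_mg_kg = 0,
    compliance = 1,
    relative_level = 1,
    vas_daily_equiv_ugRAE = 167,
    startup_years = 0L,
    first_benefit_year = 1L,
    stringsAsFactors = FALSE
  )
  validate_programs(rbind(lsff, vas))
}

#' Validate a program table
#'
#' @param programs Program table as returned by [generate_programs()].
#' @return The validated table.
#' @export
validate_programs <- function(programs) {
  stopifnot(is.data.frame(programs))
  needed <- c("id", "kind", "scope", "vehicle", "fortification_mg_kg",
              "compliance", "relative_level", "vas_daily_equiv_ugRAE",
              "startup_years", "first_benefit_year")
  missing <- setdiff(needed, names(programs))
  if (length(missing)) {
    stop("program table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(programs$id)) stop("duplicated program id", call. = FALSE)
  check_fraction(programs$compliance, "compliance")
  check_fraction(programs$relative_level, "relative_level")
  bad_lsff <- programs$kind == "LSFF" & programs$scope != "national"
  if (any(bad_lsff)) {
    stop("LSFF programs must be national in scope", call. = FALSE)
  }
  bad_vas <- programs$kind == "VAS" & programs$scope == "national"
  if (any(bad_vas)) {
    stop("VAS programs must be scoped to a macro-region", call. = FALSE)
  }
  if (any(programs$startup_years < 0 | programs$startup_years > 2)) {
    stop("startup_years must be 0, 1 or 2", call. = FALSE)
  }
  programs
}

#' Read / write a program table as YAML
#'
#' @param path File path (`programs.yaml`).
#' @return `read_programs()` returns the validated program table;
#'   `write_programs()` returns `path` invisibly.
#' @export
read_programs <- function(path) {
  lst <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(lst$programs, function(p) {
    as.data.frame(p, stringsAsFactors = FALSE)
  }))
  df$startup_years <- as.integer(df$startup_years)
  df$first_benefit_year <- as.integer(df$first_benefit_year)
  validate_programs(df)
}

#' @rdname read_programs
#' @param programs Program table to write.
#' @export
write_programs <- function(programs, path) {
  programs <- validate_programs(programs)
  lst <- list(programs = lapply(seq_len(nrow(programs)), function(i) {
    as.list(programs[i, , drop = FALSE])
  }))
  yaml::write_yaml(lst, path)
  invisible(path)
}
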