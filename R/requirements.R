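# Child nutrient and energy requirements. The adequacy model needs, for each
# child, an age- and sex-specific estimated average requirement (EAR) for
# vitamin A and an energy requirement; their ratio (per 1000 kcal) is the
# child's critical dietary density. The exact tables are analysis inputs:
# this default uses IOM-style vitamin A EARs by age band and FAO-style energy
# requirements by age band and sex, and can be replaced wholesale.

#' Default child requirement table
#'
#' Age-banded vitamin A estimated average requirements (EAR, µg RAE/day) and
#' energy requirements (kcal/day) for children 6--59 months of age, by sex.
#' The EAR is not sex-specific at these ages; energy requirements are.
#'
#' @return Data frame with columns `age_lo_months`, `age_hi_months`, `sex`,
#'   `ear_ugRAE_day`, `energy_req_kcal_day`.
#' @examples
#' default_requirements()
#' @export
default_requirements <- function() {
  bands <- data.frame(
    age_lo_months = c(6, 12, 24, 36, 48),
    age_hi_months = c(11, 23, 35, 47, 59),
    ear = c(190, 210, 210, 275, 275),
    energy_m = c(686, 894, 1133, 1281, 1360),
    energy_f = c(643, 869, 1053, 1223, 1293)
  )
  out <- rbind(
    data.frame(age_lo_months = bands$age_lo_months,
               age_hi_months = bands$age_hi_months,
               sex = "male", ear_ugRAE_day = bands$ear,
               energy_req_kcal_day = bands$energy_m,
               stringsAsFactors = FALSE),
    data.frame(age_lo_months = bands$age_lo_months,
               age_hi_months = bands$age_hi_months,
               sex = "female", ear_ugRAE_day = bands$ear,
               energy_req_kcal_day = bands$energy_f,
               stringsAsFactors = FALSE)
  )
  out[order(out$age_lo_months, out$sex), , drop = FALSE]
}

#' Look up child requirements by age and sex
#'
#' @param age_months Integer vector of ages in months (6--59).
#' @param sex Character vector, `"male"` or `"female"` (recycled if length 1).
#' @param requirements Requirement table (see [default_requirements()]).
#' @return Data frame with columns `ear_ugRAE_day` and `energy_req_kcal_day`,
#'   one row per input child.
#' @export
child_requirements <- function(age_months, sex,
                               requirements = default_requirements()) {
  if (any(age_months < 6 | age_months > 59)) {
    stop("child ages must be between 6 and 59 months", call. = FALSE)
  }
  if (length(sex) == 1L) sex <- rep(sex, length(age_months))
  stopifnot(length(sex) == length(age_months))
  if (!all(sex %in% requirements$sex)) {
    stop("unknown sex value; expected one of: ",
         paste(unique(requirements$sex), collapse = ", "), call. = FALSE)
  }
  idx <- vapply(seq_along(age_months), function(i) {
    j <- which(requirements$sex == sex[i] &
                 requirements$age_lo_months <= age_months[i] &
                 requirements$age_hi_months >= age_months[i])
    if (length(j) != 1L) {
      stop(sprintf("no unique requirement row for age %d months, sex %s",
                   age_months[i], sex[i]), call. = FALSE)
    }
    j
  }, integer(1))
  data.frame(
    ear_ugRAE_day = requirements$ear_ugRAE_day[idx],
    energy_req_kcal_day = requirements$energy_req_kcal_day[idx]
  )
}
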