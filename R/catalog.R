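#' Activity catalog
#'
#' Names the fall and ADL archetypes a simulated cohort performs. The default
#' catalog mirrors the SisFall protocol: 15 intentional fall types and 5 ADL
#' archetypes, each with a short code used in file names (`F01`..`F15`,
#' `D01`..`D05`).
#'
#' @param fall_types named character vector: code -> description. Must be unique.
#' @param adl_types named character vector of at least one ADL archetype whose
#'   descriptions are drawn from the supported set (walking, jogging,
#'   sitting down, standing up, stair walking, quiet standing).
#' @return object of class `activity_catalog` with elements `fall_types`,
#'   `adl_types`.
#' @export
activity_catalog <- function(fall_types = sisfall_fall_types(),
                             adl_types = sisfall_adl_types()) {
  if (anyDuplicated(names(fall_types)) || anyDuplicated(names(adl_types)) ||
      anyDuplicated(fall_types))
    xf_stop("activity codes and fall descriptions must be unique", "invalid_argument")
  if (length(adl_types) < 1L)
    xf_stop("need at least one ADL archetype", "invalid_argument")
  structure(list(fall_types = fall_types, adl_types = adl_types),
            class = "activity_catalog")
}

#' The 15 intentional fall archetypes of the SisFall protocol
#' @return named character vector of length 15.
#' @export
sisfall_fall_types <- function() {
  c(F01 = "fall forward while walking caused by a slip",
    F02 = "fall backward while walking caused by a slip",
    F03 = "lateral fall while walking caused by a slip",
    F04 = "fall forward while walking caused by a trip",
    F05 = "fall forward while jogging caused by a trip",
    F06 = "vertical fall while walking caused by fainting",
    F07 = "fall while walking, hands on a table to dampen fall, caused by fainting",
    F08 = "fall forward when trying to get up",
    F09 = "lateral fall when trying to get up",
    F10 = "fall forward when trying to sit down",
    F11 = "fall backward when trying to sit down",
    F12 = "lateral fall when trying to sit down",
    F13 = "fall forward while sitting, caused by fainting or falling asleep",
    F14 = "fall backward while sitting, caused by fainting or falling asleep",
    F15 = "lateral fall while sitting, caused by fainting or falling asleep")
}

#' Default ADL archetypes
#' @return named character vector of length 5.
#' @export
sisfall_adl_types <- function() {
  c(D01 = "walking", D02 = "jogging", D03 = "sitting down", D04 = "standing up",
    D05 = "stair walking")
}

#' @export
print.activity_catalog <- function(x, ...) {
  cat(sprintf("<activity_catalog> %d fall types, %d ADL types\n",
              length(x$fall_types), length(x$adl_types)))
  invisible(x)
}

## internal: map an ADL description to its oscillation parameters.
## amp is the magnitude oscillation in g, cadence bounds in Hz; quiet standing
## has no deterministic component so that noise_sd = 0 gives magnitude == 1 g.
adl_archetype_params <- function(description) {
  key <- tolower(description)
  if (grepl("quiet", key))    return(list(amp = c(0, 0),        cadence = c(0.3, 0.4)))
  if (grepl("jog", key))      return(list(amp = c(0.55, 0.80),  cadence = c(2.2, 2.6)))
  if (grepl("stair", key))    return(list(amp = c(0.30, 0.50),  cadence = c(1.4, 2.0)))
  if (grepl("sitting", key))  return(list(amp = c(0.15, 0.30),  cadence = c(0.5, 0.9)))
  if (grepl("standing up", key)) return(list(amp = c(0.15, 0.30), cadence = c(0.5, 0.9)))
  if (grepl("walk", key))     return(list(amp = c(0.25, 0.45),  cadence = c(1.5, 2.5)))
  ## unknown archetypes behave like slow generic movement
  list(amp = c(0.10, 0.25), cadence = c(0.8, 1.5))
}
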