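# Foot archetype parameters --------------------------------------------------

REGION_SCHEMES <- list(
  NF = c("hallux", "other_toes", "medial_forefoot", "lateral_forefoot",
         "medial_midfoot", "lateral_midfoot", "medial_rearfoot",
         "lateral_rearfoot"),
  HB = c("hallux", "medial_forefoot", "lateral_forefoot",
         "medial_rearfoot", "lateral_rearfoot"),
  FB = c("medial_forefoot", "lateral_forefoot",
         "medial_rearfoot", "lateral_rearfoot")
)

#' Construct archetype parameters for a synthetic foot
#'
#' Bundles the anthropometrics and plantar loading pattern that drive every
#' synthetic generator. Regional load shares are fractions of the total
#' stance-phase load impulse assigned to each plantar region of the
#' archetype's region scheme; they must be nonnegative and sum to one.
#'
#' @param foot_length foot length (mm).
#' @param foot_width foot width (mm); must be less than `foot_length`.
#' @param arch_height_ratio medial arch elevation as a fraction in `[0, 1]`
#'   of the built-in arch scale (0 = flat arch, 1 = extreme dome).
#' @param calcaneal_inclination pitch of the calcaneus long axis above the
#'   ground plane (degrees; vertical calcaneus approaches 90).
#' @param body_mass body mass (kg).
#' @param regional_load_shares named nonnegative numeric summing to 1; names
#'   must match the archetype's region scheme.
#' @param archetype one of `"NF"`, `"HB"`, `"FB"`; fixes the region scheme.
#' @param seed integer seed controlling generator randomness.
#' @return an object of class `archetype_params`.
#' @export
archetype_params <- function(foot_length, foot_width, arch_height_ratio,
                             calcaneal_inclination, body_mass,
                             regional_load_shares, archetype = "NF",
                             seed = 0L) {
  archetype <- match.arg(archetype, c("NF", "HB", "FB"))
  if (!is.finite(foot_length) || !is.finite(foot_width) ||
      foot_length <= 0 || foot_width <= 0)
    stop_param("foot dimensions must be positive and finite")
  if (foot_width >= foot_length)
    stop_param("foot_length must exceed foot_width")
  if (!is.finite(arch_height_ratio) || arch_height_ratio < 0 ||
      arch_height_ratio > 1)
    stop_param("arch_height_ratio must be in [0, 1]")
  if (!is.finite(body_mass) || body_mass <= 0)
    stop_param("body_mass must be positive")
  scheme <- REGION_SCHEMES[[archetype]]
  if (is.null(names(regional_load_shares)) ||
      !setequal(names(regional_load_shares), scheme))
    stop_param("regional_load_shares names must match the ", archetype,
               " region scheme: ", paste(scheme, collapse = ", "))
  regional_load_shares <- regional_load_shares[scheme]
  if (any(!is.finite(regional_load_shares)) || any(regional_load_shares < 0))
    stop_param("regional_load_shares must be nonnegative and finite")
  if (abs(sum(regional_load_shares) - 1) > 1e-9)
    stop_param("regional_load_shares must sum to 1")
  structure(list(foot_length = foot_length, foot_width = foot_width,
                 arch_height_ratio = arch_height_ratio,
                 calcaneal_inclination = calcaneal_inclination,
                 body_mass = body_mass,
                 regional_load_shares = regional_load_shares,
                 archetype = archetype, seed = as.integer(seed)),
            class = "archetype_params")
}

#' Default NF / HB / FB archetype parameters
#'
#' Defaults encode the three study archetypes: a typically developed foot
#' (NF), a half-bound foot (HB, binding released in youth) and a full-bound
#' foot (FB, lifelong binding). Foot lengths/widths and body masses are the
#' measured subject values (214.06/84.17 mm, 52.2 kg; 202.81/67.14 mm,
#' 49.1 kg; 165.86/65.25 mm, 47.5 kg). Load shares follow the observed
#' regional patterns: NF loads all regions fairly evenly, HB drops the
#' lesser toes and midfoot, FB additionally drops the hallux and
#' concentrates load on the rearfoot.
#'
#' @param archetype `"NF"`, `"HB"` or `"FB"`.
#' @param seed integer seed.
#' @return an `archetype_params` object.
#' @export
default_archetype <- function(archetype = c("NF", "HB", "FB"), seed = 0L) {
  archetype <- match.arg(archetype)
  switch(archetype,
    NF = archetype_params(
      foot_length = 214.06, foot_width = 84.17, arch_height_ratio = 0.15,
      calcaneal_inclination = 20, body_mass = 52.2,
      regional_load_shares = c(hallux = 0.08, other_toes = 0.05,
                               medial_forefoot = 0.14, lateral_forefoot = 0.13,
                               medial_midfoot = 0.07, lateral_midfoot = 0.08,
                               medial_rearfoot = 0.23, lateral_rearfoot = 0.22),
      archetype = "NF", seed = seed),
    HB = archetype_params(
      foot_length = 202.81, foot_width = 67.14, arch_height_ratio = 0.40,
      calcaneal_inclination = 45, body_mass = 49.1,
      regional_load_shares = c(hallux = 0.06,
                               medial_forefoot = 0.12, lateral_forefoot = 0.12,
                               medial_rearfoot = 0.36, lateral_rearfoot = 0.34),
      archetype = "HB", seed = seed),
    FB = archetype_params(
      foot_length = 165.86, foot_width = 65.25, arch_height_ratio = 0.70,
      calcaneal_inclination = 65, body_mass = 47.5,
      regional_load_shares = c(medial_forefoot = 0.11, lateral_forefoot = 0.11,
                               medial_rearfoot = 0.40, lateral_rearfoot = 0.38),
      archetype = "FB", seed = seed))
}

#' @export
print.archetype_params <- function(x, ...) {
  cat(sprintf("archetype_params [%s]  length %.2f mm, width %.2f mm, mass %.1f kg\n",
              x$archetype, x$foot_length, x$foot_width, x$body_mass))
  cat(sprintf("  arch_height_ratio %.2f, calcaneal_inclination %.0f deg, seed %d\n",
              x$arch_height_ratio, x$calcaneal_inclination, x$seed))
  cat("  load shares:", paste(sprintf("%s=%.2f", names(x$regional_load_shares),
                                      x$regional_load_shares), collapse = " "), "\n")
  invisible(x)
}
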