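#' Define a projection scenario
#'
#' A scenario rescales the wheat- and rice-derived iron components of each
#' individual's intake while holding consumed amounts (and hence energy)
#' fixed: a climate-change depletion multiplier on grain iron density, a
#' biofortification multiplier applied on top, and optional target
#' wholegrain (wheat) and brown (rice) consumption shares. Share targets
#' are "shift up to": individuals already above the target keep their
#' current share.
#'
#' @param name Scenario label.
#' @param depletion_factor Multiplier on wheat and rice component iron
#'   density, in (0, 1]; the climate-change baseline uses 0.8.
#' @param biofort_factor Biofortification multiplier (>= 1) applied on top
#'   of depletion.
#' @param target_wholegrain_share Target share of wheat consumed as
#'   wholegrain, in [0, 1], or `NA` to keep each individual's current
#'   share.
#' @param target_brown_share Target share of rice consumed as brown, in
#'   [0, 1], or `NA` for unchanged.
#' @param consumption_factor Global multiplier on wheat/rice consumed
#'   amounts (sensitivity knob; default 1 = consumption unchanged).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, depletion_factor = 0.8,
                          biofort_factor = 1,
                          target_wholegrain_share = NA_real_,
                          target_brown_share = NA_real_,
                          consumption_factor = 1) {
  if (!(depletion_factor > 0 && depletion_factor <= 1))
    stop("depletion_factor must lie in (0, 1]", call. = FALSE)
  if (biofort_factor < 1)
    stop("biofort_factor must be >= 1", call. = FALSE)
  for (s in c(target_wholegrain_share, target_brown_share))
    if (!is.na(s) && (s < 0 || s > 1))
      stop("target shares must lie in [0, 1] (or NA for unchanged)",
           call. = FALSE)
  if (consumption_factor < 0)
    stop("consumption_factor must be >= 0", call. = FALSE)
  structure(
    list(name = name, depletion_factor = depletion_factor,
         biofort_factor = biofort_factor,
         target_wholegrain_share = target_wholegrain_share,
         target_brown_share = target_brown_share,
         consumption_factor = consumption_factor),
    class = "scenario_spec"
  )
}

#' The five standard projection scenarios
#'
#' `basic`: 20% climate-change iron depletion of wheat and rice, no
#' corrective action. `s1`: basic plus 30% biofortification of both
#' grains. `s2`: basic plus a shift of wholegrain wheat consumption up to
#' 50% of total wheat. `s3`: basic plus a shift of brown rice consumption
#' up to 100% of total rice. `s4`: all corrective actions combined.
#'
#' @param depletion 20% depletion expressed as the multiplier 0.8.
#' @param biofort 30% biofortification expressed as the multiplier 1.3.
#' @param wholegrain_target,brown_target Share targets of s2/s3 (and s4).
#' @return Named list of five [scenario_spec()] objects.
#' @export
default_scenarios <- function(depletion = 0.8, biofort = 1.3,
                              wholegrain_target = 0.5,
                              brown_target = 1.0) {
  list(
    basic = scenario_spec("basic", depletion),
    s1 = scenario_spec("s1", depletion, biofort),
    s2 = scenario_spec("s2", depletion,
                       target_wholegrain_share = wholegrain_target),
    s3 = scenario_spec("s3", depletion, target_brown_share = brown_target),
    s4 = scenario_spec("s4", depletion, biofort,
                       target_wholegrain_share = wholegrain_target,
                       target_brown_share = brown_target)
  )
}

# share* = target if set and above the current share, else current
shifted_share <- function(current, target) {
  if (is.na(target)) current else pmax(current, target)
}

#' Project individual iron intake under a scenario
#'
#' Consumed grams are held fixed. Each individual's wheat iron becomes
#' `wheat_g * blend(share*) * depletion * biofort` where `blend(s)` is the
#' share-weighted component density `s * rho_whole + (1 - s) *
#' rho_refined` built from the individual's effective component densities,
#' and `share*` is the (possibly shifted) wholegrain share; rice is
#' analogous with brown/white densities. Other-source iron is unchanged.
#'
#' @param intakes Intake rows from [compute_intakes()] (needs the
#'   component columns `wheat_g_day`, `wheat_whole_g_day`, `rho_*`, etc.).
#' @param spec A [scenario_spec()].
#' @return Numeric vector: adjusted total iron, mg/day, one per row.
#' @export
apply_scenario <- function(intakes, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  need <- c("wheat_g_day", "rice_g_day", "wheat_whole_g_day",
            "rice_brown_g_day", "wheat_iron_mg_day", "rice_iron_mg_day",
            "iron_mg_day", "rho_wheat_whole", "rho_wheat_refined",
            "rho_rice_brown", "rho_rice_white")
  miss <- setdiff(need, names(intakes))
  if (length(miss))
    stop("intakes lack component column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  mult <- spec$depletion_factor * spec$biofort_factor *
    spec$consumption_factor

  cur_w <- ifelse(intakes$wheat_g_day > 0,
                  intakes$wheat_whole_g_day / intakes$wheat_g_day, 0)
  sw <- shifted_share(cur_w, spec$target_wholegrain_share)
  if (any(intakes$wheat_g_day > 0 &
          (is.na(intakes$rho_wheat_whole) |
             is.na(intakes$rho_wheat_refined))))
    stop("missing wheat component iron densities", call. = FALSE)
  wheat_iron <- ifelse(
    intakes$wheat_g_day > 0,
    intakes$wheat_g_day *
      blend_density(sw, intakes$rho_wheat_whole,
                    intakes$rho_wheat_refined) * mult,
    0)

  cur_b <- ifelse(intakes$rice_g_day > 0,
                  intakes$rice_brown_g_day / intakes$rice_g_day, 0)
  sb <- shifted_share(cur_b, spec$target_brown_share)
  if (any(intakes$rice_g_day > 0 &
          (is.na(intakes$rho_rice_brown) |
             is.na(intakes$rho_rice_white))))
    stop("missing rice component iron densities", call. = FALSE)
  rice_iron <- ifelse(
    intakes$rice_g_day > 0,
    intakes$rice_g_day *
      blend_density(sb, intakes$rho_rice_brown,
                    intakes$rho_rice_white) * mult,
    0)

  other_iron <- intakes$iron_mg_day - intakes$wheat_iron_mg_day -
    intakes$rice_iron_mg_day
  other_iron + wheat_iron + rice_iron
}

#' Per-individual and group-mean scenario deltas
#'
#' @param intakes Intake rows from [compute_intakes()].
#' @param spec Scenario to evaluate.
#' @param baseline_spec Scenario to compare against (default: the
#'   climate-change `basic` scenario).
#' @return A list: `delta` (per-individual, mg/day, in row order) and
#'   `mean_delta` (group mean).
#' @export
scenario_delta <- function(intakes, spec,
                           baseline_spec = default_scenarios()$basic) {
  d <- apply_scenario(intakes, spec) -
    apply_scenario(intakes, baseline_spec)
  list(delta = d, mean_delta = mean(d))
}

#' Run all scenarios over a cohort
#'
#' Evaluates each scenario on every individual, recomputes adequacy gaps
#' under the projected intakes, and assembles per-(sex, age class, scenario)
#' results including the mean delta versus the baseline scenario, the
#' least-significant-delta half-width from the current-diet intake
#' distribution, and the strict significance flag. Infants (<1 year) are
#' excluded from projections.
#'
#' @param intakes Intake rows from [compute_intakes()] (with `sex`,
#'   `age_years`, `age_class`).
#' @param scenarios Named list of [scenario_spec()]s; must include the
#'   `baseline` name.
#' @param schedule A [pri_schedule()].
#' @param baseline Name of the baseline scenario for deltas ("basic").
#' @param z Normal quantile for the half-width rule.
#' @return A list: `results` (data frame: sex, age_class, scenario, n,
#'   mean_iron_mg_day, mean_delta_vs_baseline, mean_gap_mg_day,
#'   half_width, significant), `individual` (matrix of per-individual
#'   projected iron, one column per scenario), and `figure_series` (long
#'   data frame of baseline vs scenario adequacy gaps per group).
#' @export
run_all_scenarios <- function(intakes, scenarios = default_scenarios(),
                              schedule = pri_schedule(),
                              baseline = "basic", z = 1.96) {
  if (!baseline %in% names(scenarios))
    stop("scenarios must include the baseline '", baseline, "'",
         call. = FALSE)
  keep <- intakes$age_class != "<1"
  intakes <- intakes[keep, , drop = FALSE]
  if (nrow(intakes) == 0L)
    stop("no individuals left after excluding infants", call. = FALSE)

  proj <- vapply(scenarios, function(sp) apply_scenario(intakes, sp),
                 numeric(nrow(intakes)))
  if (is.null(dim(proj)))
    proj <- matrix(proj, nrow = 1L,
                   dimnames = list(NULL, names(scenarios)))
  base_iron <- proj[, baseline]

  groups <- unique(intakes[c("sex", "age_class")])
  groups <- groups[order(groups$sex, match(groups$age_class,
                                           age_class_labels())), ,
                   drop = FALSE]
  res <- list()
  fig <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- intakes$sex == groups$sex[i] &
      intakes$age_class == groups$age_class[i]
    n <- sum(sel)
    hw <- if (n >= 2)
      least_significant_delta(stats::sd(intakes$iron_mg_day[sel]), n, z)
    else NA_real_
    base_gap <- mean(adequacy_gap(base_iron[sel], intakes$sex[sel],
                                  intakes$age_years[sel], schedule))
    for (nm in names(scenarios)) {
      iron <- proj[sel, nm]
      gap <- mean(adequacy_gap(iron, intakes$sex[sel],
                               intakes$age_years[sel], schedule))
      delta <- mean(iron - base_iron[sel])
      res[[length(res) + 1L]] <- data.frame(
        sex = groups$sex[i], age_class = groups$age_class[i],
        scenario = nm, n = n,
        mean_iron_mg_day = mean(iron),
        mean_delta_vs_baseline = delta,
        mean_gap_mg_day = gap,
        half_width = hw,
        significant = if (!is.na(hw)) flag_significant(delta, hw) else NA,
        stringsAsFactors = FALSE
      )
      fig[[length(fig) + 1L]] <- data.frame(
        sex = groups$sex[i], age_class = groups$age_class[i],
        scenario = nm, baseline_gap = base_gap, scenario_gap = gap,
        stringsAsFactors = FALSE
      )
    }
  }
  list(results = do.call(rbind, res),
       individual = proj,
       figure_series = do.call(rbind, fig))
}
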