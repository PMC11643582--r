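#' Configure the synthetic dietary survey generator
#'
#' The generator emulates a national two-day diary survey: per (sex, age
#' class) cell it draws individuals whose two-day-mean total iron intake
#' is lognormal with the configured group mean/SD, wheat amounts are
#' lognormal, rice consumption is zero-inflated (a Bernoulli non-consumer
#' gate times a lognormal amount), and wheat/rice arrive partly through
#' composite foods so that recipe decomposition is non-trivial.
#'
#' @param targets Calibration targets, one row per (sex, age class), in
#'   the shape of [italian_survey_targets()] (the default). Subset the
#'   rows to simulate fewer groups.
#' @param group_sizes Optional override of `targets$n`: a single count for
#'   all groups or a vector matching the rows of `targets`.
#' @param rice_zero_prob Probability that an individual consumes no rice.
#' @param wholegrain_share0 Baseline mean share of wheat consumed as
#'   wholegrain.
#' @param brown_share0 Baseline mean share of rice consumed as brown.
#' @param within_person_cv Within-person day-to-day coefficient of
#'   variation; the two diary days scatter around the individual's latent
#'   mean with this CV while averaging to it exactly.
#' @param wholegrain_refined_ratio Iron-density ratio wholegrain:refined
#'   wheat (>= 1).
#' @param brown_white_ratio Iron-density ratio brown:white rice (>= 1).
#' @param share_concentration Beta concentration of the per-individual
#'   wholegrain/brown shares around their baseline means.
#' @param holiday_prob Probability a survey day falls on a holiday
#'   (metadata only).
#' @param areas Geographical strata sampled uniformly (metadata only).
#' @param seed Integer seed; mandatory.
#' @return A list of class `population_config`.
#' @export
population_config <- function(targets = italian_survey_targets(),
                              group_sizes = NULL,
                              rice_zero_prob = 0.25,
                              wholegrain_share0 = 0.04,
                              brown_share0 = 0.01,
                              within_person_cv = 0.3,
                              wholegrain_refined_ratio = 2,
                              brown_white_ratio = 3,
                              share_concentration = 10,
                              holiday_prob = 0.29,
                              areas = c("Northwest", "Northeast",
                                        "Centre", "South and Islands"),
                              seed = NULL) {
  need <- c("sex", "age_class", "n", "total_g_mean", "total_g_sd",
            "energy_mean", "energy_sd", "iron_mean", "iron_sd",
            "wheat_g_mean", "wheat_g_sd", "wheat_kcal_mean",
            "wheat_iron_mean", "rice_g_mean", "rice_g_sd",
            "rice_kcal_mean", "rice_iron_mean", "cereal_g_mean")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("invalid config field 'targets': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(group_sizes)) {
    if (length(group_sizes) == 1L)
      group_sizes <- rep(group_sizes, nrow(targets))
    if (length(group_sizes) != nrow(targets))
      stop("invalid config field 'group_sizes': length must be 1 or ",
           nrow(targets), call. = FALSE)
    targets$n <- as.integer(group_sizes)
  }
  if (any(targets$n < 1))
    stop("invalid config field 'group_sizes': all group sizes must be >= 1",
         call. = FALSE)
  mean_cols <- c("total_g_mean", "energy_mean", "iron_mean",
                 "wheat_g_mean", "wheat_kcal_mean", "wheat_iron_mean",
                 "rice_g_mean", "rice_kcal_mean", "rice_iron_mean",
                 "cereal_g_mean")
  for (cl in mean_cols)
    if (any(targets[[cl]] <= 0))
      stop("invalid config field 'targets$", cl,
           "': target means must be > 0", call. = FALSE)
  for (cl in c("total_g_sd", "energy_sd", "iron_sd", "wheat_g_sd",
               "rice_g_sd"))
    if (any(targets[[cl]] < 0))
      stop("invalid config field 'targets$", cl,
           "': SDs must be >= 0", call. = FALSE)
  for (nm in c("rice_zero_prob", "wholegrain_share0", "brown_share0",
               "holiday_prob")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("invalid config field '", nm, "': must lie in [0, 1]",
           call. = FALSE)
  }
  if (within_person_cv < 0 || within_person_cv >= 1)
    stop("invalid config field 'within_person_cv': must lie in [0, 1)",
         call. = FALSE)
  if (wholegrain_refined_ratio < 1)
    stop("invalid config field 'wholegrain_refined_ratio': must be >= 1",
         call. = FALSE)
  if (brown_white_ratio < 1)
    stop("invalid config field 'brown_white_ratio': must be >= 1",
         call. = FALSE)
  if (share_concentration <= 0)
    stop("invalid config field 'share_concentration': must be > 0",
         call. = FALSE)
  if (is.null(seed) || !is.finite(seed))
    stop("invalid config field 'seed': an integer seed is mandatory",
         call. = FALSE)
  structure(
    list(targets = targets, rice_zero_prob = rice_zero_prob,
         wholegrain_share0 = wholegrain_share0,
         brown_share0 = brown_share0,
         within_person_cv = within_person_cv,
         wholegrain_refined_ratio = wholegrain_refined_ratio,
         brown_white_ratio = brown_white_ratio,
         share_concentration = share_concentration,
         holiday_prob = holiday_prob, areas = areas,
         seed = as.integer(seed)),
    class = "population_config"
  )
}

# fixed generator constants: allocation of refined wheat grams across the
# wheat foods (fraction of wheat mass), wheat mass fraction of each food,
# the share of white rice eaten plain vs in a composite dish, and the
# densities of the filler foods that absorb the non-grain remainder of
# the diet
generator_constants <- function() {
  list(
    wheat_alloc = c(semolina = 0.35, bread = 0.35, biscuit = 0.15,
                    flakes = 0.15),
    wheat_frac = c(semolina = 1, bread = 0.65, biscuit = 0.55,
                   flakes = 0.80, wholemeal = 1),
    rice_plain_share = 0.8,
    rice_dish_frac = 0.35,
    oc_iron = 0.009, oc_energy = 3.5,       # other cereals (maize, oats)
    plate_iron = 0.012, plate_energy = 1.5, # mixed dishes, meat, veg
    bev_iron = 0.0002, bev_energy = 0.45,   # milk, juice, soft drinks
    water_iron = 0.00005, water_energy = 0.004  # water, tea
  )
}

# per-group derived quantities: component iron densities solving the
# calibration (blend at the baseline share reproduces the target grain
# iron-to-mass ratio), energy densities, and the mean grams of the
# other-cereal filler
group_params <- function(config) {
  tg <- config$targets
  k <- generator_constants()
  s0 <- config$wholegrain_share0
  b0 <- config$brown_share0
  rw <- config$wholegrain_refined_ratio
  rb <- config$brown_white_ratio
  d_wheat <- tg$wheat_iron_mean / tg$wheat_g_mean
  d_rice <- tg$rice_iron_mean / tg$rice_g_mean
  out <- tg
  out$rho_wheat_refined <- d_wheat / (1 - s0 + s0 * rw)
  out$rho_wheat_whole <- rw * out$rho_wheat_refined
  out$rho_rice_white <- d_rice / (1 - b0 + b0 * rb)
  out$rho_rice_brown <- rb * out$rho_rice_white
  out$e_wheat <- tg$wheat_kcal_mean / tg$wheat_g_mean
  out$e_rice <- tg$rice_kcal_mean / tg$rice_g_mean
  # mean cereal-category grams already delivered by wheat/rice foods
  cer_per_refined_g <- sum(k$wheat_alloc[c("semolina", "bread", "flakes")] /
                             k$wheat_frac[c("semolina", "bread", "flakes")])
  cer_wheat <- tg$wheat_g_mean * (s0 + (1 - s0) * cer_per_refined_g)
  cer_rice <- tg$rice_g_mean * (b0 + k$rice_plain_share * (1 - b0))
  out$oc_mean <- pmax(0, tg$cereal_g_mean - cer_wheat - cer_rice)
  out$group_code <- paste(substr(tg$sex, 1, 1), tg$age_class, sep = "_")
  out
}

#' Generate the synthetic food composition table
#'
#' Deterministic given the configuration: per (sex, age class) group it
#' emits refined-wheat and wholegrain-wheat base foods, three composite
#' wheat foods (bread, biscuit, breakfast flakes with wheat fractions
#' strictly between 0 and 1), white and brown rice plus a composite rice
#' dish, an other-cereal food, and three filler foods (mixed plate,
#' beverage, water with trace densities). Component iron densities are
#' derived from the group's target grain iron-to-mass ratio so that the
#' cohort reproduces the published component means; foods differ across
#' age groups the way real diets do (infant foods are denser in iron per
#' gram of grain).
#'
#' @param config A [population_config()].
#' @return A validated `composition_table`.
#' @export
generate_composition_table <- function(config) {
  stopifnot(inherits(config, "population_config"))
  gp <- group_params(config)
  k <- generator_constants()
  rows <- list()
  for (i in seq_len(nrow(gp))) {
    g <- gp[i, ]
    base <- function(food, category, e, fe, wf = 0, rf = 0,
                     wg = 0, br = 0) {
      data.frame(
        food_code = paste(g$group_code, food, sep = "_"),
        category = category, energy_density = e, iron_density = fe,
        wheat_fraction = wf, rice_fraction = rf,
        wholegrain_share = wg, brown_share = br,
        iron_density_wheat_refined = g$rho_wheat_refined,
        iron_density_wheat_whole = g$rho_wheat_whole,
        iron_density_rice_white = g$rho_rice_white,
        iron_density_rice_brown = g$rho_rice_brown,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      base("semolina", "cereal", g$e_wheat, g$rho_wheat_refined, wf = 1),
      base("wholemeal", "cereal", g$e_wheat, g$rho_wheat_whole,
           wf = 1, wg = 1),
      base("bread", "cereal", g$e_wheat,
           k$wheat_frac[["bread"]] * g$rho_wheat_refined,
           wf = k$wheat_frac[["bread"]]),
      base("biscuit", "sweets", g$e_wheat,
           k$wheat_frac[["biscuit"]] * g$rho_wheat_refined,
           wf = k$wheat_frac[["biscuit"]]),
      base("flakes", "cereal", g$e_wheat,
           k$wheat_frac[["flakes"]] * g$rho_wheat_refined,
           wf = k$wheat_frac[["flakes"]]),
      base("rice_white", "cereal", g$e_rice, g$rho_rice_white, rf = 1),
      base("rice_brown", "cereal", g$e_rice, g$rho_rice_brown,
           rf = 1, br = 1),
      base("rice_dish", "mixed", g$e_rice,
           k$rice_dish_frac * g$rho_rice_white, rf = k$rice_dish_frac),
      base("other_cereal", "cereal", k$oc_energy, k$oc_iron),
      base("mixed_plate", "other", k$plate_energy, k$plate_iron),
      base("beverage", "beverages", k$bev_energy, k$bev_iron),
      base("water", "beverages", k$water_energy, k$water_iron)
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  as_composition_table(tab)
}

# moment-matched lognormal draw from standard-normal quantiles
lnorm_from_z <- function(z, m, s) {
  sigma2 <- log(1 + (s / m)^2)
  exp(log(m) - sigma2 / 2 + sqrt(sigma2) * z)
}

beta_share <- function(n, mean, conc) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# allocate the non-grain residual of (iron, energy, grams) to the three
# filler foods; iron has priority, then energy, then total mass
solve_fillers <- function(resid, k) {
  A <- rbind(c(k$plate_iron, k$bev_iron, k$water_iron),
             c(k$plate_energy, k$bev_energy, k$water_energy),
             c(1, 1, 1))
  Ainv <- solve(A)
  g <- resid %*% t(Ainv)
  bad <- which(apply(g < -1e-9, 1L, any))
  g[g < 0] <- 0
  for (i in bad) {
    r <- resid[i, ]
    A2 <- A[1:2, 1:2]
    g2 <- solve(A2, r[1:2])
    if (all(g2 >= 0)) {
      g[i, ] <- c(g2, 0)
    } else if (r[1] >= 0) {
      plate <- r[1] / k$plate_iron
      g[i, ] <- c(plate, 0, max(0, r[3] - plate))
    } else {
      g[i, ] <- c(0, 0, max(0, r[3]))
    }
  }
  colnames(g) <- c("mixed_plate", "beverage", "water")
  g
}

#' Generate a synthetic survey population and its diaries
#'
#' Draws the configured number of individuals per (sex, age class) cell
#' and two non-consecutive diary days each (at least 15 days apart).
#' Per-person latent intakes are drawn from moment-matched lognormals on
#' a one-factor Gaussian copula (heavier eaters eat more of everything),
#' rice passes a Bernoulli non-consumer gate, and each person's wheat is
#' split across base and composite wheat foods with a Beta-distributed
#' wholegrain share. The two diary days scatter around the person's
#' latent mean with the configured within-person CV while averaging to it
#' exactly. Identical seed and configuration give identical output.
#'
#' @param config A [population_config()].
#' @return A list: `individuals` (id, sex, age_years, age_class, area,
#'   survey-day metadata) and `diaries` (individual_id, day_index,
#'   food_code, grams).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  gp <- group_params(config)
  k <- generator_constants()
  lam <- c(iron = 0.7, energy = 0.8, grams = 0.8, wheat = 0.5,
           rice = 0.3)
  ind_rows <- list()
  diary_rows <- list()
  for (i in seq_len(nrow(gp))) {
    g <- gp[i, ]
    n <- g$n
    id <- sprintf("%s_%04d", g$group_code, seq_len(n))

    # ages: completed years uniform over the class, survey starts at 3
    # months for infants; the oldest completed age keeps fraction 0 so
    # ages never exceed 74
    b <- age_class_bounds()
    b <- b[b$age_class == g$age_class, ]
    comp <- sample(seq(b$min_age, b$max_age), n, replace = TRUE)
    frac <- stats::runif(n)
    if (g$age_class == "<1") frac <- stats::runif(n, 0.25, 1)
    age <- comp + ifelse(comp >= 74, 0, frac)

    area <- sample(config$areas, n, replace = TRUE)
    d1 <- sample.int(330, n, replace = TRUE)
    gap <- sample(15:35, n, replace = TRUE)
    h1 <- stats::runif(n) < config$holiday_prob
    h2 <- stats::runif(n) < config$holiday_prob

    # correlated latent intakes (one-factor Gaussian copula)
    u <- stats::rnorm(n)
    z <- vapply(lam, function(l) l * u + sqrt(1 - l^2) * stats::rnorm(n),
                numeric(n))
    if (is.null(dim(z)))
      z <- matrix(z, nrow = 1L, dimnames = list(NULL, names(lam)))
    T_iron <- lnorm_from_z(z[, "iron"], g$iron_mean, g$iron_sd)
    E <- lnorm_from_z(z[, "energy"], g$energy_mean, g$energy_sd)
    G <- lnorm_from_z(z[, "grams"], g$total_g_mean, g$total_g_sd)
    W <- lnorm_from_z(z[, "wheat"], g$wheat_g_mean, g$wheat_g_sd)

    p0 <- config$rice_zero_prob
    if (p0 >= 1) {
      R <- rep(0, n)
    } else {
      m_plus <- g$rice_g_mean / (1 - p0)
      v_plus <- (g$rice_g_sd^2 + g$rice_g_mean^2) / (1 - p0) - m_plus^2
      if (v_plus <= 0) v_plus <- (0.3 * m_plus)^2
      eats <- stats::runif(n) >= p0
      R <- ifelse(eats,
                  lnorm_from_z(z[, "rice"], m_plus, sqrt(v_plus)), 0)
    }

    s_i <- beta_share(n, config$wholegrain_share0,
                      config$share_concentration)
    b_i <- beta_share(n, config$brown_share0, config$share_concentration)

    wheat_iron <- W * (s_i * g$rho_wheat_whole +
                         (1 - s_i) * g$rho_wheat_refined)
    rice_iron <- R * (b_i * g$rho_rice_brown +
                        (1 - b_i) * g$rho_rice_white)

    # per-food per-day-mean grams
    refined <- (1 - s_i) * W
    food_g <- cbind(
      semolina = refined * k$wheat_alloc[["semolina"]],
      wholemeal = s_i * W,
      bread = refined * k$wheat_alloc[["bread"]] /
        k$wheat_frac[["bread"]],
      biscuit = refined * k$wheat_alloc[["biscuit"]] /
        k$wheat_frac[["biscuit"]],
      flakes = refined * k$wheat_alloc[["flakes"]] /
        k$wheat_frac[["flakes"]],
      rice_white = k$rice_plain_share * (1 - b_i) * R,
      rice_brown = b_i * R,
      rice_dish = (1 - k$rice_plain_share) * (1 - b_i) * R /
        k$rice_dish_frac,
      other_cereal = g$oc_mean * W / g$wheat_g_mean
    )
    oc <- food_g[, "other_cereal"]
    resid <- cbind(
      T_iron - wheat_iron - rice_iron - oc * k$oc_iron,
      E - g$e_wheat * rowSums(food_g[, c("semolina", "wholemeal",
                                         "bread", "biscuit", "flakes"),
                                     drop = FALSE]) -
        g$e_rice * rowSums(food_g[, c("rice_white", "rice_brown",
                                      "rice_dish"), drop = FALSE]) -
        k$oc_energy * oc,
      G - rowSums(food_g)
    )
    food_g <- cbind(food_g, solve_fillers(resid, k))

    # split the per-day means across the two days; the split factor keeps
    # the two-day average exactly at the latent mean
    cv <- config$within_person_cv
    f <- if (cv > 0) {
      a <- (1 / cv^2 - 1) / 2
      2 * stats::rbeta(n, a, a)
    } else rep(1, n)

    codes <- paste(g$group_code, colnames(food_g), sep = "_")
    for (day in 1:2) {
      dayf <- if (day == 1L) f else 2 - f
      m <- food_g * dayf
      keep <- m > 0
      diary_rows[[length(diary_rows) + 1L]] <- data.frame(
        individual_id = rep(id, ncol(m))[keep],
        day_index = day,
        food_code = rep(codes, each = n)[keep],
        grams = m[keep],
        stringsAsFactors = FALSE
      )
    }

    ind_rows[[length(ind_rows) + 1L]] <- data.frame(
      individual_id = id, sex = g$sex, age_years = age,
      age_class = g$age_class, area = area,
      day1_date = d1, day2_date = d1 + gap,
      day1_holiday = h1, day2_holiday = h2,
      stringsAsFactors = FALSE
    )
  }
  individuals <- do.call(rbind, ind_rows)
  diaries <- do.call(rbind, diary_rows)
  rownames(individuals) <- rownames(diaries) <- NULL
  diaries <- diaries[order(diaries$individual_id, diaries$day_index,
                           diaries$food_code), ]
  rownames(diaries) <- NULL
  list(individuals = individuals, diaries = diaries)
}

#' Generate a full synthetic survey
#'
#' Convenience wrapper: [generate_population()] plus
#' [generate_composition_table()].
#'
#' @param config A [population_config()].
#' @return A list: `individuals`, `diaries`, `composition`, `config`.
#' @export
#' @examples
#' sim <- simulate_survey(population_config(seed = 1, group_sizes = 20))
#' str(sim$individuals)
simulate_survey <- function(config) {
  pop <- generate_population(config)
  composition <- generate_composition_table(config)
  list(individuals = pop$individuals, diaries = pop$diaries,
       composition = composition, config = config)
}
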