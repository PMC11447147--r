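# Generative model of parent-offspring risk transmission with case-control
# ascertainment. Parents receive genotypes (Hardy-Weinberg at each locus),
# express dementia through the SAME logistic liability the offspring face --
# that shared liability is what makes "parental history" an informative proxy
# for parental genotype -- and transmit alleles Mendelianly. Remote
# consanguinity is modelled at the offspring-genotype level: for same-town
# parental pairs, the offspring's two alleles are identical by descent with
# probability F (the kinship coefficient), giving the classical homozygote
# frequency q^2 + F q (1 - q).

#' Define a risk locus
#'
#' @param chromosome `"autosomal"`, `"X"` or `"Y"`.
#' @param q Risk-allele frequency in (0, 1).
#' @param mode `"dominant"`, `"recessive"` or `"additive"` (autosomal loci;
#'   X-locus expression is governed by `lambda_x`, Y loci are hemizygous).
#' @param gamma Log-odds increment for the risk genotype (per allele when
#'   additive).
#' @param lambda_x Expression attenuation in heterozygous X-carrier females:
#'   1 = full expression, 0 = fully silenced by X-inactivation. Ignored
#'   unless `chromosome = "X"`.
#' @return A `locus` object.
#' @export
locus <- function(chromosome = c("autosomal", "X", "Y"), q,
                  mode = c("dominant", "recessive", "additive"),
                  gamma = 0, lambda_x = 1) {
  chromosome <- match.arg(chromosome)
  mode <- match.arg(mode)
  stopifnot(q > 0, q < 1, lambda_x >= 0, lambda_x <= 1, is.finite(gamma))
  structure(list(chromosome = chromosome, q = q, mode = mode, gamma = gamma,
                 lambda_x = lambda_x),
            class = "locus")
}

#' Simulator configuration
#'
#' Defaults state a realistic late-onset dementia world: controls ascertained
#' unaffected and older than 75, case onset around 72 +/- 9 years, fathers
#' dying earlier than mothers (hence rarer paternal history), ~59% same-town
#' parental pairs, and a kinship coefficient of 1/16 (second-cousin scale)
#' for same-town pairs.
#'
#' @param n_cases,n_controls Target group sizes.
#' @param loci List of [locus()] objects.
#' @param pi_same_town Probability the parents share a birthplace.
#' @param kinship_phi Kinship coefficient for same-town pairs; equals the
#'   offspring inbreeding coefficient F, in `[0, 0.25]`.
#' @param beta0 Baseline log-odds of dementia at age 75 (male, no risk
#'   genotype).
#' @param beta_age Log-odds per year of age.
#' @param beta_sex_female Log-odds increment for females.
#' @param beta_apoe4 Log-odds increment for APOE e4 carriers.
#' @param parent_death_age List with `father` and `mother` each `c(mean, sd)`
#'   in years (liability is evaluated at the parent's death age).
#' @param onset_base `c(mean, sd)` of case onset age, years.
#' @param delta_autozygous Onset shift (years, subtracted) for
#'   autozygous-risk carriers.
#' @param endophenotype_model Per-marker list `c(mean, sd, beta_paternal,
#'   beta_autozygous)`: Gaussian mean/residual SD plus shifts for
#'   paternal-history and autozygous-risk cases. Default signs: paternal
#'   history lowers total tau and raises phosphorylated tau; autozygosity
#'   raises amyloid-beta 42 and phosphorylated tau, lowers total tau.
#' @param apoe_freq Allele frequencies `c(e2, e3, e4)`.
#' @param p_female Offspring female fraction.
#' @param age_at_assessment `c(mean, sd)` of candidate assessment age.
#' @param p_csf Fraction of cases with CSF biomarkers.
#' @param p_missing_history `c(father, mother)` probabilities a history is
#'   unknown.
#' @param p_missing_birthplace `c(control, case)` probabilities both
#'   birthplaces are unknown.
#' @param n_towns Size of the birthplace alphabet.
#' @param assessment_year Calendar year of collection (sets year_of_birth).
#' @param seed RNG seed (single stream per cohort).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cases = 907, n_controls = 2183, loci = list(),
                       pi_same_town = 0.59, kinship_phi = 0.0625,
                       beta0 = -2.4, beta_age = 0.09, beta_sex_female = 0.25,
                       beta_apoe4 = 0,
                       parent_death_age = list(father = c(73, 8),
                                               mother = c(80, 8)),
                       onset_base = c(72, 9), delta_autozygous = 3,
                       endophenotype_model = list(
                         csf_abeta42 = c(mean = 520, sd = 180,
                                         beta_paternal = 0,
                                         beta_autozygous = 70),
                         csf_ttau = c(mean = 640, sd = 320,
                                      beta_paternal = -100,
                                      beta_autozygous = -70),
                         csf_ptau = c(mean = 105, sd = 55,
                                      beta_paternal = 19,
                                      beta_autozygous = 4)),
                       apoe_freq = c(e2 = 0.065, e3 = 0.78, e4 = 0.155),
                       p_female = 0.64,
                       age_at_assessment = c(81, 5), p_csf = 0.365,
                       p_missing_history = c(father = 0.027, mother = 0.011),
                       p_missing_birthplace = c(control = 0.158, case = 0),
                       n_towns = 40, assessment_year = 2015, seed = 1) {
  stopifnot(n_cases >= 0, n_controls >= 0,
            pi_same_town >= 0, pi_same_town <= 1,
            kinship_phi >= 0, kinship_phi <= 0.25,
            onset_base[2] > 0, age_at_assessment[2] > 0,
            all(vapply(loci, inherits, TRUE, "locus")),
            abs(sum(apoe_freq) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw parental genotypes at a locus (Hardy-Weinberg)
#'
#' Fathers carry two autosomal alleles, one X and one Y; mothers two
#' autosomal or X alleles and no Y (`NA`). Genotypes are risk-allele counts.
#'
#' @param loc A [locus()].
#' @param n Number of parental pairs.
#' @return List with integer vectors `father` and `mother`.
#' @export
draw_parent_genotypes <- function(loc, n = 1) {
  stopifnot(inherits(loc, "locus"))
  switch(loc$chromosome,
    autosomal = list(father = stats::rbinom(n, 2, loc$q),
                     mother = stats::rbinom(n, 2, loc$q)),
    X = list(father = stats::rbinom(n, 1, loc$q),
             mother = stats::rbinom(n, 2, loc$q)),
    Y = list(father = stats::rbinom(n, 1, loc$q),
             mother = rep(NA_integer_, n)))
}

#' Mendelian transmission of one locus
#'
#' Autosomal: one random allele per parent. X: sons receive one random
#' maternal X allele; daughters one random maternal allele plus the paternal
#' X. Y: sons receive the paternal Y; daughters carry no Y locus and get
#' `NA` ("absent"), never an error.
#'
#' @param father,mother Parental risk-allele counts (vectors).
#' @param offspring_sex Character vector, `"male"`/`"female"`.
#' @param loc A [locus()].
#' @return Integer vector of offspring risk-allele counts.
#' @export
transmit <- function(father, mother, offspring_sex, loc) {
  stopifnot(inherits(loc, "locus"))
  n <- length(offspring_sex)
  male <- offspring_sex == "male"
  draw_allele <- function(g) {
    # one gamete from a diploid parent: P(risk) = g/2
    stats::rbinom(length(g), 1, g / 2)
  }
  if (loc$chromosome == "autosomal") {
    draw_allele(father) + draw_allele(mother)
  } else if (loc$chromosome == "X") {
    g <- draw_allele(mother)          # one maternal X for everyone
    g[!male] <- g[!male] + father[!male]  # daughters add the paternal X
    g
  } else {
    out <- rep(NA_integer_, n)
    out[male] <- father[male]
    out
  }
}

#' Offspring genotype with the consanguinity (autozygosity) shortcut
#'
#' Mendelian transmission, except that for same-town parental pairs the
#' offspring's two alleles are identical by descent with probability
#' `kinship_phi`: both alleles are then a single population draw, so the
#' homozygote frequency is `q^2 + F q (1 - q)`. Applies to autosomal loci
#' and to the two X alleles of daughters; hemizygous genotypes cannot be
#' autozygous.
#'
#' @param father,mother Parental risk-allele counts.
#' @param offspring_sex Character vector.
#' @param loc A [locus()].
#' @param same_town Logical vector.
#' @param kinship_phi Kinship coefficient F.
#' @return List: `g` (genotypes) and `autozygous_risk` (logical: homozygous
#'   risk by descent).
#' @export
offspring_genotype <- function(father, mother, offspring_sex, loc,
                               same_town = FALSE, kinship_phi = 0) {
  n <- length(offspring_sex)
  same_town <- rep_len(same_town, n)
  g <- transmit(father, mother, offspring_sex, loc)
  autoz <- rep(FALSE, n)
  diploid <- if (loc$chromosome == "autosomal") rep(TRUE, n)
             else if (loc$chromosome == "X") offspring_sex == "female"
             else rep(FALSE, n)
  ibd <- diploid & same_town & (stats::runif(n) < kinship_phi)
  if (any(ibd)) {
    allele <- stats::rbinom(sum(ibd), 1, loc$q)
    g[ibd] <- 2L * allele
    autoz[ibd] <- allele == 1L
  }
  list(g = g, autozygous_risk = autoz)
}

.locus_contribution <- function(g, sex, loc) {
  out <- numeric(length(g))
  male <- sex == "male"
  gg <- ifelse(is.na(g), 0L, g)
  if (loc$chromosome == "Y") {
    out[male & gg == 1] <- loc$gamma
  } else if (loc$chromosome == "X") {
    out[male & gg == 1] <- loc$gamma
    out[!male & gg == 1] <- loc$lambda_x * loc$gamma
    out[!male & gg == 2] <- loc$gamma
  } else {
    out <- switch(loc$mode,
                  dominant = loc$gamma * (gg >= 1),
                  recessive = loc$gamma * (gg == 2),
                  additive = loc$gamma * gg)
  }
  out
}

#' Disease probability from the logistic liability model
#'
#' `logit P = beta0 + beta_age (age - 75) + beta_sex_female [female] + sum of
#' locus contributions + extra`. An X-locus heterozygous female contributes
#' `lambda_x * gamma`, a hemizygous male or homozygous female `gamma`;
#' recessive autosomal loci contribute only when homozygous, additive ones
#' `gamma` per allele.
#'
#' @param genotypes List of genotype vectors, parallel to `config$loci`.
#' @param sex Character vector.
#' @param age Numeric vector, years.
#' @param config A [sim_config()].
#' @param extra Additional log-odds terms (e.g., APOE), default 0.
#' @return Vector of disease probabilities.
#' @export
liability <- function(genotypes, sex, age, config, extra = 0) {
  stopifnot(inherits(config, "sim_config"),
            length(genotypes) == length(config$loci))
  eta <- config$beta0 + config$beta_age * (age - 75) +
    config$beta_sex_female * (sex == "female") + extra
  for (i in seq_along(config$loci)) {
    eta <- eta + .locus_contribution(genotypes[[i]], sex, config$loci[[i]])
  }
  stats::plogis(eta)
}

.draw_apoe <- function(n, freq, same_town, kinship_phi) {
  alleles <- names(freq)
  a1 <- sample(alleles, n, TRUE, prob = freq)
  a2 <- sample(alleles, n, TRUE, prob = freq)
  ibd <- same_town & (stats::runif(n) < kinship_phi)
  a2[ibd] <- a1[ibd]
  paste0(pmin(a1, a2), pmax(a1, a2))
}

#' Generate a synthetic case-control cohort
#'
#' Simulates parental genotypes and phenotypes (through the same liability as
#' the offspring, evaluated at the parent's death age), Mendelian
#' transmission with the consanguinity shortcut, offspring disease status,
#' and case-control ascertainment: emitted controls are unaffected and older
#' than 75, cases are affected, with exactly the requested counts per group.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param max_batches Batch cap for the rejection sampler.
#' @return A `cohort` object (`source = "simulated"`).
#' @export
generate_cohort <- function(config, max_batches = 60) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  need <- c(case = config$n_cases, control = config$n_controls)
  got <- list(case = NULL, control = NULL)
  for (b in seq_len(max_batches)) {
    remaining <- c(need["case"] - NROW(got$case),
                   need["control"] - NROW(got$control))
    if (all(remaining <= 0)) break
    m <- min(500000L, max(2000L, as.integer(4 * max(remaining))))
    batch <- .simulate_batch(config, m)
    for (grp in c("case", "control")) {
      take <- batch[batch$status == grp, , drop = FALSE]
      short <- need[grp] - NROW(got[[grp]])
      if (short > 0 && nrow(take) > 0) {
        got[[grp]] <- rbind(got[[grp]],
                            take[seq_len(min(short, nrow(take))), ,
                                 drop = FALSE])
      }
    }
  }
  if (NROW(got$case) < need["case"] || NROW(got$control) < need["control"]) {
    stop("could not reach target group sizes within the iteration cap; ",
         "consider a larger beta0 (cases) or age window (controls)",
         call. = FALSE)
  }
  df <- rbind(got$case, got$control)
  df$subject_id <- sprintf("S%05d", seq_len(nrow(df)))
  new_cohort(df, source = "simulated")
}

.simulate_batch <- function(config, m) {
  sex <- ifelse(stats::runif(m) < config$p_female, "female", "male")
  same_town <- stats::runif(m) < config$pi_same_town
  f_town <- sample.int(config$n_towns, m, TRUE)
  m_town <- ifelse(same_town, f_town,
                   1L + (f_town - 1L + sample.int(config$n_towns - 1L, m,
                                                  TRUE)) %% config$n_towns)
  n_loci <- length(config$loci)
  off_g <- vector("list", n_loci)
  fat_g <- vector("list", n_loci)
  mot_g <- vector("list", n_loci)
  autoz <- rep(FALSE, m)
  for (i in seq_len(max(n_loci, 0))) {
    loc <- config$loci[[i]]
    pg <- draw_parent_genotypes(loc, m)
    fat_g[[i]] <- pg$father
    mot_g[[i]] <- pg$mother
    og <- offspring_genotype(pg$father, pg$mother, sex, loc, same_town,
                             config$kinship_phi)
    off_g[[i]] <- og$g
    autoz <- autoz | og$autozygous_risk
  }
  f_age <- stats::rnorm(m, config$parent_death_age$father[1],
                        config$parent_death_age$father[2])
  mo_age <- stats::rnorm(m, config$parent_death_age$mother[1],
                         config$parent_death_age$mother[2])
  p_f <- liability(fat_g, rep("male", m), f_age, config)
  p_m <- liability(mot_g, rep("female", m), mo_age, config)
  father_dem <- stats::runif(m) < p_f
  mother_dem <- stats::runif(m) < p_m
  paternal <- ifelse(stats::runif(m) < config$p_missing_history["father"],
                     NA_character_, ifelse(father_dem, "yes", "no"))
  maternal <- ifelse(stats::runif(m) < config$p_missing_history["mother"],
                     NA_character_, ifelse(mother_dem, "yes", "no"))
  apoe <- .draw_apoe(m, config$apoe_freq, same_town, config$kinship_phi)
  e4 <- grepl("e4", apoe)
  education <- pmax(0, round(stats::rnorm(m, 4.3, 3.8)))
  age <- round(pmin(99, pmax(65, stats::rnorm(m, config$age_at_assessment[1],
                                              config$age_at_assessment[2]))),
               1)
  p_dis <- liability(off_g, sex, age, config,
                     extra = config$beta_apoe4 * e4)
  affected <- stats::runif(m) < p_dis
  status <- ifelse(affected, "case",
                   ifelse(age > 75, "control", NA_character_))
  onset <- pmin(95, pmax(45, stats::rnorm(m, config$onset_base[1],
                                          config$onset_base[2]) -
                               config$delta_autozygous * autoz))
  age_assess <- round(ifelse(affected, onset + stats::runif(m, 0, 3), age), 1)
  has_csf <- affected & (stats::runif(m) < config$p_csf)
  em <- config$endophenotype_model
  csf <- lapply(em, function(par) {
    v <- par["mean"] + par["beta_paternal"] *
      (!is.na(paternal) & paternal == "yes") +
      par["beta_autozygous"] * autoz +
      stats::rnorm(m, 0, par["sd"])
    ifelse(has_csf, pmax(v, 1), NA_real_)
  })
  bp_missing <- stats::runif(m) <
    ifelse(affected, config$p_missing_birthplace["case"],
           config$p_missing_birthplace["control"])
  town_name <- function(idx) sprintf("town_%03d", idx)
  data.frame(
    subject_id = NA_character_,
    status = status,
    sex = sex,
    age_at_assessment = round(age_assess, 1),
    age_of_onset = ifelse(affected, round(onset, 1), NA_real_),
    education = education,
    year_of_birth = as.integer(config$assessment_year - round(age_assess)),
    paternal_history = paternal,
    maternal_history = maternal,
    father_birthplace = ifelse(bp_missing, NA_character_, town_name(f_town)),
    mother_birthplace = ifelse(bp_missing, NA_character_, town_name(m_town)),
    n_siblings = stats::rpois(m, 2.5),
    siblings_with_dementia = NA_integer_,
    apoe = apoe,
    csf_abeta42 = csf$csf_abeta42,
    csf_ttau = csf$csf_ttau,
    csf_ptau = csf$csf_ptau,
    age_at_lp = ifelse(has_csf, round(onset + stats::runif(m, 0, 2), 1),
                       NA_real_),
    stringsAsFactors = FALSE
  ) -> out
  out$siblings_with_dementia <- stats::rbinom(m, out$n_siblings, 0.07)
  out[!is.na(out$status), , drop = FALSE]
}

#' Scenario presets
#'
#' Named parameterizations of the generative model, one per analysis arm:
#' \describe{
#'   \item{null}{No genetic effect anywhere; used to calibrate the type-I
#'     error of the dyad-comparison test.}
#'   \item{x_linked}{A common X locus whose expression is attenuated in
#'     heterozygous females (X-inactivation), so maternal history carries
#'     more risk for sons than daughters.}
#'   \item{y_linked}{A paternally transmitted Y locus; maternal-history dyads
#'     behave as under the null.}
#'   \item{recessive_consanguinity}{An autosomal recessive locus plus
#'     same-town kinship, producing autozygosity-driven risk, earlier onset
#'     and the configured endophenotype shifts.}
#'   \item{paperlike}{A mixed scenario calibrated so that parental-history
#'     exposure frequencies land near the published cohort margins
#'     (paternal ~4.7%/13.5%, maternal ~8.9%/26.3% in controls/cases) with
#'     ~59% same-town pairs at n = 3090.}
#' }
#'
#' @param name Preset name.
#' @param n_cases,n_controls,seed Optional overrides.
#' @return A [sim_config()].
#' @export
scenario_preset <- function(name = c("null", "x_linked", "y_linked",
                                     "recessive_consanguinity", "paperlike"),
                            n_cases = NULL, n_controls = NULL, seed = 1) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1], "'; available: null, x_linked, ",
         "y_linked, recessive_consanguinity, paperlike", call. = FALSE))
  cfg <- switch(name,
    null = sim_config(
      loci = list(locus("X", q = 0.2, gamma = 0, lambda_x = 0.5)),
      seed = seed),
    x_linked = sim_config(
      loci = list(locus("X", q = 0.2, gamma = 5.5, lambda_x = 0)),
      beta0 = -5.2, beta_age = 0.07, beta_sex_female = 0.3,
      parent_death_age = list(father = c(71, 8), mother = c(80, 8)),
      seed = seed),
    y_linked = sim_config(
      loci = list(locus("Y", q = 0.2, gamma = 1.4)),
      seed = seed),
    recessive_consanguinity = sim_config(
      loci = list(locus("autosomal", q = 0.15, mode = "recessive",
                        gamma = 1.5)),
      delta_autozygous = 3, seed = seed),
    paperlike = sim_config(
      loci = list(
        locus("X", q = 0.15, gamma = 3.7, lambda_x = 0.7),
        locus("autosomal", q = 0.05, mode = "dominant", gamma = 3.4),
        locus("autosomal", q = 0.05, mode = "dominant", gamma = 3.4),
        locus("autosomal", q = 0.15, mode = "recessive", gamma = 2.0)),
      beta0 = -5.2, beta_age = 0.07, beta_sex_female = 0.3,
      beta_apoe4 = log(2),
      parent_death_age = list(father = c(71, 8), mother = c(80, 8)),
      seed = seed))
  if (!is.null(n_cases)) cfg$n_cases <- n_cases
  if (!is.null(n_controls)) cfg$n_controls <- n_controls
  cfg
}

#' Simulate a female-AD-with-CSF regression subset with known coefficients
#'
#' Draws the ten endophenotype-model covariates with realistic marginals and
#' generates ONE chosen outcome from the linear predictor `X beta` plus
#' Gaussian noise, so [fit_endophenotype_models()] can be checked for exact
#' recovery (`sigma = 0`) and CI coverage. The other potential outcomes are
#' drawn as covariates only; CSF outcomes are floored at 1 pg/mL to respect
#' the schema's positivity invariant (negligible at the default scales).
#'
#' @param n Subset size.
#' @param outcome One of `age_of_onset`, `csf_abeta42`, `csf_ttau`,
#'   `csf_ptau`.
#' @param beta Named coefficient vector: `(Intercept)` plus the ten
#'   predictors of that outcome's model.
#' @param sigma Residual SD.
#' @param seed RNG seed.
#' @return List: `cohort` (a `cohort` of female cases with CSF) and `beta`
#'   (the true coefficients, in model order).
#' @export
simulate_csf_subset <- function(n, outcome = "csf_ptau", beta, sigma = 30,
                                seed = 1) {
  set.seed(seed)
  outcome <- match.arg(outcome, names(.csf_outcomes))
  onset <- stats::rnorm(n, 71, 9)
  covars <- data.frame(
    paternal = stats::rbinom(n, 1, 0.2),
    maternal = stats::rbinom(n, 1, 0.25),
    same_town = stats::rbinom(n, 1, 0.59),
    age_at_lp = onset + stats::runif(n, 0, 2),
    education = pmax(0, round(stats::rnorm(n, 5, 4))),
    apoe_e4 = stats::rbinom(n, 1, 0.45),
    age_of_onset = onset,
    csf_abeta42 = pmax(1, stats::rnorm(n, 520, 180)),
    csf_ttau = pmax(1, stats::rnorm(n, 640, 320)),
    csf_ptau = pmax(1, stats::rnorm(n, 105, 55)),
    year_of_birth = as.integer(2015 - round(onset + stats::runif(n, 0, 3))))
  preds <- c("paternal", "maternal", "same_town", "age_at_lp", "education",
             "apoe_e4",
             setdiff(c("age_of_onset", "csf_abeta42", "csf_ttau", "csf_ptau"),
                     outcome),
             "year_of_birth")
  stopifnot(setequal(names(beta), c("(Intercept)", preds)))
  X <- cbind(1, as.matrix(covars[, preds]))
  colnames(X)[1] <- "(Intercept)"
  beta <- beta[colnames(X)]
  y <- drop(X %*% beta) + stats::rnorm(n, 0, sigma)
  if (outcome != "age_of_onset") y <- pmax(y, 1)
  covars[[outcome]] <- y
  df <- data.frame(
    subject_id = sprintf("F%05d", seq_len(n)),
    status = "case", sex = "female",
    age_at_assessment = round(covars$age_of_onset + 1, 1),
    age_of_onset = covars$age_of_onset,
    education = covars$education,
    year_of_birth = covars$year_of_birth,
    paternal_history = ifelse(covars$paternal == 1, "yes", "no"),
    maternal_history = ifelse(covars$maternal == 1, "yes", "no"),
    father_birthplace = "town_001",
    mother_birthplace = ifelse(covars$same_town == 1, "town_001", "town_002"),
    n_siblings = 2L, siblings_with_dementia = 0L,
    apoe = ifelse(covars$apoe_e4 == 1, "e3e4", "e3e3"),
    csf_abeta42 = covars$csf_abeta42,
    csf_ttau = covars$csf_ttau,
    csf_ptau = covars$csf_ptau,
    age_at_lp = covars$age_at_lp,
    stringsAsFactors = FALSE)
  list(cohort = new_cohort(df, source = "simulated:csf_subset"),
       beta = beta)
}

#' Simulate a cohort from the logistic risk model with known coefficients
#'
#' Covariates are drawn with realistic marginals and case status follows
#' `logit P = beta0 + beta_female female + beta_age (age - 75) +
#' beta_education education + beta_apoe4 e4 + log(or_same_town) same_town`,
#' i.e., the exact model [fit_ad_logistic()] estimates (for cases the age
#' variable is recorded as age of onset).
#'
#' @param n Cohort size.
#' @param or_same_town True odds ratio of the same-town flag.
#' @param beta Named vector `c(beta0, beta_female, beta_age,
#'   beta_education, beta_apoe4)`.
#' @param seed RNG seed.
#' @return A `cohort` object.
#' @export
simulate_risk_cohort <- function(n, or_same_town = 1.3,
                                 beta = c(beta0 = -1.6, beta_female = 0.2,
                                          beta_age = 0.05,
                                          beta_education = 0.02,
                                          beta_apoe4 = 0.8),
                                 seed = 1) {
  set.seed(seed)
  female <- stats::rbinom(n, 1, 0.64)
  age <- stats::rnorm(n, 78, 7)
  education <- pmax(0, round(stats::rnorm(n, 4.5, 4)))
  e4 <- stats::rbinom(n, 1, 0.3)
  same_town <- stats::rbinom(n, 1, 0.59)
  eta <- beta["beta0"] + beta["beta_female"] * female +
    beta["beta_age"] * (age - 75) + beta["beta_education"] * education +
    beta["beta_apoe4"] * e4 + log(or_same_town) * same_town
  case <- stats::runif(n) < stats::plogis(eta)
  df <- data.frame(
    subject_id = sprintf("L%06d", seq_len(n)),
    status = ifelse(case, "case", "control"),
    sex = ifelse(female == 1, "female", "male"),
    age_at_assessment = round(age, 1),
    age_of_onset = ifelse(case, round(age, 1), NA_real_),
    education = education,
    year_of_birth = as.integer(2015 - round(age)),
    paternal_history = "no", maternal_history = "no",
    father_birthplace = "town_001",
    mother_birthplace = ifelse(same_town == 1, "town_001", "town_002"),
    n_siblings = 2L, siblings_with_dementia = 0L,
    apoe = ifelse(e4 == 1, "e3e4", "e3e3"),
    csf_abeta42 = NA_real_, csf_ttau = NA_real_, csf_ptau = NA_real_,
    age_at_lp = NA_real_,
    stringsAsFactors = FALSE)
  new_cohort(df, source = "simulated:logistic")
}
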