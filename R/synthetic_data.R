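#' Parameters for the synthetic case-control cohort generator
#'
#' Defaults reproduce the marginal clinical characteristics of the 351-
#' subject EBC case-control series: 166 cases and 185 controls; case/control
#' mean ages 66.93/56.40 years; smoking-status mixes (current, former,
#' never) of (.434, .476, .090) in cases and (.205, .416, .378) in controls;
#' mean pack-years 43.43/19.21 among ever-smokers and mean quit-years
#' 7.33/9.40 among former smokers. Dispersions are not reported for those
#' marginals, so they are explicit parameters here: ages are normal with
#' `age_sd` (default 10 years), pack- and quit-years gamma-shaped with
#' coefficient of variation `dose_cv` (default 0.8). The underlying-lung-
#' disease trichotomy (carcinogenesis-risk / granulomatous-airway /
#' none-other) uses renormalised per-arm mixes.
#'
#' MicroRNA calls follow a per-microRNA logistic model: control-arm
#' prevalence `mir_baseline_prevalence` with a planted case odds ratio
#' `mir_odds_ratios`. The default panel plants an odds ratio of 2.5 on the
#' miR-21, miR-33b and miR-212 analogues and 1.0 elsewhere. An optional
#' confounding link (`smoking_mir_log_or`) lets current smoking shift call
#' probability, for stress-testing covariate adjustment; it is off by
#' default so planted odds ratios stay interpretable.
#'
#' @param n_cases,n_controls arm sizes (each >= 2).
#' @param age_mean_case,age_mean_control,age_sd age distribution (years).
#' @param smoking_probs_case,smoking_probs_control probabilities over
#'   (current, former, never); must sum to 1.
#' @param pack_years_mean_case,pack_years_mean_control mean pack-years for
#'   ever-smokers per arm.
#' @param quit_years_mean_case,quit_years_mean_control mean quit-years for
#'   former smokers per arm.
#' @param dose_cv coefficient of variation of the gamma pack-/quit-years.
#' @param uld_probs_case,uld_probs_control probabilities over
#'   (risk, granulomatous_airway, none_other).
#' @param male_prob_case,male_prob_control probability male.
#' @param stage_probs case stage mix over (I, II, III, IV).
#' @param panel microRNA ids of the simulated panel.
#' @param mir_baseline_prevalence control-arm call prevalence, recycled over
#'   the panel. Default 0.3.
#' @param mir_odds_ratios named (or recycled) case odds ratios per microRNA.
#' @param missing_rate completely-at-random missingness of calls. Default 0.02.
#' @param smoking_mir_log_or log-odds added to every microRNA for current
#'   smokers (confounding switch). Default 0.
#' @return Object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_cases = 166L, n_controls = 185L,
                              age_mean_case = 66.93, age_mean_control = 56.40,
                              age_sd = 10,
                              smoking_probs_case = c(current = .4337, former = .4759, never = .0904),
                              smoking_probs_control = c(current = .2054, former = .4162, never = .3784),
                              pack_years_mean_case = 43.43,
                              pack_years_mean_control = 19.21,
                              quit_years_mean_case = 7.33,
                              quit_years_mean_control = 9.40,
                              dose_cv = 0.8,
                              uld_probs_case = c(risk = .669, granulomatous_airway = .034, none_other = .297),
                              uld_probs_control = c(risk = .446, granulomatous_airway = .104, none_other = .450),
                              male_prob_case = .488, male_prob_control = .497,
                              stage_probs = c(I = .377, II = .137, III = .356, IV = .130),
                              panel = ebc_mir_panel(),
                              mir_baseline_prevalence = 0.3,
                              mir_odds_ratios = NULL,
                              missing_rate = 0.02,
                              smoking_mir_log_or = 0) {
  if (is.null(mir_odds_ratios)) {
    mir_odds_ratios <- stats::setNames(rep(1, length(panel)), panel)
    planted <- intersect(c("miR-21", "miR-33b", "miR-212"), panel)
    mir_odds_ratios[planted] <- 2.5
  } else if (is.null(names(mir_odds_ratios))) {
    mir_odds_ratios <- stats::setNames(rep_len(mir_odds_ratios, length(panel)), panel)
  } else {
    full <- stats::setNames(rep(1, length(panel)), panel)
    full[names(mir_odds_ratios)] <- mir_odds_ratios
    mir_odds_ratios <- full
  }
  mir_baseline_prevalence <-
    stats::setNames(rep_len(mir_baseline_prevalence, length(panel)), panel)
  check_simplex <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop(what, " must be a probability vector summing to 1")
  }
  check_simplex(smoking_probs_case, "smoking_probs_case")
  check_simplex(smoking_probs_control, "smoking_probs_control")
  check_simplex(uld_probs_case, "uld_probs_case")
  check_simplex(uld_probs_control, "uld_probs_control")
  check_simplex(stage_probs, "stage_probs")
  stopifnot(n_cases >= 2L, n_controls >= 2L,
            all(mir_baseline_prevalence > 0 & mir_baseline_prevalence < 1),
            all(mir_odds_ratios > 0),
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment())[c(
    "n_cases", "n_controls", "age_mean_case", "age_mean_control", "age_sd",
    "smoking_probs_case", "smoking_probs_control",
    "pack_years_mean_case", "pack_years_mean_control",
    "quit_years_mean_case", "quit_years_mean_control", "dose_cv",
    "uld_probs_case", "uld_probs_control",
    "male_prob_case", "male_prob_control", "stage_probs", "panel",
    "mir_baseline_prevalence", "mir_odds_ratios", "missing_rate",
    "smoking_mir_log_or")],
    class = "cohort_sim_params")
}

#' Generate a synthetic case-control cohort
#'
#' Draws a cohort from [cohort_sim_params()]: per-arm clinical covariates
#' (normal ages, multinomial smoking status, gamma pack-/quit-years zeroed
#' for never/non-former smokers, trichotomous underlying lung disease,
#' case-only stage and histology) and binary microRNA calls from the
#' planted logistic model, with completely-at-random missingness. The
#' returned truth record retains every planted parameter.
#'
#' @param params a [cohort_sim_params()].
#' @param seed integer seed; identical params + seed give identical output.
#' @return List with `cohort` (data frame, one row per subject) and `truth`
#'   (the planted parameters).
#' @export
#' @examples
#' sim <- generate_cohort(seed = 1)
#' table(sim$cohort$status)
generate_cohort <- function(params = cohort_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(seed)
  p <- params
  n <- p$n_cases + p$n_controls
  status <- c(rep("case", p$n_cases), rep("control", p$n_controls))
  is_case <- status == "case"
  gshape <- 1 / p$dose_cv^2
  draw_arm <- function(case_val, ctrl_val) ifelse(is_case, case_val, ctrl_val)
  age <- stats::rnorm(n, draw_arm(p$age_mean_case, p$age_mean_control), p$age_sd)
  gender <- ifelse(stats::runif(n) < draw_arm(p$male_prob_case, p$male_prob_control),
                   "male", "female")
  smk_lvls <- c("current", "former", "never")
  smoking <- character(n)
  smoking[is_case] <- sample(smk_lvls, p$n_cases, TRUE, p$smoking_probs_case)
  smoking[!is_case] <- sample(smk_lvls, p$n_controls, TRUE, p$smoking_probs_control)
  rgam <- function(k, mean) if (k > 0) stats::rgamma(k, shape = gshape,
                                                     scale = mean / gshape) else numeric(0)
  pack_years <- numeric(n)
  ever <- smoking != "never"
  pack_years[ever & is_case] <- rgam(sum(ever & is_case), p$pack_years_mean_case)
  pack_years[ever & !is_case] <- rgam(sum(ever & !is_case), p$pack_years_mean_control)
  quit_years <- numeric(n)
  fmr <- smoking == "former"
  quit_years[fmr & is_case] <- rgam(sum(fmr & is_case), p$quit_years_mean_case)
  quit_years[fmr & !is_case] <- rgam(sum(fmr & !is_case), p$quit_years_mean_control)
  uld_lvls <- c("risk", "granulomatous_airway", "none_other")
  uld <- character(n)
  uld[is_case] <- sample(uld_lvls, p$n_cases, TRUE, p$uld_probs_case)
  uld[!is_case] <- sample(uld_lvls, p$n_controls, TRUE, p$uld_probs_control)
  stage <- rep(NA_character_, n)
  stage[is_case] <- sample(names(p$stage_probs), p$n_cases, TRUE, p$stage_probs)
  hist_lvls <- c(adeno = .50, squam = .211, undiff_nsclc = .157,
                 small_cell = .090, mets_other = .042)
  histology <- rep(NA_character_, n)
  histology[is_case] <- sample(names(hist_lvls), p$n_cases, TRUE, hist_lvls)
  cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       status = status, age = age, gender = gender,
                       smoking_status = smoking, pack_years = pack_years,
                       quit_years = quit_years, uld_group = uld,
                       stage = stage, histology = histology,
                       stringsAsFactors = FALSE)
  for (m in p$panel) {
    eta <- stats::qlogis(p$mir_baseline_prevalence[[m]]) +
      log(p$mir_odds_ratios[[m]]) * is_case +
      p$smoking_mir_log_or * (smoking == "current")
    call <- stats::rbinom(n, 1L, stats::plogis(eta))
    if (p$missing_rate > 0)
      call[stats::runif(n) < p$missing_rate] <- NA_integer_
    cohort[[m]] <- call
  }
  list(cohort = cohort,
       truth = list(params = unclass(p), seed = seed,
                    planted_mirs = names(p$mir_odds_ratios)[p$mir_odds_ratios != 1]))
}

#' Parameters for the multi-tissue profile-set generator
#'
#' Each individual carries a latent binary lung microRNA profile; each
#' tissue's observed profile copies every latent call with that tissue's
#' concordance probability and otherwise draws an independent call at the
#' population prevalence. High concordance in two tissues makes their
#' profiles similar within individuals. Defaults mirror the pilot
#' topography sub-study design: 12 individuals, 13 microRNAs, five airway
#' levels (EBC, BAL, BB, SP, MW). The default concordances make EBC and BAL
#' track the latent lung profile closely (0.9), mouthwash weakly (0.2) and
#' sputum/bronchial brush hardly at all (0.1), so the expected
#' within-individual similarity gradient of the generated sets runs
#' BAL >> MW > SP/BB, the ordering the pilot sub-study reported.
#'
#' @param n_individuals number of donors (>= 2). Default 12.
#' @param n_mirs panel size. Default 13.
#' @param tissues tissue codes. Default `c("EBC","BAL","BB","SP","MW")`.
#' @param concordance per-tissue copy probability in `[0,1]`, named by
#'   tissue or recycled.
#' @param prevalence population call prevalence for latent and independent
#'   draws. Default 0.5.
#' @return Object of class `topo_sim_params`.
#' @export
topo_sim_params <- function(n_individuals = 12L, n_mirs = 13L,
                            tissues = c("EBC", "BAL", "BB", "SP", "MW"),
                            concordance = c(EBC = 0.9, BAL = 0.9, BB = 0.1,
                                            SP = 0.1, MW = 0.2),
                            prevalence = 0.5) {
  stopifnot(n_individuals >= 2L, n_mirs >= 1L, length(tissues) >= 2L,
            !anyDuplicated(tissues), prevalence > 0, prevalence < 1)
  if (is.null(names(concordance)))
    concordance <- stats::setNames(rep_len(concordance, length(tissues)), tissues)
  if (!all(tissues %in% names(concordance)))
    stop("concordance must cover every tissue")
  concordance <- concordance[tissues]
  if (any(concordance < 0 | concordance > 1))
    stop("concordance values must lie in [0, 1]")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_mirs = as.integer(n_mirs), tissues = tissues,
                 concordance = concordance, prevalence = prevalence),
            class = "topo_sim_params")
}

#' Generate a synthetic multi-tissue profile set
#'
#' @param params a [topo_sim_params()].
#' @param seed integer seed.
#' @return List with `set` (a [tissue_profile_set()]) and `truth` (latent
#'   profiles and parameters).
#' @export
#' @examples
#' sim <- generate_tissue_profiles(seed = 3)
#' similarity_statistic(sim$set, "EBC", "BAL")
generate_tissue_profiles <- function(params = topo_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "topo_sim_params"))
  set.seed(seed)
  p <- params
  inds <- sprintf("I%02d", seq_len(p$n_individuals))
  mirs <- sprintf("mir%02d", seq_len(p$n_mirs))
  latent <- matrix(stats::rbinom(p$n_individuals * p$n_mirs, 1L, p$prevalence),
                   nrow = p$n_individuals,
                   dimnames = list(inds, mirs))
  arr <- array(NA_integer_, dim = c(p$n_individuals, length(p$tissues), p$n_mirs),
               dimnames = list(inds, p$tissues, mirs))
  for (t in p$tissues) {
    copy <- matrix(stats::runif(p$n_individuals * p$n_mirs) < p$concordance[[t]],
                   nrow = p$n_individuals)
    indep <- matrix(stats::rbinom(p$n_individuals * p$n_mirs, 1L, p$prevalence),
                    nrow = p$n_individuals)
    arr[, t, ] <- ifelse(copy, latent, indep)
  }
  list(set = tissue_profile_set(arr),
       truth = list(latent = latent, params = unclass(p), seed = seed))
}

#' Generate a synthetic qPCR plate
#'
#' Simulates well-level realtime-PCR records for end-to-end scoring
#' validation. Each (sample, microRNA) pair has a latent truth call at the
#' given prevalence. Truly present microRNAs amplify in every replicate with
#' Ct uniform on `ct_present_range` and Tm jittered around the primerset's
#' reference; truly absent ones either fail to amplify or, with probability
#' `artifact_rate` per replicate, produce an off-temperature artifact
#' product `artifact_tm_offset` degrees away from the reference.
#'
#' @param n_samples number of samples.
#' @param mir_panel microRNA ids on the plate. Default [ebc_mir_panel()].
#' @param prevalence truth-call prevalence. Default 0.5.
#' @param tm_jitter_sd Tm measurement noise (degrees C, >= 0). Default 0.3.
#' @param seed integer seed.
#' @param n_replicates wells per (sample, microRNA). Default 2.
#' @param artifact_rate per-replicate probability an absent microRNA yields
#'   an artifact product. Default 0.1.
#' @param artifact_tm_offset Tm displacement of artifact products. Default 4.
#' @param ct_present_range Ct range of true amplifications. Default c(25, 40).
#' @param ct_artifact_range Ct range of artifact products. Default c(35, 43.5).
#' @return List with `wells` (well-record data frame), `reference_tm`
#'   (`mir_id`, `reference_tm`) and `truth` (samples x microRNAs 0/1 matrix).
#' @export
#' @examples
#' plate <- generate_qpcr_plate(4, mir_panel = c("miR-21", "miR-33b"),
#'                              tm_jitter_sd = 0, artifact_rate = 0, seed = 2)
#' score_wells(plate$wells, plate$reference_tm)
generate_qpcr_plate <- function(n_samples, mir_panel = ebc_mir_panel(),
                                prevalence = 0.5, tm_jitter_sd = 0.3,
                                seed = 1L, n_replicates = 2L,
                                artifact_rate = 0.1, artifact_tm_offset = 4,
                                ct_present_range = c(25, 40),
                                ct_artifact_range = c(35, 43.5)) {
  stopifnot(n_samples >= 1L, length(mir_panel) >= 1L, tm_jitter_sd >= 0,
            artifact_rate >= 0, artifact_rate <= 1, n_replicates >= 1L)
  set.seed(seed)
  samples <- sprintf("EBC%03d", seq_len(n_samples))
  # deterministic, well-separated reference Tm per primerset
  ref_tm <- round(seq(72, 88, length.out = length(mir_panel)), 1)
  reference_tm <- data.frame(mir_id = mir_panel, reference_tm = ref_tm,
                             stringsAsFactors = FALSE)
  truth <- matrix(stats::rbinom(n_samples * length(mir_panel), 1L, prevalence),
                  nrow = n_samples, dimnames = list(samples, mir_panel))
  rows <- vector("list", n_samples * length(mir_panel) * n_replicates)
  k <- 0L
  for (i in seq_len(n_samples)) for (j in seq_along(mir_panel)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      if (truth[i, j] == 1L) {
        ct <- stats::runif(1, ct_present_range[1L], ct_present_range[2L])
        tm <- ref_tm[j] + stats::rnorm(1, 0, tm_jitter_sd)
      } else if (stats::runif(1) < artifact_rate) {
        ct <- stats::runif(1, ct_artifact_range[1L], ct_artifact_range[2L])
        tm <- ref_tm[j] + artifact_tm_offset + stats::rnorm(1, 0, tm_jitter_sd)
      } else {
        ct <- NA_real_
        tm <- NA_real_
      }
      rows[[k]] <- data.frame(sample_id = samples[i], mir_id = mir_panel[j],
                              replicate = r, ct = ct, tm = tm,
                              is_positive_control = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  list(wells = do.call(rbind, rows), reference_tm = reference_tm,
       truth = truth)
}
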