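#' Class-conditional motion distributions for a synthetic cohort
#'
#' Kinematic reading of the Fried phenotype: pre-frail subjects move more
#' slowly (longer cycle periods), with smaller excursions and noisier
#' tracking than healthy subjects. The defaults make the classes clearly
#' separable — pre-frail periods 1.5x longer, amplitudes 0.7x smaller and
#' jitter 1.5x larger than healthy; set the ratios to 1 for a null cohort
#' with identical class profiles.
#'
#' @param period_ratio,amplitude_ratio,noise_ratio Multipliers applied to
#'   the healthy per-exercise defaults to obtain the pre-frail (and, scaled
#'   further, frail) profile means.
#' @param between_subject_sd Log-normal standard deviation of the
#'   subject-level period and amplitude multipliers (biological
#'   between-subject variability).
#' @param noise_sd Healthy per-axis tracking jitter in meters.
#' @return A `class_profiles` list used by [cohort_spec()].
#' @export
class_profiles <- function(period_ratio = 1.5, amplitude_ratio = 0.7,
                           noise_ratio = 1.5, between_subject_sd = 0.08,
                           noise_sd = 0.008) {
  structure(list(
    healthy = list(period = 1, amplitude = 1, noise_sd = noise_sd),
    pre_frail = list(period = period_ratio, amplitude = amplitude_ratio,
                     noise_sd = noise_sd * noise_ratio),
    frail = list(period = period_ratio^2, amplitude = amplitude_ratio^2,
                 noise_sd = noise_sd * noise_ratio^2),
    between_subject_sd = between_subject_sd
  ), class = "class_profiles")
}

#' Specify a synthetic cohort
#'
#' @param n_per_class Subjects per frailty class.
#' @param classes Frailty classes to generate (default healthy and
#'   pre-frail, the two classes with usable support in community cohorts).
#' @param profiles A [class_profiles()] object.
#' @param exercises Exercises to record; gait is recorded in 3 repetitions.
#' @param frame_rate Hz.
#' @param p_female Probability of female gender (community-cohort default
#'   0.65); males get a 1.1x amplitude multiplier so gender leaves a weak
#'   kinematic trace.
#' @param durations Optional named list of per-exercise recording lengths
#'   in seconds, overriding the protocol defaults (useful to shorten
#'   simulations).
#' @param seed Master seed; every random element derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class, classes = c("healthy", "pre_frail"),
                        profiles = class_profiles(),
                        exercises = exercise_types(),
                        frame_rate = 30, p_female = 0.65,
                        durations = NULL, seed = 1L) {
  if (n_per_class < 1) {
    abort("`n_per_class` must be >= 1", class = "frailmotion_validation_error")
  }
  bad <- setdiff(classes, c("healthy", "pre_frail", "frail"))
  if (length(bad) > 0) {
    abort(paste0("Unknown class(es): ", paste(bad, collapse = ", ")),
          class = "frailmotion_validation_error")
  }
  lapply(exercises, assert_exercise)
  structure(list(n_per_class = n_per_class, classes = classes,
                 profiles = profiles, exercises = exercises,
                 frame_rate = frame_rate, p_female = p_female,
                 durations = durations, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fried components consistent with a target class: healthy = all zero;
# pre-frail = 1-2 positives (slowness/weakness first, the components with a
# kinematic expression); frail = 3-5 positives.
sample_components <- function(class) {
  comp <- setNames(rep(0L, 5), c("WL", "WK", "PE", "SL", "LA"))
  n_pos <- switch(class, healthy = 0L,
                  pre_frail = sample(1:2, 1),
                  frail = sample(3:5, 1))
  if (n_pos > 0) {
    order_pref <- c("SL", "WK", "PE", "LA", "WL")
    picked <- c(order_pref[1:min(n_pos, 2)],
                if (n_pos > 2) sample(order_pref[3:5], n_pos - 2))
    comp[picked] <- 1L
  }
  comp
}

#' Generate a synthetic cohort of subjects and recordings
#'
#' Draws per-subject motion profiles from the class-conditional
#' distributions and generates every requested exercise recording (gait in
#' 3 repetitions). Subject-level speed and amplitude multipliers are shared
#' across exercises, so a slow subject is slow everywhere.
#'
#' @param spec A [cohort_spec()].
#' @return A list with
#'   \describe{
#'     \item{subjects}{tibble: `subject_id`, `gender`, `age`, the five
#'       binary Fried components, `fs`, `frailty_class`;}
#'     \item{recordings}{tibble: `subject_id`, `exercise`, `repetition`,
#'       `recording` (list);}
#'     \item{ground_truth}{tibble with the per-recording analytic ground
#'       truth from [generate_recording()].}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    subs <- list(); recs <- list(); gts <- list()
    sid_n <- 0L
    for (cls in spec$classes) {
      prof_cls <- spec$profiles[[cls]]
      for (i in seq_len(spec$n_per_class)) {
        sid_n <- sid_n + 1L
        sid <- sprintf("S%03d", sid_n)
        gender <- if (runif(1) < spec$p_female) "female" else "male"
        age <- round(runif(1, 60, 88))
        comp <- sample_components(cls)
        subs[[sid_n]] <- tibble::tibble(
          subject_id = sid, gender = gender, age = age,
          WL = comp["WL"], WK = comp["WK"], PE = comp["PE"],
          SL = comp["SL"], LA = comp["LA"])
        # subject-level multipliers, shared across exercises
        bsd <- spec$profiles$between_subject_sd
        speed_mult <- exp(rnorm(1, 0, bsd))
        amp_mult <- exp(rnorm(1, 0, bsd)) * if (gender == "male") 1.1 else 1
        hand <- if (runif(1) < 0.9) "right" else "left"
        for (ex in spec$exercises) {
          n_rep <- if (ex == "gait") 3L else 1L
          for (rep_i in seq_len(n_rep)) {
            base <- motion_profile(ex, frame_rate = spec$frame_rate)
            prof <- motion_profile(
              ex,
              cycle_period = base$cycle_period * prof_cls$period * speed_mult,
              amplitude = base$amplitude * prof_cls$amplitude * amp_mult,
              noise_sd = prof_cls$noise_sd,
              frame_rate = spec$frame_rate,
              duration = if (!is.null(spec$durations))
                spec$durations[[ex]] else NULL,
              dominant_hand = hand)
            gen <- generate_recording(ex, prof,
                                      seed = sample.int(2^31 - 1, 1))
            rec <- gen$recording
            attr(rec, "subject_id") <- sid
            attr(rec, "repetition") <- rep_i
            recs[[length(recs) + 1]] <- tibble::tibble(
              subject_id = sid, exercise = ex, repetition = rep_i,
              recording = list(rec))
            gts[[length(gts) + 1]] <- tibble::tibble(
              subject_id = sid, exercise = ex, repetition = rep_i,
              ground_truth = list(gen$ground_truth))
          }
        }
      }
    }
    subjects <- label_cohort(dplyr::bind_rows(subs))
    list(subjects = subjects,
         recordings = dplyr::bind_rows(recs),
         ground_truth = dplyr::bind_rows(gts))
  })
}
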