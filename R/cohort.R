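#' Fried frailty score
#'
#' The Fried phenotype scores five binary components — unintentional weight
#' loss (WL), weakness (WK), poor endurance (PE), slowness (SL) and low
#' physical activity (LA) — and sums them:
#' `FS = WL + WK + PE + SL + LA`, an integer between 0 and 5.
#'
#' @param wl,wk,pe,sl,la Binary (0/1) component vectors, recycled to a
#'   common length.
#' @return Integer vector of frailty scores in 0..5.
#' @examples
#' fried_score(1, 1, 1, 1, 1)  # 5 -> "frail"
#' @export
fried_score <- function(wl, wk, pe, sl, la) {
  comp <- vctrs_recycle(list(wl = wl, wk = wk, pe = pe, sl = sl, la = la))
  for (nm in names(comp)) {
    v <- comp[[nm]]
    if (!all(v %in% c(0, 1))) {
      abort(paste0("Component `", nm, "` must be binary 0/1"),
            class = "frailmotion_validation_error")
    }
  }
  as.integer(comp$wl + comp$wk + comp$pe + comp$sl + comp$la)
}

vctrs_recycle <- function(lst) {
  n <- max(lengths(lst))
  lapply(lst, function(v) {
    if (length(v) == n) v
    else if (length(v) == 1) rep(v, n)
    else abort("Component lengths must match",
               class = "frailmotion_validation_error")
  })
}

#' Frailty class from the Fried score
#'
#' Score 0 is `healthy`, 1-2 `pre_frail`, 3-5 `frail`.
#'
#' @param fs Integer vector of Fried scores (0..5).
#' @return Factor with levels `healthy`, `pre_frail`, `frail`.
#' @examples
#' frailty_class(0:5)
#' @export
frailty_class <- function(fs) {
  if (!all(fs %in% 0:5)) {
    abort("Fried score must be an integer in 0..5",
          class = "frailmotion_validation_error")
  }
  cls <- ifelse(fs == 0, "healthy", ifelse(fs <= 2, "pre_frail", "frail"))
  factor(cls, levels = c("healthy", "pre_frail", "frail"))
}

#' Attach Fried score and frailty class to a subject table
#'
#' @param subjects A data frame with binary columns `WL`, `WK`, `PE`, `SL`,
#'   `LA` (one row per subject).
#' @return The input as a tibble with `fs` and `frailty_class` columns
#'   appended.
#' @export
label_cohort <- function(subjects) {
  subjects <- tibble::as_tibble(subjects)
  need <- c("WL", "WK", "PE", "SL", "LA")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols) > 0) {
    abort(paste0("Subject table lacks component column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "frailmotion_validation_error")
  }
  subjects$fs <- fried_score(subjects$WL, subjects$WK, subjects$PE,
                             subjects$SL, subjects$LA)
  subjects$frailty_class <- frailty_class(subjects$fs)
  subjects
}

#' Balance class labels by random down-sampling
#'
#' Draws, without replacement, an equal number of subjects from each
#' retained class — the size of the smallest retained class — so that the
#' classifier sees no label imbalance. For the frailty target only
#' `healthy` and `pre_frail` are retained by default: the `frail` class is
#' far too small in typical community cohorts to support training.
#' Balancing happens before any train/test split; downstream splits operate
#' on the balanced table.
#'
#' @param subjects A data frame with one row per subject.
#' @param label Column name holding the class label (`"frailty_class"` or
#'   `"gender"`).
#' @param seed Integer seed making the draw reproducible.
#' @param keep_classes Classes to retain; `NULL` keeps all classes present
#'   (the default for labels other than `frailty_class`).
#' @return A tibble with equal per-class counts, in drawn order.
#' @examples
#' df <- tibble::tibble(subject_id = 1:10,
#'                      gender = rep(c("female", "male"), c(7, 3)))
#' table(balance_labels(df, "gender", seed = 1)$gender)
#' @export
balance_labels <- function(subjects, label = "frailty_class", seed = 1L,
                           keep_classes = NULL) {
  subjects <- tibble::as_tibble(subjects)
  if (!label %in% names(subjects)) {
    abort(paste0("No such label column: ", label),
          class = "frailmotion_validation_error")
  }
  if (is.null(keep_classes) && label == "frailty_class") {
    keep_classes <- c("healthy", "pre_frail")
  }
  lab <- as.character(subjects[[label]])
  if (!is.null(keep_classes)) {
    empty <- setdiff(keep_classes, unique(lab))
    if (length(empty) > 0) {
      abort(paste0("Retained class(es) with no subjects: ",
                   paste(empty, collapse = ", ")),
            class = "frailmotion_balancing_error")
    }
    subjects <- subjects[lab %in% keep_classes, ]
    lab <- lab[lab %in% keep_classes]
  }
  classes <- sort(unique(lab))
  if (length(classes) < 2) {
    abort("Need at least 2 distinct classes to balance",
          class = "frailmotion_balancing_error")
  }
  n_min <- min(table(lab))
  withr::with_seed(seed, {
    picked <- unlist(lapply(classes, function(cl) {
      idx <- which(lab == cl)
      sample(idx, n_min)
    }))
  })
  subjects[picked, ]
}
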