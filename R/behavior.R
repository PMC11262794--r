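#' Choice counts from a two-sided preference plate
#'
#' After 5 min on the test plate, larvae are counted on each side and in
#' the middle. Counts must sum to the group size; middle larvae enter the
#' denominator of preference scores but neither side count.
#'
#' @param side_a,side_b,middle non-negative counts.
#' @param side_a_label,side_b_label what each side holds (e.g. `"AM"` /
#'   `"OCT"`, `"odor"` / `"no odor"`, `"agarose"` / `"quinine"`).
#' @return Object of class `choice_counts`.
#' @export
choice_counts <- function(side_a, side_b, middle = 0,
                          side_a_label = "side_a", side_b_label = "side_b") {
  for (nm in c("side_a", "side_b", "middle")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v)) {
      stop(sprintf("`%s` must be a single non-negative count", nm),
           call. = FALSE)
    }
  }
  structure(list(side_a = as.integer(side_a), side_b = as.integer(side_b),
                 middle = as.integer(middle),
                 group_size = as.integer(side_a + side_b + middle),
                 side_a_label = side_a_label, side_b_label = side_b_label),
            class = "choice_counts")
}

#' @export
print.choice_counts <- function(x, ...) {
  cat(sprintf("<choice_counts> %s: %d | middle: %d | %s: %d (n = %d)\n",
              x$side_a_label, x$side_a, x$middle, x$side_b_label, x$side_b,
              x$group_size))
  invisible(x)
}

#' Mouth-hook feeding rate
#'
#' Feeding rate is the number of mouth-hook contractions counted over a
#' 5-min observation. Raw counts are recorded; when an observation is
#' shorter or longer than 300 s, `rescale = TRUE` linearly rescales the
#' count to a 300-s window.
#'
#' @param mouthhook_count contractions counted.
#' @param observation_s observation length, seconds (default 300).
#' @param rescale rescale to per-5-min; default `FALSE` (raw counts, the
#'   standard protocol observes exactly 5 min).
#' @return Contractions per 5 min (numeric).
#' @export
feeding_rate <- function(mouthhook_count, observation_s = 300,
                         rescale = FALSE) {
  check_positive(mouthhook_count, "mouthhook_count", allow_zero = TRUE)
  check_positive(observation_s, "observation_s")
  if (rescale) mouthhook_count * 300 / observation_s else mouthhook_count
}

#' Dye-based food intake
#'
#' Food intake is the optical density at 629 nm of the homogenate of a
#' group of larvae fed blue-dyed food; the OD value itself is the
#' measurement. A blank correction is available but off by default (raw OD
#' is what is reported).
#'
#' @param od629 measured optical density (>= 0).
#' @param blank_od optional blank OD to subtract.
#' @param clamp_negative if a blank correction goes negative, clamp to 0
#'   (with a warning) instead of erroring.
#' @return Optical density (dimensionless).
#' @export
food_intake <- function(od629, blank_od = NULL, clamp_negative = TRUE) {
  check_positive(od629, "od629", allow_zero = TRUE)
  if (is.null(blank_od)) return(od629)
  check_positive(blank_od, "blank_od", allow_zero = TRUE)
  out <- od629 - blank_od
  if (out < 0) {
    if (!clamp_negative) stop("blank-corrected OD is negative", call. = FALSE)
    warning("blank-corrected OD was negative; clamped to 0", call. = FALSE)
    out <- 0
  }
  out
}

#' Naive preference score
#'
#' (count on side A - count on side B) / total, with side A the odorant
#' side (or the agarose side of a quinine plate). Middle larvae count only
#' in the denominator. Values lie in [-1, 1].
#'
#' @param counts a [choice_counts()] with `side_a` = odorant (or agarose).
#' @return Preference in [-1, 1].
#' @examples
#' naive_preference(choice_counts(20, 5, 5))  # 0.5
#' @export
naive_preference <- function(counts) {
  stopifnot(inherits(counts, "choice_counts"))
  if (counts$group_size == 0L) {
    stop("group size must be positive", call. = FALSE)
  }
  (counts$side_a - counts$side_b) / counts$group_size
}

#' Reciprocal preference scores and the associative performance index
#'
#' Two groups receive reciprocal training (AM paired with the reinforcer,
#' or OCT paired with the reinforcer) and are tested on an AM-vs-OCT
#' plate. For the AM-trained group PREF = (#AM - #OCT) / total; for the
#' OCT-trained group PREF = (#OCT - #AM) / total. The performance index is
#' the mean of the two reciprocal PREFs. Both counts objects must have
#' `side_a` = the group's conditioned (CS+) odorant side.
#'
#' @param am_plus_group [choice_counts()] for the AM-trained group
#'   (`side_a` = AM side).
#' @param oct_plus_group [choice_counts()] for the OCT-trained group
#'   (`side_a` = OCT side).
#' @return Object of class `performance_index`: list with `pref_am_plus`,
#'   `pref_oct_plus`, `pi`, all in [-1, 1].
#' @examples
#' pref_scores(choice_counts(20, 5, 5, "AM", "OCT"),
#'             choice_counts(20, 5, 5, "OCT", "AM"))  # PI = 0.5
#' @export
pref_scores <- function(am_plus_group, oct_plus_group) {
  stopifnot(inherits(am_plus_group, "choice_counts"),
            inherits(oct_plus_group, "choice_counts"))
  if (am_plus_group$group_size == 0L || oct_plus_group$group_size == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  p1 <- (am_plus_group$side_a - am_plus_group$side_b) /
    am_plus_group$group_size
  p2 <- (oct_plus_group$side_a - oct_plus_group$side_b) /
    oct_plus_group$group_size
  structure(list(pref_am_plus = p1, pref_oct_plus = p2,
                 pi = (p1 + p2) / 2), class = "performance_index")
}

#' @export
print.performance_index <- function(x, ...) {
  cat(sprintf("<performance_index> PREF(AM+) = %.3f, PREF(OCT+) = %.3f, ",
              x$pref_am_plus, x$pref_oct_plus))
  cat(sprintf("PI = %.3f\n", x$pi))
  invisible(x)
}

#' Group mean, SEM and n
#'
#' Data are presented as mean +/- SEM; SEM is the sample standard
#' deviation over the square root of n, and is `NA` for a single value.
#'
#' @param values numeric vector (NAs dropped).
#' @return data.frame with columns `mean`, `sem`, `n`.
#' @examples
#' group_summary(c(1, 2, 3))  # mean 2, sem 0.577
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("`values` must contain at least one number",
                    call. = FALSE)
  data.frame(mean = mean(values),
             sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
             n = n)
}

#' Two-sided permutation comparison of two groups
#'
#' A convenience randomization test on the difference of group means:
#' labels are permuted `n_perm` times and the two-sided p-value is the
#' add-one-smoothed proportion of permutations whose absolute mean
#' difference is at least the observed one,
#' `p = (1 + #\{|d_perm| >= |d_obs|\}) / (n_perm + 1)`.
#' This is a convenience for screening simulated experiments; exported
#' group tables are intended for standard inferential workflows.
#'
#' @param group_a,group_b numeric vectors.
#' @param n_perm number of label permutations (>= 100).
#' @param seed optional integer seed.
#' @return Two-sided p-value in (0, 1].
#' @export
permutation_compare <- function(group_a, group_b, n_perm = 999L,
                                seed = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  na <- length(group_a)
  pooled <- c(group_a, group_b)
  n <- length(pooled)
  obs <- abs(mean(group_a) - mean(group_b))
  total <- sum(pooled)
  exceed <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      ia <- sample.int(n, na)
      sa <- sum(pooled[ia])
      d <- abs(sa / na - (total - sa) / (n - na))
      # >= with a relative tolerance so exact ties (identical groups)
      # are counted despite floating-point noise
      if (d >= obs - 1e-12 * max(1, obs)) hits <- hits + 1L
    }
    hits
  })
  (1 + exceed) / (n_perm + 1)
}
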