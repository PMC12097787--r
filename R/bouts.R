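TREATMENT_LEVELS <- c("low", "intermediate", "high")
KCAL_PER_SLICE <- 1.1
KJ_PER_KCAL <- 4.186

bout_columns <- c("bout_id", "trial_id", "individual_id", "sex",
                  "ordinal_rank", "age_class", "treatment", "brushing_s",
                  "washing_s", "travel_s", "slices_consumed",
                  "bout_duration_s", "trial_participants")

#' Read a food-handling bout table from CSV
#'
#' One row per bout: identifiers, sex, ordinal dominance rank, sand
#' treatment, brushing/washing/travel durations, slices consumed, bout
#' duration, and the number of monkeys participating in the trial.
#' Treatment labels are a closed vocabulary (`low`, `intermediate`,
#' `high`); unknown labels fail fast.
#'
#' @param path CSV path (UTF-8, comma-delimited, header required).
#' @return a data frame of bouts.
#' @export
read_bouts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_bouts(df)
}

validate_bouts <- function(df) {
  missing_cols <- setdiff(bout_columns, names(df))
  if (length(missing_cols) > 0L)
    stop("bout table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(bad) > 0L)
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(TREATMENT_LEVELS, collapse = "/"),
         call. = FALSE)
  over <- df$brushing_s + df$washing_s > df$bout_duration_s + 1e-9
  if (any(over, na.rm = TRUE))
    stop("cleaning durations exceed bout duration in bout(s): ",
         paste(utils::head(df$bout_id[which(over)], 5), collapse = ", "),
         call. = FALSE)
  df
}

#' Restrict to low-competition trials
#'
#' Trials with more participants than feeding stations produce scramble
#' competition and almost no cleaning, erasing the individual variation of
#' interest; bouts from trials with more than `max_participants` monkeys
#' are therefore dropped. The number of excluded bouts is reported as a
#' message and attached as `attr(, "n_excluded")`.
#'
#' @param bouts a bout data frame (see [read_bouts()]).
#' @param max_participants largest trial size retained (default 3).
#' @return the retained bouts.
#' @export
filter_trials <- function(bouts, max_participants = 3) {
  miss <- is.na(bouts$trial_participants)
  if (any(miss))
    stop("missing trial participant counts for trial(s): ",
         paste(unique(bouts$trial_id[miss]), collapse = ", "),
         call. = FALSE)
  keep <- bouts$trial_participants <= max_participants
  message(sum(!keep), " bout(s) excluded (trials with > ",
          max_participants, " participants); ", sum(keep), " retained")
  out <- bouts[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Per-treatment cleaning-duration summaries
#'
#' For each sand treatment and behavior, the median and SD of cleaning
#' durations (median paired with SD, the field's reporting convention for
#' these right-skewed, zero-heavy data; zero-duration bouts are real
#' observations and are included).
#'
#' @param bouts a bout data frame.
#' @return a data frame with columns `treatment`, `behavior`, `n_bouts`,
#'   `median_s`, `sd_s`.
#' @export
treatment_summaries <- function(bouts) {
  if (nrow(bouts) == 0L) stop("no bouts to summarize", call. = FALSE)
  validate_bouts(bouts)
  long <- rbind(
    data.frame(treatment = bouts$treatment, behavior = "brushing",
               duration_s = bouts$brushing_s),
    data.frame(treatment = bouts$treatment, behavior = "washing",
               duration_s = bouts$washing_s))
  out <- do.call(rbind, lapply(split(
    long, list(long$treatment, long$behavior), drop = TRUE),
    function(d) data.frame(
      treatment = d$treatment[1], behavior = d$behavior[1],
      n_bouts = nrow(d),
      median_s = stats::median(d$duration_s),
      sd_s = if (nrow(d) > 1L) stats::sd(d$duration_s) else 0)))
  out$treatment <- factor(out$treatment, levels = TREATMENT_LEVELS)
  out <- out[order(out$behavior, out$treatment), ]
  rownames(out) <- NULL
  out
}

#' Energy intake from a food-handling bout
#'
#' Each cucumber slice carries 1.1 kcal = 4.6046 kJ; the intake rate is
#' total energy over the bout duration.
#'
#' @param slices_consumed slices eaten during the bout (vectorized).
#' @param bout_duration_s bout duration in seconds (`> 0`).
#' @return a data frame with `kj_total` and `kj_per_s`.
#' @examples
#' energy_intake_rate(3, 10)  # 13.81 kJ at 1.38 kJ/s
#' @export
energy_intake_rate <- function(slices_consumed, bout_duration_s) {
  if (is.data.frame(slices_consumed)) {
    bout_duration_s <- slices_consumed$bout_duration_s
    slices_consumed <- slices_consumed$slices_consumed
  }
  check_nonnegative(slices_consumed, "slices_consumed")
  check_positive(bout_duration_s, "bout_duration_s")
  kj <- slices_consumed * KCAL_PER_SLICE * KJ_PER_KCAL
  data.frame(kj_total = kj, kj_per_s = kj / bout_duration_s)
}

#' Standardized ordinal dominance ranks
#'
#' Combines all individuals (both sexes) into a single ordinal ranking
#' 1..n, 1 = most dominant, from raw within-group rank scores. The
#' species' hierarchy is strictly linear, so tied raw ranks indicate a
#' data problem and raise an error. Output is sorted by rank, making the
#' result invariant to input order.
#'
#' @param individuals a data frame with columns `id`, `sex`, `raw_rank`
#'   (smaller = more dominant).
#' @return a data frame with columns `id`, `sex`, `ordinal_rank`.
#' @export
standardize_ranks <- function(individuals) {
  stopifnot(all(c("id", "raw_rank") %in% names(individuals)))
  r <- individuals$raw_rank
  if (anyDuplicated(r))
    stop("tied raw ranks for: ",
         paste(individuals$id[r %in% r[duplicated(r)]], collapse = ", "),
         "; the hierarchy is strictly linear", call. = FALSE)
  ord <- order(r)
  out <- data.frame(id = individuals$id[ord],
                    sex = if ("sex" %in% names(individuals))
                      individuals$sex[ord] else NA_character_,
                    ordinal_rank = seq_along(ord))
  rownames(out) <- NULL
  out
}

#' Model-ready bout table
#'
#' Emits the exact table a zero-inflated mixed-model fit would consume:
#' one row per (filtered) bout with integer-second cleaning durations,
#' treatment, sex, ordinal rank and individual identity. Durations are
#' recorded from video at 0.1 s resolution but modeled as whole-number
#' counts, so fractional durations are floor-rounded here; the number of
#' rounded values is reported as a message.
#'
#' @param bouts a (filtered) bout data frame.
#' @return a data frame with columns `individual_id`, `sex`,
#'   `ordinal_rank`, `treatment`, `brushing_s`, `washing_s`.
#' @export
model_ready_table <- function(bouts) {
  validate_bouts(bouts)
  n_frac <- sum(bouts$brushing_s %% 1 != 0) + sum(bouts$washing_s %% 1 != 0)
  if (n_frac > 0L)
    message(n_frac, " fractional duration(s) floor-rounded to whole seconds")
  out <- data.frame(individual_id = bouts$individual_id,
                    sex = bouts$sex,
                    ordinal_rank = as.integer(bouts$ordinal_rank),
                    treatment = bouts$treatment,
                    brushing_s = as.integer(floor(bouts$brushing_s)),
                    washing_s = as.integer(floor(bouts$washing_s)))
  rownames(out) <- NULL
  out
}

#' Observed cleaning durations for overcleaning diagnostics
#'
#' Pulls the observed durations of one behavior under one treatment
#' (default: the high-sand treatment, where cleaning is reliably
#' elicited), for use with [overcleaning_factor()].
#'
#' @param bouts a bout data frame.
#' @param behavior `"brushing"` or `"washing"`.
#' @param treatment treatment level to condition on.
#' @return numeric vector of durations in seconds.
#' @export
observed_durations <- function(bouts, behavior = c("brushing", "washing"),
                               treatment = "high") {
  behavior <- match.arg(behavior)
  validate_bouts(bouts)
  col <- paste0(behavior, "_s")
  bouts[bouts$treatment == treatment, col]
}
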