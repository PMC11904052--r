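# Corpus-level z-scoring, the distancing composite, reliability, and
# participant-level aggregation with delta scores for both study designs.

z_categories <- c("pct_fps", "pct_present", "pct_discrepancy",
                  "pct_article", "pct_long")
reverse_coded <- c("pct_fps", "pct_present", "pct_discrepancy")

#' Z-score the five distancing categories across trials
#'
#' Standardizes each category to mean 0 and unit sample SD over a z-scoring
#' population of trials. By default the population is all trials within each
#' study sample (`group = "sample_id"`); set `group = NULL` to pool across
#' samples. A category with zero variance in its population maps to all-zero
#' z-scores rather than non-finite values.
#'
#' @param scored A trial-level tibble containing the five `pct_*` columns
#'   (e.g. the output of [score_texts()] bound to its trial table).
#' @param group Optional name of a grouping column defining the z-scoring
#'   population; `NULL` pools everything.
#' @return The input with `z_fps`, `z_present`, `z_discrepancy`,
#'   `z_article`, `z_long` columns appended (raw z-scores, not yet
#'   reverse-coded).
#' @export
zscore_categories <- function(scored, group = "sample_id") {
  stopifnot(all(z_categories %in% names(scored)))
  if (!is.null(group) && !group %in% names(scored)) {
    stop("grouping column '", group, "' not found")
  }
  grp <- if (is.null(group)) rep(1L, nrow(scored)) else scored[[group]]
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (sum(!is.na(scored$pct_fps[idx])) < 2L) {
      stop("z-scoring population '", g, "' has fewer than 2 scored trials")
    }
  }
  for (cat in z_categories) {
    x <- scored[[cat]]
    z <- rep(NA_real_, length(x))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      m <- mean(x[idx], na.rm = TRUE)
      s <- stats::sd(x[idx], na.rm = TRUE)
      z[idx] <- if (is.na(s) || s == 0) 0 else (x[idx] - m) / s
      z[idx][is.na(x[idx])] <- NA_real_
    }
    scored[[sub("pct_", "z_", cat)]] <- z
  }
  scored
}

#' Linguistic distancing composite from z-scored categories
#'
#' Reverse-codes the first-person-singular, present-tense and discrepancy
#' z-scores (multiplying by -1) and averages all five classes. Higher values
#' indicate greater linguistic separation from the here and now.
#'
#' @param z A tibble with columns `z_fps`, `z_present`, `z_discrepancy`,
#'   `z_article`, `z_long` (as produced by [zscore_categories()]), or a
#'   numeric vector of the five raw z-scores in that order.
#' @return A numeric vector of per-trial composites (`NA` where any
#'   component is missing).
#' @export
#' @examples
#' distancing_composite(c(1, 1, 1, -1, -1))  # -1: close language
distancing_composite <- function(z) {
  if (is.numeric(z) && is.null(dim(z))) {
    stopifnot(length(z) == 5L)
    z <- tibble::tibble(z_fps = z[1], z_present = z[2], z_discrepancy = z[3],
                        z_article = z[4], z_long = z[5])
  }
  cols <- c("z_fps", "z_present", "z_discrepancy", "z_article", "z_long")
  stopifnot(all(cols %in% names(z)))
  m <- cbind(-z$z_fps, -z$z_present, -z$z_discrepancy, z$z_article, z$z_long)
  out <- rowMeans(m)
  out[!stats::complete.cases(m)] <- NA_real_
  out
}

#' Cronbach's alpha for a multi-item composite
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i var_i / var_{total})} over the item
#' columns, computed on complete rows. For the distancing composite the
#' items are the five reverse-coded z-scores at trial level.
#'
#' @param items A numeric matrix or data frame, rows = observations,
#'   columns = items.
#' @return A list with `alpha`, `k` (items) and `n` (rows used).
#' @export
#' @examples
#' x <- matrix(rnorm(300), ncol = 3)
#' cronbach_alpha(cbind(x, x[, 1] + rnorm(100, sd = .5)))
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  n <- nrow(items)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items")
  if (n < 3L) stop("Cronbach's alpha needs at least 3 complete rows")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total variance across items")
  alpha <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  list(alpha = alpha, k = k, n = n)
}

#' Reverse-coded z-score item matrix for reliability analysis
#'
#' @param z A tibble with the `z_*` columns from [zscore_categories()].
#' @return A numeric matrix with the fps/present/discrepancy items negated.
#' @export
distancing_items <- function(z) {
  cbind(fps = -z$z_fps, present = -z$z_present,
        discrepancy = -z$z_discrepancy, article = z$z_article,
        long = z$z_long)
}

#' Aggregate scored trials to participant condition means and delta scores
#'
#' Computes per-participant condition means of the distancing composite,
#' abstractness and affect, then the design's difference scores. For the
#' within-subject reappraisal design (`design = "study1"`, conditions
#' `look_negative`, `reappraise_negative`, `look_neutral`):
#' `delta_distancing` and `delta_abstractness` are reappraise minus
#' look-negative, `reappraisal_success` is look-negative minus reappraise
#' affect, `emotional_reactivity` is look-negative minus look-neutral
#' affect, and `delta_abstractness_reactivity` is the matching
#' look-negative minus look-neutral abstractness difference. For the
#' distance-by-domain design (`design = "study2"`, conditions `close`,
#' `far`, between-subject `domain`): language deltas are far minus close
#' and `delta_affect` is close minus far.
#'
#' Abstractness means use qualifying trials only; distancing means use all
#' trials with at least one word. A participant missing a required
#' condition gets `NA` deltas with a warning.
#'
#' @param trials A trial-level tibble with `participant_id`, `sample_id`,
#'   `condition` (and `domain` for study 2), `affect`, the `z_*` columns
#'   and `abstractness`/`qualifying` columns.
#' @param design `"study1"` or `"study2"`.
#' @return A participant-level tibble of condition means and delta scores.
#' @export
aggregate_participants <- function(trials, design = c("study1", "study2")) {
  design <- match.arg(design)
  needed <- c("participant_id", "sample_id", "condition", "affect",
              "abstractness", "qualifying")
  stopifnot(all(needed %in% names(trials)))
  trials$distancing <- distancing_composite(trials)

  means <- trials |>
    dplyr::group_by(.data$participant_id, .data$sample_id, .data$condition) |>
    dplyr::summarise(
      distancing = mean(.data$distancing[.data$word_count >= 1], na.rm = TRUE),
      abstractness = if (any(.data$qualifying))
        mean(.data$abstractness[.data$qualifying]) else NA_real_,
      affect = mean(.data$affect, na.rm = TRUE),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  if (design == "study2") {
    dom <- trials |>
      dplyr::distinct(.data$participant_id, .data$domain)
    if (anyDuplicated(dom$participant_id)) {
      stop("a participant appears in more than one domain")
    }
    means <- dplyr::left_join(means, dom, by = "participant_id")
  }

  wide <- tidyr::pivot_wider(
    means,
    names_from = "condition",
    values_from = c("distancing", "abstractness", "affect", "n_trials")
  )
  col_or_na <- function(nm) {
    if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  }
  if (design == "study1") {
    out <- dplyr::mutate(
      wide,
      delta_distancing = col_or_na("distancing_reappraise_negative") -
        col_or_na("distancing_look_negative"),
      delta_abstractness = col_or_na("abstractness_reappraise_negative") -
        col_or_na("abstractness_look_negative"),
      reappraisal_success = col_or_na("affect_look_negative") -
        col_or_na("affect_reappraise_negative"),
      emotional_reactivity = col_or_na("affect_look_negative") -
        col_or_na("affect_look_neutral"),
      delta_abstractness_reactivity = col_or_na("abstractness_look_negative") -
        col_or_na("abstractness_look_neutral")
    )
  } else {
    out <- dplyr::mutate(
      wide,
      delta_distancing = col_or_na("distancing_far") - col_or_na("distancing_close"),
      delta_abstractness = col_or_na("abstractness_far") - col_or_na("abstractness_close"),
      delta_affect = col_or_na("affect_close") - col_or_na("affect_far")
    )
  }
  n_missing <- sum(!stats::complete.cases(
    out[grep("^delta_|^reappraisal", names(out))]))
  if (n_missing > 0) {
    warning(n_missing, " participant(s) missing a required condition; ",
            "their delta scores are NA")
  }
  out
}
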