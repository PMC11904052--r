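# Study pipelines: read a trial table, score every text, z-score and
# aggregate, then run the design's full analysis set and render a report.

study1_conditions <- c("look_negative", "reappraise_negative", "look_neutral")
study2_conditions <- c("close", "far")

#' Read a trial table from delimited text
#'
#' Validates required columns and the 1-7 affect range. Rows with invalid
#' affect are rejected with a warning naming their line numbers; a missing
#' column is fatal.
#'
#' @param path Path to a comma-separated file with a header row
#'   (`participant_id`, `sample_id`, `condition`, `text`, `affect`, plus
#'   `domain` for the distance-by-domain design).
#' @param design `"study1"` or `"study2"`.
#' @return A tibble of valid trial records.
#' @export
read_trials <- function(path, design = c("study1", "study2")) {
  design <- match.arg(design)
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("participant_id", "sample_id", "condition", "text", "affect")
  if (design == "study2") required <- c(required, "domain")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  affect <- suppressWarnings(as.numeric(d$affect))
  bad <- is.na(affect) | affect < 1 | affect > 7 | affect != round(affect)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected for affect outside 1-7: lines ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
    d <- d[!bad, , drop = FALSE]
  }
  d$affect <- as.integer(d$affect)
  expected <- if (design == "study1") study1_conditions else study2_conditions
  unknown <- setdiff(unique(d$condition), expected)
  if (length(unknown)) {
    stop("condition label(s) outside the ", design, " design: ",
         paste(unknown, collapse = ", "))
  }
  tibble::as_tibble(d)
}

participant_condition_means <- function(scored) {
  scored$distancing <- distancing_composite(scored)
  scored |>
    dplyr::group_by(.data$participant_id, .data$sample_id, .data$condition) |>
    dplyr::summarise(
      distancing = mean(.data$distancing[.data$word_count >= 1], na.rm = TRUE),
      abstractness = if (any(.data$qualifying))
        mean(.data$abstractness[.data$qualifying]) else NA_real_,
      affect = mean(.data$affect), .groups = "drop")
}

#' Run the full analysis pipeline for one study design
#'
#' Scores every trial text, z-scores the five distancing categories within
#' each sample, aggregates to participant condition means and delta scores,
#' and runs the design's analysis set. For the reappraisal design:
#' abstractness-distancing association regressions (overall and per
#' condition), the delta-delta regression, the repeated-measures ANCOVA
#' across the three conditions with pairwise follow-ups, the reappraisal
#' success and emotional reactivity regressions, and the two-predictor
#' model. For the distance-by-domain design: association regressions
#' (overall, per condition cell, delta-delta overall and per domain), the
#' 2 x 3 mixed ANCOVA with per-domain follow-ups, and the delta
#' abstractness - delta affect regression. All regressions control for the
#' sample indicator.
#'
#' @param trials A trial tibble (see [read_trials()]) or a `lingdist_sim`
#'   object.
#' @param design `"study1"` or `"study2"`.
#' @param lexicons Lexicon set.
#' @param z_group Column defining the z-scoring population
#'   (default `"sample_id"`; `NULL` pools samples).
#' @param min_classified Qualifying threshold for abstractness scores.
#' @return A `lingdist_report` list: `trial_scores`, `participant_scores`,
#'   `regressions`, `anovas`, `reliability`, `within_ci`, `design`, `log`.
#' @export
#' @examples
#' sim <- simulate_study1(study1_config(n_participants = 12,
#'                                      trials_per_condition = 3), seed = 2)
#' rep <- run_pipeline(sim, design = "study1")
#' rep$anovas
run_pipeline <- function(trials, design = c("study1", "study2"),
                         lexicons = default_lexicons(), z_group = "sample_id",
                         min_classified = 1L) {
  design <- match.arg(design)
  if (inherits(trials, "lingdist_sim")) trials <- trials$trials
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  scored <- dplyr::bind_cols(trials,
                             score_texts(trials$text, lexicons,
                                         min_classified = min_classified))
  n_empty <- sum(scored$word_count == 0)
  if (n_empty) note(n_empty, " trial(s) with empty text excluded from scoring")
  note("scored ", nrow(scored), " trials from ",
       dplyr::n_distinct(scored$participant_id), " participants")
  if (nrow(scored) == 0 || all(scored$word_count == 0)) {
    stop("no scorable trials after filtering (", nrow(scored), " rows, ",
         n_empty, " empty)")
  }
  scored <- zscore_categories(scored, group = z_group)
  pc <- participant_condition_means(scored)
  agg <- suppressWarnings(aggregate_participants(scored, design = design))

  # ANOVAs and within-subject intervals need complete condition sets
  conds <- if (design == "study1") study1_conditions else study2_conditions
  ok <- pc |>
    dplyr::filter(!is.na(.data$abstractness)) |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == length(conds))
  pc_ok <- pc[pc$participant_id %in% ok$participant_id &
                !is.na(pc$abstractness), ]
  n_drop <- dplyr::n_distinct(pc$participant_id) -
    dplyr::n_distinct(pc_ok$participant_id)
  if (n_drop > 0) {
    note(n_drop, " participant(s) without complete condition sets excluded ",
         "from ANOVAs and within-subject intervals")
  }

  rel <- cronbach_alpha(distancing_items(scored))
  note("Cronbach's alpha of the five-item composite: ",
       round(rel$alpha, 3), " (trial level, n = ", rel$n, ")")

  regressions <- list()
  anovas <- list()
  reg <- function(name, data, y, x, cov = "sample_id") {
    res <- standardized_regression(data, y, x, covariates = cov)
    res$analysis <- name
    regressions[[name]] <<- res
  }

  if (design == "study1") {
    overall <- pc |>
      dplyr::group_by(.data$participant_id, .data$sample_id) |>
      dplyr::summarise(abstractness = mean(.data$abstractness),
                       distancing = mean(.data$distancing), .groups = "drop")
    reg("association_overall", overall, "abstractness", "distancing")
    for (cond in study1_conditions) {
      reg(paste0("association_", cond), pc[pc$condition == cond, ],
          "abstractness", "distancing")
    }
    reg("delta_delta", agg, "delta_abstractness", "delta_distancing")
    reg("success_abstractness", agg, "reappraisal_success",
        "delta_abstractness")
    reg("reactivity_control", agg, "emotional_reactivity",
        "delta_abstractness_reactivity")
    reg("success_distancing", agg, "reappraisal_success", "delta_distancing")
    two <- standardized_regression(agg, "reappraisal_success",
                                   c("delta_distancing", "delta_abstractness"),
                                   covariates = "sample_id")
    two$analysis <- "success_both"
    regressions[["success_both"]] <- two

    anovas[["condition"]] <- rm_ancova(pc_ok, "participant_id", "condition",
                                       "abstractness", covariate = "sample_id")
    pairs <- utils::combn(study1_conditions, 2, simplify = FALSE)
    for (pr in pairs) {
      nm <- paste(pr, collapse = "_vs_")
      sub <- pc_ok[pc_ok$condition %in% pr, ]
      anovas[[nm]] <- rm_ancova(sub, "participant_id", "condition",
                                "abstractness", covariate = "sample_id")
      anovas[[nm]]$effect <- nm
    }
    within_ci <- morey_within_ci(pc_ok, "participant_id", "condition",
                                 "abstractness")
  } else {
    overall <- pc |>
      dplyr::group_by(.data$participant_id, .data$sample_id) |>
      dplyr::summarise(abstractness = mean(.data$abstractness),
                       distancing = mean(.data$distancing), .groups = "drop")
    reg("association_overall", overall, "abstractness", "distancing")
    pc2 <- dplyr::left_join(pc,
                            dplyr::distinct(trials, .data$participant_id,
                                            .data$domain),
                            by = "participant_id")
    for (dom in unique(pc2$domain)) {
      for (cond in study2_conditions) {
        cell <- pc2[pc2$domain == dom & pc2$condition == cond, ]
        reg(paste0("association_", dom, "_", cond), cell,
            "abstractness", "distancing")
      }
    }
    reg("delta_delta", agg, "delta_abstractness", "delta_distancing")
    for (dom in unique(agg$domain)) {
      reg(paste0("delta_delta_", dom), agg[agg$domain == dom, ],
          "delta_abstractness", "delta_distancing")
    }
    reg("affect_abstractness", agg, "delta_affect", "delta_abstractness")

    pc2_ok <- pc2[pc2$participant_id %in% ok$participant_id &
                    !is.na(pc2$abstractness), ]
    anovas[["mixed_2x3"]] <- mixed_ancova(pc2_ok, "participant_id", "condition",
                                          "domain", "abstractness",
                                          covariate = "sample_id")
    for (dom in unique(pc2_ok$domain)) {
      sub <- pc2_ok[pc2_ok$domain == dom, ]
      nm <- paste0("distance_", dom)
      anovas[[nm]] <- rm_ancova(sub, "participant_id", "condition",
                                "abstractness", covariate = "sample_id")
      anovas[[nm]]$effect <- nm
    }
    within_ci <- pc2_ok |>
      dplyr::group_by(.data$domain) |>
      dplyr::group_modify(~ morey_within_ci(.x, "participant_id", "condition",
                                            "abstractness")) |>
      dplyr::ungroup()
  }

  structure(list(
    design = design,
    trial_scores = scored,
    participant_scores = agg,
    regressions = dplyr::bind_rows(regressions),
    anovas = dplyr::bind_rows(anovas),
    reliability = rel,
    within_ci = within_ci,
    log = log
  ), class = "lingdist_report")
}

fmt_p <- function(p) {
  ifelse(p < .001, "p < .001", paste0("p = ", sub("^0", "", sprintf("%.3f", p))))
}

#' @export
print.lingdist_report <- function(x, ...) {
  cat("Linguistic distancing/abstractness report (", x$design, ")\n", sep = "")
  cat(sprintf("Cronbach's alpha = %.2f (k = %d, n = %d)\n",
              x$reliability$alpha, x$reliability$k, x$reliability$n))
  cat("\nRegressions (standardized beta, 95% CI):\n")
  r <- x$regressions
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-28s beta = %.2f, 95%% CI [%.2f, %.2f], %s\n",
                paste0(r$analysis[i], ":", r$term[i]),
                round_half_up(r$beta[i]), round_half_up(r$ci_low[i]),
                round_half_up(r$ci_high[i]), fmt_p(r$p[i])))
  }
  cat("\nANCOVAs (type III, partial eta squared, 90% CI):\n")
  a <- x$anovas
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-36s F(%d, %d) = %.2f, %s, eta_p^2 = %.2f, 90%% CI [%.2f, %.2f]\n",
                a$effect[i], a$df1[i], a$df2[i], round_half_up(a$f[i]),
                fmt_p(a$p[i]), round_half_up(a$eta_p_sq[i]),
                round_half_up(a$eta_ci_low[i]), round_half_up(a$eta_ci_high[i])))
  }
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes the trial-level score table, the participant score table, the
#' machine-readable analysis tables and a plain-text rendering. Numbers in
#' the delimited tables are stored at full precision; only the text
#' rendering rounds to 2 decimals.
#'
#' @param report A `lingdist_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lingdist_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trial_scores.csv", "participant_scores.csv",
                            "regressions.csv", "anovas.csv", "report.txt",
                            "run_log.txt"))
  utils::write.csv(report$trial_scores, paths[1], row.names = FALSE)
  utils::write.csv(report$participant_scores, paths[2], row.names = FALSE)
  utils::write.csv(report$regressions, paths[3], row.names = FALSE)
  utils::write.csv(report$anovas, paths[4], row.names = FALSE)
  utils::capture.output(print(report), file = paths[5])
  writeLines(report$log, paths[6])
  invisible(paths)
}

#' Condition means with Morey-adjusted within-subject error bars
#'
#' @param report A `lingdist_report`.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(report) {
  ci <- report$within_ci
  p <- ggplot2::ggplot(ci, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::labs(y = "linguistic abstractness",
                  x = NULL,
                  caption = "error bars: 95% CI, within-person adjusted") +
    ggplot2::theme_minimal()
  if ("domain" %in% names(ci)) {
    p <- p + ggplot2::facet_wrap(~domain)
  }
  p
}
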