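#' Build an incident case/control assignment for one phecode
#'
#' Implements the incident-disease logic with related-disease exclusion
#' ranges: a sample is a *case* when its first event mapping to the target
#' phecode falls strictly after its baseline date and no such event falls
#' on or before baseline; any target event on or before baseline makes the
#' sample *prevalent* and it is excluded entirely; among non-cases, any
#' event whose phecode lies in the target's exclusion range (at any time)
#' also excludes the sample from the controls; everyone else is a control.
#' Events at exactly the baseline date count as prevalent.
#'
#' @param events Tibble `sample_id, code, event_date` (Date).
#' @param map Phecode map tibble `code, phecode, excl_low, excl_high`.
#' @param baselines Tibble `sample_id, baseline_date` covering every sample
#'   to classify.
#' @param phecode Target phecode (numeric).
#' @return Tibble `sample_id, status` (factor case/control/excluded) and
#'   `onset_date` (first post-baseline target event, cases only).
#' @export
build_case_control <- function(events, map, baselines, phecode) {
  target_rows <- dplyr::filter(map, .data$phecode == !!phecode)
  if (!nrow(target_rows)) {
    abort(sprintf("phecode %s is absent from the map.", format(phecode)))
  }
  lo <- target_rows$excl_low[1]
  hi <- target_rows$excl_high[1]
  if (anyNA(baselines$baseline_date)) abort("every sample needs a baseline date.")

  ev <- dplyr::inner_join(events, map[c("code", "phecode")], by = "code",
                          relationship = "many-to-many") %>%
    dplyr::inner_join(baselines, by = "sample_id")
  if (nrow(ev) < nrow(dplyr::semi_join(events, map, by = "code"))) {
    warn("some events belong to samples without a baseline date; they are ignored.")
  }
  per <- ev %>%
    group_by(.data$sample_id) %>%
    summarise(
      prevalent = any(.data$phecode == !!phecode &
                        .data$event_date <= .data$baseline_date),
      incident_date = suppressWarnings(min(
        .data$event_date[.data$phecode == !!phecode &
                           .data$event_date > .data$baseline_date]
      )),
      related = any(.data$phecode >= lo & .data$phecode <= hi),
      .groups = "drop"
    ) %>%
    mutate(incident = is.finite(.data$incident_date))

  out <- baselines["sample_id"] %>%
    left_join(per, by = "sample_id") %>%
    mutate(
      prevalent = dplyr::coalesce(.data$prevalent, FALSE),
      incident = dplyr::coalesce(.data$incident, FALSE),
      related = dplyr::coalesce(.data$related, FALSE),
      status = factor(dplyr::case_when(
        .data$prevalent ~ "excluded",
        .data$incident ~ "case",
        .data$related ~ "excluded",
        TRUE ~ "control"
      ), levels = c("case", "control", "excluded")),
      onset_date = dplyr::if_else(.data$status == "case",
                                  .data$incident_date, as.Date(NA))
    ) %>%
    select("sample_id", "status", "onset_date")
  out
}

phewas_fit_one <- function(df, xvals, covariates) {
  df$.x <- xvals
  fml <- stats::reformulate(c(".x", covariates), response = ".case")
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  est <- sm[".x", "Estimate"]
  se <- sm[".x", "Std. Error"]
  if (!fit$converged || !is.finite(se) || se > 10 || abs(est) > 15) {
    return(NULL)  # separation / non-convergence
  }
  z <- qnorm(0.975)
  tibble(
    odds_ratio = exp(est),
    ci_low = exp(est - z * se), ci_high = exp(est + z * se),
    p_value = sm[".x", "Pr(>|z|)"]
  )
}

#' Tertile-exposure phenome-wide association study
#'
#' Fits one logistic regression per qualifying phecode of incident case
#' status on discretized (tertile) mtDNA abundance plus covariates. The
#' primary contrast treats the tertile ordinally (0/1/2), so the reported
#' odds ratio is per tertile step; the secondary contrasts compare the
#' lowest or highest tertile against the middle one (the U-shape check).
#' Phecodes with `min_cases` cases or fewer, and phecodes whose fit shows
#' separation or fails to converge, are skipped with a reason (attribute
#' `"skipped"`). Q-values are Benjamini-Hochberg across tested phecodes
#' within each contrast.
#'
#' @param data Tibble with `sample_id`, the tertile column and covariates.
#' @param assignments Tibble `sample_id, phecode, status` stacking
#'   [build_case_control()] output for each phecode.
#' @param tertile Name of the tertile column (factor `T1`/`T2`/`T3`).
#' @param covariates Character vector of adjustment columns.
#' @param min_cases Phecodes are kept only when the number of modeled cases
#'   is strictly greater than this (default 250).
#' @param contrasts Subset of `"ordinal"`, `"T1_vs_T2"`, `"T3_vs_T2"`.
#' @return Tibble of class `"phewas_result"` with columns
#'   `phecode, contrast, n_cases, n_controls, odds_ratio, ci_low, ci_high,
#'   p_value, q_value`.
#' @export
run_phewas <- function(data, assignments, tertile = "tertile",
                       covariates = NULL, min_cases = 250,
                       contrasts = c("ordinal", "T1_vs_T2", "T3_vs_T2")) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  skipped <- list()
  res <- purrr::map(sort(unique(assignments$phecode)), function(pc) {
    asg <- dplyr::filter(assignments, .data$phecode == pc,
                         .data$status %in% c("case", "control"))
    df <- dplyr::inner_join(asg, data, by = "sample_id")
    cols <- c(tertile, covariates)
    df <- df[complete.cases(df[cols]), ]
    df$.case <- as.integer(df$status == "case")
    n_cases <- sum(df$.case)
    n_controls <- sum(df$.case == 0)
    if (n_cases <= min_cases) {
      skipped[[length(skipped) + 1]] <<-
        tibble(phecode = pc, reason = sprintf("cases (%d) not > %d", n_cases, min_cases))
      return(NULL)
    }
    tl <- df[[tertile]]
    purrr::map(contrasts, function(ct) {
      if (ct == "ordinal") {
        sub <- df
        x <- as.integer(tl) - 1L
      } else {
        lowlab <- if (ct == "T1_vs_T2") "T1" else "T3"
        keep <- tl %in% c(lowlab, "T2")
        sub <- df[keep, ]
        x <- as.integer(tl[keep] == lowlab)
      }
      row <- phewas_fit_one(sub, x, covariates)
      if (is.null(row)) {
        skipped[[length(skipped) + 1]] <<-
          tibble(phecode = pc, reason = sprintf("separation/non-convergence (%s)", ct))
        return(NULL)
      }
      dplyr::bind_cols(
        tibble(phecode = pc, contrast = ct,
               n_cases = sum(sub$.case), n_controls = sum(sub$.case == 0)),
        row
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (nrow(res)) {
    res <- res %>%
      group_by(.data$contrast) %>%
      mutate(q_value = bh_fdr(.data$p_value)) %>%
      ungroup()
  }
  attr(res, "skipped") <- bind_rows(skipped)
  class(res) <- c("phewas_result", class(res))
  res
}
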