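#' Covariate blocks for the determinant models
#'
#' The determinants are modelled in two independent blocks, fitted
#' separately: patient demographics and treatment exposure
#' (`male`, `age_ge_60`, `prior_steroid`, `current_steroid`) and
#' comorbidities (`hypertension`, `heart_disease`, `respiratory_illness`,
#' `diabetes`, `cds_high`).
#'
#' @return named list of two character vectors.
#' @export
determinant_blocks <- function() {
  list(
    demographics = c("male", "age_ge_60", "prior_steroid", "current_steroid"),
    comorbidities = c("hypertension", "heart_disease", "respiratory_illness",
                      "diabetes", "cds_high")
  )
}

#' Fit a logistic regression and report odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on binary covariates,
#' with Wald 95% confidence intervals: `OR = exp(beta)`,
#' `CI = exp(beta +/- 1.96 * SE)`. Separation and rank deficiency are
#' surfaced as errors naming the offending covariate rather than returned as
#' unstable estimates.
#'
#' @param data data.frame containing the outcome and covariates.
#' @param outcome name of the binary (logical/0-1) outcome column.
#' @param covariates character vector of covariate column names.
#' @return data.frame with one row per covariate: `term`, `estimate`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
fit_logistic <- function(data, outcome, covariates) {
  stopifnot(length(covariates) >= 1)
  fm <- stats::as.formula(paste(outcome, "~",
                                paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fm, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: covariate(s) ",
         paste(covariate_of(names(cf)[is.na(cf)], covariates), collapse = ", "),
         " aliased", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1]
  est <- sm[-1, "Estimate"]; se <- sm[-1, "Std. Error"]
  sep <- abs(est) > 15 | se > 100
  if (any(sep)) {
    stop("separation detected for covariate(s): ",
         paste(covariate_of(terms[sep], covariates), collapse = ", "),
         call. = FALSE)
  }
  data.frame(term = covariate_of(terms, covariates), estimate = unname(est),
             se = unname(se), odds_ratio = unname(exp(est)),
             ci_low = unname(exp(est - 1.96 * se)),
             ci_high = unname(exp(est + 1.96 * se)),
             p_value = unname(sm[-1, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

# glm labels logical terms "maleTRUE"; map back to covariate names.
covariate_of <- function(terms, covariates) {
  hit <- vapply(terms, function(t) {
    m <- covariates[startsWith(t, covariates)]
    if (length(m)) m[which.max(nchar(m))] else t
  }, character(1))
  unname(hit)
}

#' Stepwise backward elimination for a covariate block
#'
#' Starts from the full block model and iteratively removes the covariate
#' with the largest Wald p-value while that p-value exceeds `alpha`,
#' refitting after each removal. Ties are broken deterministically in favour
#' of the earlier-listed covariate. Removed covariates are reported as not
#' significant (`retained = FALSE`, odds ratio columns `NA`), matching the
#' "NS" convention of printed determinant tables. An empty final model (all
#' covariates removed) is allowed.
#'
#' @inheritParams fit_logistic
#' @param alpha removal threshold on the Wald p-value (default 0.05).
#' @return data.frame with one row per block covariate (input order):
#'   `term`, `retained`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
stepwise_backward <- function(data, outcome, covariates, alpha = 0.05) {
  current <- covariates
  res <- NULL
  while (length(current) > 0) {
    res <- fit_logistic(data, outcome, current)
    res <- res[match(current, res$term), , drop = FALSE]
    worst <- which(res$p_value == max(res$p_value))[1]
    if (res$p_value[worst] <= alpha) break
    current <- current[-worst]
    res <- NULL
  }
  out <- data.frame(term = covariates, retained = covariates %in% current,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(res)) {
    j <- match(res$term, out$term)
    out$odds_ratio[j] <- res$odds_ratio
    out$ci_low[j] <- res$ci_low
    out$ci_high[j] <- res$ci_high
    out$p_value[j] <- res$p_value
  }
  out
}

#' Fit the determinant models
#'
#' Merges covariates with the adherence and persistence outcomes and fits
#' stepwise backward logistic models per covariate block for each outcome
#' (`adherent_80` and `persistent_at_365`), or a single combined block when
#' `combined = TRUE`.
#'
#' @param covariates covariate data.frame from [build_covariates()].
#' @param adherence adherence results from [compute_adherence()].
#' @param episodes episode data.frame from [build_episodes()].
#' @param blocks named list of covariate blocks (default
#'   [determinant_blocks()]).
#' @param alpha removal threshold.
#' @param combined fit all covariates jointly instead of per block.
#' @return named list over outcomes, each a named list over blocks of
#'   [stepwise_backward()] results; the merged analysis data is attached as
#'   attribute `data`.
#' @export
fit_determinants <- function(covariates, adherence, episodes,
                             blocks = determinant_blocks(), alpha = 0.05,
                             combined = FALSE) {
  d <- merge(covariates,
             adherence[, c("patient_id", "adherent_80")], by = "patient_id")
  d <- merge(d, episodes[, c("patient_id", "persistent_at_365")],
             by = "patient_id")
  if (combined) blocks <- list(combined = unlist(blocks, use.names = FALSE))
  out <- lapply(c(adherent_80 = "adherent_80",
                  persistent_at_365 = "persistent_at_365"), function(y) {
    lapply(blocks, function(b) stepwise_backward(d, y, b, alpha))
  })
  attr(out, "data") <- d
  out
}

#' Determinants table in printed-report layout
#'
#' One row per covariate level with outcome counts, one-decimal percentages,
#' and the adjusted odds ratio with its 95% CI for retained covariates
#' (`"NS"` otherwise), for both outcomes side by side.
#'
#' @param fits output of [fit_determinants()].
#' @return data.frame with columns `term`, `n_yes`, `n_no`, and per outcome
#'   the counts/percentages among the yes/no levels and the `OR [CI]` text.
#' @export
determinants_table <- function(fits) {
  d <- attr(fits, "data")
  all_terms <- unique(unlist(lapply(fits[[1]], function(b) b$term)))
  fmt_or <- function(block_res, term) {
    r <- block_res[block_res$term == term, ]
    if (nrow(r) == 0 || !r$retained) return("NS")
    sprintf("%.1f [%.2f-%.2f]", round_half_up(r$odds_ratio),
            r$ci_low, r$ci_high)
  }
  or_for <- function(outcome, term) {
    for (b in fits[[outcome]]) if (term %in% b$term) return(fmt_or(b, term))
    "NS"
  }
  rows <- lapply(all_terms, function(term) {
    yes <- d[[term]]
    cnt <- function(outcome, level) sum(d[[outcome]][yes == level])
    pct <- function(outcome, level) {
      round_half_up(100 * cnt(outcome, level) / sum(yes == level))
    }
    data.frame(term = term, n_yes = sum(yes), n_no = sum(!yes),
               adherent_yes = sprintf("%d (%.1f)", cnt("adherent_80", TRUE),
                                      pct("adherent_80", TRUE)),
               adherent_no = sprintf("%d (%.1f)", cnt("adherent_80", FALSE),
                                     pct("adherent_80", FALSE)),
               adherence_or = or_for("adherent_80", term),
               persistent_yes = sprintf("%d (%.1f)",
                                        cnt("persistent_at_365", TRUE),
                                        pct("persistent_at_365", TRUE)),
               persistent_no = sprintf("%d (%.1f)",
                                       cnt("persistent_at_365", FALSE),
                                       pct("persistent_at_365", FALSE)),
               persistence_or = or_for("persistent_at_365", term),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
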