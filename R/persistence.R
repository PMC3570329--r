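#' Build a treatment episode for one cohort member
#'
#' Scans the member's 5-ASA fills from the index date forward and classifies
#' the episode:
#' \describe{
#'   \item{GAP_DISCONTINUATION}{a supply runout followed by `grace_days`
#'     (default 60, twice the usual 30-day refill time) with no gap-closing
#'     5-ASA fill. The event time is the day after the pre-gap runout (days
#'     on treatment), not the last fill date.}
#'   \item{SWITCH}{a fill of a different 5-ASA product inside the window
#'     before any qualifying gap; non-persistent at that fill's day.}
#'   \item{CENSORED}{neither event by day 365; `event_time_days = 365`.}
#' }
#' Early refills accumulate supply (carry-forward), so they never create
#' artificial gaps. Gaps are evaluated using fills observed through day
#' 365 + `grace_days` - 1; a runout near the window end whose grace interval
#' extends past `data_end` (end of observable data, by default the window
#' end, or the eligibility end when supplied) is censored, not discontinued.
#'
#' @param member one-row cohort member data.frame.
#' @param dispensing dispensing claims for (at least) that patient.
#' @param grace_days permissible gap after runout before declaring
#'   discontinuation (default 60).
#' @param data_end last date with observable claims for this patient
#'   (default: the member's `window_end`).
#' @param require_abandonment if `TRUE`, a different-product fill only counts
#'   as a switch when no index-product fill follows it.
#' @param gap_any_asa if `TRUE` (default) any 5-ASA fill interrupts a gap
#'   (a different product doing so is a switch); if `FALSE` only
#'   index-product fills close gaps.
#' @return one-row data.frame: `patient_id`, `index_product`, `event_type`,
#'   `event_time_days` (1..365), `persistent_at_365`.
#' @export
build_episode <- function(member, dispensing, grace_days = 60,
                          data_end = NULL, require_abandonment = FALSE,
                          gap_any_asa = TRUE) {
  stopifnot(nrow(member) == 1)
  if (is.null(data_end)) data_end <- member$window_end
  f <- dispensing[dispensing$patient_id == member$patient_id &
                    dispensing$drug_class == "FIVE_ASA", , drop = FALSE]
  rel <- as.numeric(f$dispense_date - member$index_date)
  classify_episode(day = rel, product = f$product,
                   days_supply = f$days_supply,
                   index_product = member$index_product,
                   data_end = as.numeric(data_end - member$index_date),
                   grace_days = grace_days,
                   require_abandonment = require_abandonment,
                   gap_any_asa = gap_any_asa,
                   patient_id = member$patient_id)
}

# Core episode classifier on index-relative days. Walks fills in date order
# maintaining the accumulated index-product runout day `r`; the first
# completed grace gap or switch fill ends the episode.
classify_episode <- function(day, product, days_supply, index_product,
                             data_end, grace_days, require_abandonment,
                             gap_any_asa, patient_id) {
  horizon <- 364 + grace_days - 1
  keep <- day >= 0 & day <= horizon
  day <- day[keep]; product <- product[keep]; days_supply <- days_supply[keep]
  o <- order(day, product != index_product)  # same-day: index fill first
  day <- day[o]; product <- product[o]; days_supply <- days_supply[o]
  if (length(day) == 0 || day[1] != 0 || product[1] != index_product) {
    stop("internal consistency error: no index fill at the index date for ",
         patient_id)
  }
  has_later_index <- rev(cumsum(rev(product == index_product)) -
                           (product == index_product)) > 0

  r <- -1  # accumulated runout day of index-product supply
  event <- NULL
  for (k in seq_along(day)) {
    d <- day[k]
    is_index <- product[k] == index_product
    closes_gap <- is_index || (gap_any_asa && d <= 364)
    if (closes_gap && d > r + grace_days) {
      event <- list(type = "GAP_DISCONTINUATION", time = r + 1)
      break
    }
    if (is_index) {
      r <- max(r, d - 1) + days_supply[k]
    } else if (d <= 364) {
      if (!require_abandonment || !has_later_index[k]) {
        event <- list(type = "SWITCH", time = max(1, d))
        break
      }
    }
  }
  if (is.null(event)) {
    if (r < 364 && r + grace_days <= data_end) {
      event <- list(type = "GAP_DISCONTINUATION", time = r + 1)
    } else {
      event <- list(type = "CENSORED", time = 365)
    }
  }
  if (event$time > 365) event <- list(type = "CENSORED", time = 365)
  data.frame(patient_id = patient_id, index_product = index_product,
             event_type = event$type,
             event_time_days = as.integer(event$time),
             persistent_at_365 = event$type == "CENSORED",
             stringsAsFactors = FALSE)
}

#' Build treatment episodes for a cohort
#'
#' Applies [build_episode()] to every member. When `eligibility` is given,
#' each member's `data_end` is the end of their merged eligibility (capped at
#' index + 364 + `grace_days`), enabling gap evaluation past the window end.
#'
#' @param members cohort members.
#' @param dispensing dispensing claims.
#' @param eligibility optional eligibility periods.
#' @inheritParams build_episode
#' @return data.frame of episodes, one row per member.
#' @export
build_episodes <- function(members, dispensing, eligibility = NULL,
                           grace_days = 60, require_abandonment = FALSE,
                           gap_any_asa = TRUE) {
  f_all <- dispensing[dispensing$drug_class == "FIVE_ASA" &
                        dispensing$patient_id %in% members$patient_id, ,
                      drop = FALSE]
  f_by <- split(f_all, f_all$patient_id)
  elig_end <- rep(NA, nrow(members))
  if (!is.null(eligibility)) {
    e_by <- split(eligibility, eligibility$patient_id)
    elig_end <- vapply(members$patient_id, function(pid) {
      ep <- e_by[[pid]]
      if (is.null(ep)) NA_real_ else as.numeric(max(ep$end_date))
    }, numeric(1))
  }
  rows <- lapply(seq_len(nrow(members)), function(i) {
    m <- members[i, , drop = FALSE]
    de <- if (is.na(elig_end[i])) m$window_end else {
      min(as.Date(elig_end[i], origin = "1970-01-01"),
          m$index_date + 364 + grace_days)
    }
    f <- f_by[[m$patient_id]]
    rel <- as.numeric(f$dispense_date - m$index_date)
    classify_episode(rel, f$product, f$days_supply, m$index_product,
                     as.numeric(de - m$index_date), grace_days,
                     require_abandonment, gap_any_asa, m$patient_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier time to discontinuation
#'
#' Product-limit estimate of staying on the index treatment, over episode
#' event times. Censored-at-365 episodes contribute risk but no event.
#'
#' @param episodes episode data.frame (from [build_episodes()]).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`
#'   (product-limit estimate, non-increasing from 1).
#' @export
km_estimate <- function(episodes) {
  stopifnot(nrow(episodes) >= 1)
  fit <- survival::survfit(
    survival::Surv(episodes$event_time_days,
                   episodes$event_type != "CENSORED") ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' @rdname km_estimate
#' @param curve a curve from [km_estimate()].
#' @param day day at which to evaluate the step function.
#' @return `km_survival_at()`: the survival estimate at `day`.
#' @export
km_survival_at <- function(curve, day) {
  i <- which(curve$time <= day)
  if (length(i) == 0) return(1)
  curve$survival[max(i)]
}

#' Log-rank comparison of discontinuation curves
#'
#' Standard log-rank chi-square across two or more groups, with an optional
#' seeded permutation p-value (group labels permuted) as a small-sample
#' check on the asymptotic chi-square p.
#'
#' @param episodes episode data.frame.
#' @param group vector of group labels, one per episode.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm number of label permutations (permutation method).
#' @param seed RNG seed for the permutation method.
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_compare <- function(episodes, group, method = c("asymptotic",
                                                        "permutation"),
                            n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  group <- factor(group)
  check_partition(as.character(group), nrow(episodes))
  if (nlevels(group) < 2 || any(table(group) == 0)) {
    stop("log-rank comparison needs >= 2 non-empty groups")
  }
  time <- episodes$event_time_days
  status <- as.integer(episodes$event_type != "CENSORED")
  stat_fun <- function(g) {
    sd <- survival::survdiff(survival::Surv(time, status) ~ g)
    unname(sd$chisq)
  }
  stat <- stat_fun(group)
  df <- nlevels(group) - 1
  if (method == "asymptotic") {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    set.seed(seed)
    exceed <- vapply(seq_len(n_perm), function(i) {
      stat_fun(sample(group)) >= stat - 1e-12
    }, logical(1))
    p <- (1 + sum(exceed)) / (n_perm + 1)
  }
  list(statistic = stat, df = df, p_value = p, method = method)
}

#' Summarize persistence by group
#'
#' Counts and one-decimal percentages of members persistent at 365 days.
#'
#' @param episodes episode data.frame.
#' @param by grouping as in [adherence_summary()].
#' @return data.frame with `group`, `n`, `n_persistent_365`, `pct`.
#' @export
persistence_summary <- function(episodes, by = NULL) {
  g <- resolve_grouping(episodes, by)
  n <- as.vector(table(g))
  np <- as.vector(tapply(episodes$persistent_at_365, g, sum))
  out <- data.frame(group = levels(g), n = n, n_persistent_365 = np,
                    pct = round_half_up(100 * np / n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
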