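#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (2.45 -> 2.5 at one
#' decimal), matching the convention of printed claims-study tables rather
#' than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(14.449, 8.575, 27.66), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Parse ISO 8601 dates strictly; returns Date with NA for unparseable input.
parse_iso_date <- function(x) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  # as.Date accepts e.g. "2005-1-1"; require canonical form for file inputs
  d[!is.na(d) & format(d, "%Y-%m-%d") != as.character(x)] <- NA
  d
}

# Stop unless all required columns are present, naming the missing ones.
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Merge possibly-overlapping eligibility periods per patient into maximal
# disjoint intervals. Periods touching end-to-start on consecutive days
# (end + 1 == next start) are treated as continuous coverage.
merge_periods <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (as.numeric(start[i]) <= as.numeric(me) + 1) {
        if (end[i] > me) me <- end[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start_date = as.Date(out_s, origin = "1970-01-01"),
             end_date = as.Date(out_e, origin = "1970-01-01"))
}

# TRUE iff the patient's merged eligibility fully covers [from, to].
covers_interval <- function(elig_patient, from, to) {
  if (nrow(elig_patient) == 0) return(FALSE)
  m <- merge_periods(elig_patient$start_date, elig_patient$end_date)
  any(m$start_date <= from & m$end_date >= to)
}

# Validate that `by` is a complete partition label vector for n units.
check_partition <- function(by, n) {
  if (length(by) != n || anyNA(by)) {
    stop("grouping must assign every member to exactly one group (no NAs)",
         call. = FALSE)
  }
  invisible(by)
}
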