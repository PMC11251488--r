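# cUHDRS composite, time-adjusted change, slow/fast decliner split.

#' Compute the cUHDRS composite score
#'
#' The composite Unified Huntington's Disease Rating Scale combines the four
#' standard clinical components into a single progression score,
#' \deqn{cUHDRS = \frac{TFC-10.4}{1.9} - \frac{TMS-29.7}{14.9} +
#'   \frac{SDMT-28.4}{11.3} + \frac{SWR-66.1}{20.1} + 10,}
#' where TFC is Total Functional Capacity (0--13), TMS the Total Motor Score
#' (0--124, worse = higher, hence the negative sign), SDMT the Symbol Digit
#' Modalities Test and SWR the Stroop Word Reading score. Lower cUHDRS means
#' more advanced disease.
#'
#' Components outside their usual clinical ranges raise a warning but are
#' scored anyway (the formula is defined off-range). Any missing component
#' yields `NA` for that visit; nothing is imputed.
#'
#' @param tfc,tms,sdmt,swr Numeric vectors (recycled to a common length) with
#'   the four component scores.
#' @param warn_range Warn when a component lies outside its usual clinical
#'   range (default `TRUE`).
#' @return Numeric vector of cUHDRS scores; `NA` where any component is
#'   missing.
#' @examples
#' compute_cuhdrs(12.88, 2.56, 54.47, 100.78)  # ~17.16
#' compute_cuhdrs(10.4, 29.7, 28.4, 66.1)      # exactly 10
#' @export
compute_cuhdrs <- function(tfc, tms, sdmt, swr, warn_range = TRUE) {
  n <- max(length(tfc), length(tms), length(sdmt), length(swr))
  tfc <- rep_len(as.numeric(tfc), n)
  tms <- rep_len(as.numeric(tms), n)
  sdmt <- rep_len(as.numeric(sdmt), n)
  swr <- rep_len(as.numeric(swr), n)
  if (warn_range) {
    bad <- (tfc < 0 | tfc > 13) | (tms < 0 | tms > 124) | sdmt < 0 | swr < 0
    if (any(bad, na.rm = TRUE))
      warning(sum(bad, na.rm = TRUE),
              " visit(s) have components outside usual clinical ranges; ",
              "scored anyway")
  }
  (tfc - 10.4) / 1.9 - (tms - 29.7) / 14.9 +
    (sdmt - 28.4) / 11.3 + (swr - 66.1) / 20.1 + 10
}

#' Add a cUHDRS column to a visits table
#'
#' @param visits Data frame with columns `tfc`, `tms`, `sdmt`, `swr`.
#' @inheritParams compute_cuhdrs
#' @return `visits` with a `cuhdrs` column appended (or overwritten).
#' @export
score_visits <- function(visits, warn_range = TRUE) {
  need <- c("tfc", "tms", "sdmt", "swr")
  miss <- setdiff(need, names(visits))
  if (length(miss))
    stop("visits table lacks component column(s): ", paste(miss, collapse = ", "))
  visits$cuhdrs <- compute_cuhdrs(visits$tfc, visits$tms, visits$sdmt,
                                  visits$swr, warn_range = warn_range)
  visits
}

#' Time-adjusted cUHDRS change per subject
#'
#' For each subject, (last cUHDRS - first cUHDRS) / (last age - first age),
#' with visits ordered by age. Intermediate visits are ignored by definition:
#' the change score is the first-to-last difference adjusted for follow-up
#' time, not a regression slope. Subjects with fewer than two scorable visits
#' or zero elapsed time get `NA`.
#'
#' @param visits Data frame with columns `subjid`, `visit_age` and either
#'   `cuhdrs` or the four component columns (scored on the fly).
#' @return Data frame with one row per subject: `subjid`, `n_visits`,
#'   `followup_years`, `delta_per_year`.
#' @export
delta_cuhdrs_per_time <- function(visits) {
  if (!"cuhdrs" %in% names(visits)) visits <- score_visits(visits, warn_range = FALSE)
  ok <- !is.na(visits$cuhdrs) & !is.na(visits$visit_age)
  visits <- visits[ok, , drop = FALSE]
  split_idx <- split(seq_len(nrow(visits)), visits$subjid)
  out <- lapply(names(split_idx), function(id) {
    idx <- split_idx[[id]]
    age <- visits$visit_age[idx]
    sc <- visits$cuhdrs[idx]
    o <- order(age)
    age <- age[o]; sc <- sc[o]
    span <- age[length(age)] - age[1]
    delta <- if (length(age) < 2 || span <= 0) NA_real_ else
      (sc[length(sc)] - sc[1]) / span
    data.frame(subjid = id, n_visits = length(age),
               followup_years = if (length(age) < 2) NA_real_ else span,
               delta_per_year = delta, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify subjects as slow or fast decliners
#'
#' The cohort threshold is `T = |mean(delta_per_year)|` over the analysed
#' subjects. Under the default signed convention a subject is a slow decliner
#' iff `delta_per_year >= -T` (improvers are slow decliners); under
#' `convention = "absolute"` the label follows `|delta| <= T`, the literal
#' absolute-value reading, which classes strong improvers as fast. The
#' boundary is inclusive on the slow side in both conventions.
#'
#' @param deltas Data frame from [delta_cuhdrs_per_time()], or a numeric
#'   vector of per-subject changes.
#' @param convention `"signed"` (default) or `"absolute"`; see Details.
#' @return List with `labels` (data frame `subjid`, `delta_per_year`,
#'   `label` in `{"slow","fast"}`) and `threshold`.
#' @export
classify_decliners <- function(deltas, convention = c("signed", "absolute")) {
  convention <- match.arg(convention)
  if (is.numeric(deltas))
    deltas <- data.frame(subjid = as.character(seq_along(deltas)),
                         delta_per_year = as.numeric(deltas),
                         stringsAsFactors = FALSE)
  d <- deltas$delta_per_year
  if (all(is.na(d))) stop("all per-subject changes are missing; cannot classify")
  thr <- abs(mean(d, na.rm = TRUE))
  lab <- if (convention == "signed") {
    ifelse(d >= -thr, "slow", "fast")
  } else {
    ifelse(abs(d) <= thr, "slow", "fast")
  }
  lab[is.na(d)] <- NA_character_
  list(labels = data.frame(subjid = deltas$subjid, delta_per_year = d,
                           label = lab, stringsAsFactors = FALSE),
       threshold = thr)
}
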