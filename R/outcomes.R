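#' Quit status under the Russell standard
#'
#' Smoking-trial convention: a participant with missing outcome data is
#' counted as a smoker. Under the primary (verified) definition, a quit
#' additionally requires biochemical verification — carbon monoxide, or
#' the covid-era pathway of self-report plus a saliva sample; a reported
#' quit whose verification failed counts as a smoker. With
#' `self_report = TRUE` (sensitivity definition) the reported status is
#' taken at face value, with missing still counted as smoker.
#'
#' @param reported reported status, `"quit"`, `"smoker"` or `NA`
#' @param verified_flag logical, biochemical verification passed (`NA` =
#'   not verified)
#' @param covid_era logical, outcome collected in the covid era
#' @param saliva_provided logical, saliva sample provided (covid pathway)
#' @param self_report use the self-reported definition
#' @return tibble with columns `status` (`"quit"`/`"smoker"`) and `basis`
#'   (`"verified"`, `"self_report"`, `"imputed_smoker"`)
#' @export
russell_quit <- function(reported, verified_flag = NA, covid_era = FALSE,
                         saliva_provided = FALSE, self_report = FALSE) {
  k <- max(length(reported), length(verified_flag), length(covid_era),
           length(saliva_provided))
  reported <- rep_len(reported, k)
  verified_flag <- rep_len(verified_flag, k)
  covid_era <- rep_len(rep(covid_era, length.out = k), k)
  saliva_provided <- rep_len(rep(saliva_provided, length.out = k), k)

  status <- character(k); basis <- character(k)
  for (i in seq_len(k)) {
    if (is.na(reported[i])) {
      status[i] <- "smoker"; basis[i] <- "imputed_smoker"
    } else if (reported[i] != "quit") {
      status[i] <- "smoker"; basis[i] <- "self_report"
    } else if (self_report) {
      status[i] <- "quit"; basis[i] <- "self_report"
    } else {
      ok <- isTRUE(verified_flag[i]) ||
        (isTRUE(covid_era[i]) && isTRUE(saliva_provided[i]))
      status[i] <- if (ok) "quit" else "smoker"
      basis[i] <- if (ok) "verified" else "self_report"
    }
  }
  tibble::tibble(status = status, basis = basis)
}

#' Convert EQ-5D-5L responses to a utility
#'
#' Maps a five-digit profile (one level 1-5 per dimension) to a utility via
#' a supplied value set. Two value-set layouts are supported: a full lookup
#' table with columns `profile`, `utility`; or an additive decrement table
#' with columns `dimension`, `level`, `decrement`, where the utility is 1
#' minus the sum of the decrements of the observed levels (full health,
#' profile 11111, anchors at 1). The published crosswalk value set is
#' consumed in the same layouts; it is not shipped here.
#'
#' @param responses character vector of 5-digit profiles (e.g. `"21132"`)
#'   or a 5-column matrix of levels
#' @param valueset data frame in one of the two layouts
#' @return numeric utilities
#' @export
eq5d_to_utility <- function(responses, valueset) {
  if (is.matrix(responses)) {
    responses <- apply(responses, 1, paste0, collapse = "")
  }
  ok <- grepl("^[1-5]{5}$", responses) | is.na(responses)
  if (!all(ok)) {
    stop_field("responses", "profiles must be five digits, levels 1-5")
  }
  if (all(c("profile", "utility") %in% names(valueset))) {
    idx <- match(responses, as.character(valueset$profile))
    if (any(is.na(idx) & !is.na(responses))) {
      stop_field("valueset", "value set lacks a value for a supplied profile")
    }
    return(valueset$utility[idx])
  }
  if (!all(c("dimension", "level", "decrement") %in% names(valueset))) {
    stop_field("valueset",
               "expected columns profile/utility or dimension/level/decrement")
  }
  # Dimension order follows first appearance in the value set, matching
  # the digit positions of the profile.
  dims <- unique(valueset$dimension)
  if (length(dims) != 5) stop_field("valueset", "need exactly 5 dimensions")
  vapply(responses, function(p) {
    if (is.na(p)) return(NA_real_)
    lv <- as.integer(strsplit(p, "")[[1]])
    dec <- mapply(function(d, l) {
      row <- valueset$decrement[valueset$dimension == d & valueset$level == l]
      if (length(row) == 0 && l == 1L) 0 else if (length(row) == 0) {
        stop_field("valueset", sprintf("no decrement for %s level %d", d, l))
      } else row[1]
    }, dims, lv)
    1 - sum(dec)
  }, numeric(1), USE.NAMES = FALSE)
}

#' QALYs by area under the utility curve
#'
#' Trapezoid integral of the utility trajectory over elapsed time in
#' years, treating changes between follow-up points as linear. At least
#' two non-missing points are required; otherwise the result is `NA`
#' (undefined — the record flows to imputation rather than contributing a
#' silent zero).
#'
#' @param times numeric vector of times in years, strictly increasing
#' @param utilities numeric vector of utilities at those times (NA allowed)
#' @return QALYs in years, or `NA` if fewer than two points are observed
#' @export
qaly_auc <- function(times, utilities) {
  stopifnot(length(times) == length(utilities))
  if (any(diff(times) <= 0)) {
    stop_field("times", "times must be strictly increasing")
  }
  keep <- !is.na(utilities)
  if (sum(keep) < 2) return(NA_real_)
  t <- times[keep]; u <- utilities[keep]
  sum(diff(t) * (head(u, -1) + u[-1]) / 2)
}

#' Attach Russell-standard quit outcomes and QALYs to a participant table
#'
#' Adds `quit_late_russell`, `quit_postpartum_russell` (0/1 under the
#' Russell rule), and `qaly_late` / `qaly_postpartum` columns. The
#' late-pregnancy QALY integrates baseline to late pregnancy; the
#' post-partum QALY integrates the full follow-up to 6 months post-partum.
#'
#' @param table participant tibble
#' @param self_report use the self-reported quit definition (sensitivity)
#' @return the table with outcome columns appended
#' @export
attach_outcomes <- function(table, self_report = FALSE) {
  reported_col <- if (self_report) "quit_late_selfreport" else "quit_late"
  late <- russell_quit(table[[reported_col]],
                       verified_flag = table[[reported_col]] == "quit",
                       covid_era = table$covid_era,
                       saliva_provided = table$saliva_provided,
                       self_report = self_report)
  pp <- russell_quit(table$quit_postpartum,
                     verified_flag = table$quit_postpartum == "quit",
                     covid_era = table$covid_era,
                     saliva_provided = table$saliva_provided,
                     self_report = self_report)
  out <- table
  out$quit_late_russell <- as.integer(late$status == "quit")
  out$quit_late_basis <- late$basis
  out$quit_postpartum_russell <- as.integer(pp$status == "quit")

  n <- nrow(table)
  qlate <- numeric(n); qpp <- numeric(n)
  for (i in seq_len(n)) {
    t1 <- table$t_late_years[i]
    t2 <- t1 + table$t_postpartum_years[i]
    qlate[i] <- qaly_auc(c(0, t1),
                         c(table$utility_baseline[i], table$utility_late[i]))
    qpp[i] <- qaly_auc(c(0, t1, t2),
                       c(table$utility_baseline[i], table$utility_late[i],
                         table$utility_postpartum[i]))
  }
  out$qaly_late <- qlate
  out$qaly_postpartum <- qpp
  out
}
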