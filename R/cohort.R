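#' Specimen records
#'
#' One row per unilateral cavity: `specimen_id`, `patient_id`, `side`
#' (`"right"`/`"left"`), `excluded` flag and `reason`. `(patient_id,
#' side)` must be unique and excluded rows must carry a reason.
#'
#' @param patient_id,side vectors of equal length.
#' @param specimen_id defaults to `<patient>_<side>`.
#' @param excluded,reason exclusion flag and reason text.
#' @return data.frame of class `specimen_records`.
#' @export
specimen_records <- function(patient_id, side,
                             specimen_id = paste(patient_id, side, sep = "_"),
                             excluded = FALSE, reason = "") {
  side <- as.character(side)
  if (!all(side %in% c("right", "left")))
    .mc_stop("side must be 'right' or 'left'", class = "validation_error")
  df <- data.frame(specimen_id = as.character(specimen_id),
                   patient_id = as.character(patient_id),
                   side = side,
                   excluded = rep_len(excluded, length(patient_id)),
                   reason = rep_len(as.character(reason), length(patient_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("patient_id", "side")]))
    .mc_stop("(patient_id, side) must be unique", class = "validation_error")
  if (any(df$excluded & !nzchar(df$reason)))
    .mc_stop("excluded specimens need a reason", class = "validation_error")
  class(df) <- c("specimen_records", "data.frame")
  df
}

#' Apply exclusion rules to specimen records
#'
#' Marks the specimens matched by `rules` (a data.frame with columns
#' `patient_id`, `side`, `reason`) as excluded and returns the retained
#' records plus an audit log of every exclusion.
#'
#' @param records a [specimen_records()] table.
#' @param rules data.frame of exclusions; `NULL` or 0 rows = identity.
#' @return list with `records` (retained rows), `audit` (excluded rows
#'   with reasons), `n_input`, `n_retained`.
#' @export
exclude_specimens <- function(records, rules = NULL) {
  if (is.null(rules) || nrow(rules) == 0) {
    return(list(records = records[!records$excluded, , drop = FALSE],
                audit = records[records$excluded, , drop = FALSE],
                n_input = nrow(records),
                n_retained = sum(!records$excluded)))
  }
  key <- paste(records$patient_id, records$side)
  rkey <- paste(rules$patient_id, rules$side)
  hit <- match(key, rkey)
  records$excluded <- records$excluded | !is.na(hit)
  newly <- !is.na(hit)
  records$reason[newly] <- rules$reason[hit[newly]]
  list(records = records[!records$excluded, , drop = FALSE],
       audit = records[records$excluded, , drop = FALSE],
       n_input = nrow(records),
       n_retained = sum(!records$excluded))
}

# percentages rounded to 1 decimal, half away from zero (printed-table
# convention: 11/73 -> 15.1)
.round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Patient-level cluster pairing
#'
#' Associates the two cavities of each patient and counts the unordered
#' pair of clusters they fall into (1-2 and 2-1 are the same pair,
#' independently of laterality). Patients with fewer or more than two
#' labelled cavities are excluded from the pairing and listed in the
#' audit.
#'
#' @param labels named integer vector: cluster label per specimen_id.
#' @param records the [specimen_records()] the labels refer to.
#' @return a `pair_summary`: `pairs` (data.frame pair / n / percent),
#'   `total_patients`, `excluded_patients`.
#' @export
pair_clusters_by_patient <- function(labels, records) {
  if (is.null(names(labels)))
    .mc_stop("labels must be named by specimen_id", class = "validation_error")
  records <- records[records$specimen_id %in% names(labels), , drop = FALSE]
  by_patient <- split(records$specimen_id, records$patient_id)
  complete <- names(by_patient)[lengths(by_patient) == 2L]
  excluded <- setdiff(names(by_patient), complete)
  pair_of <- vapply(complete, function(p) {
    lab <- sort(labels[by_patient[[p]]])
    paste(lab, collapse = "-")
  }, character(1))
  counts <- table(pair_of)
  total <- length(complete)
  pairs <- data.frame(pair = names(counts), n = as.integer(counts),
                      percent = .round_half_away(100 * as.integer(counts) /
                                                   total),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(pairs = pairs, total_patients = total,
                 excluded_patients = excluded,
                 pair_by_patient = pair_of),
            class = "pair_summary")
}

#' Build a pair summary directly from printed pair counts
#'
#' Convenience constructor for recomputing published summaries from a
#' table of pair counts (e.g. `c("1-1" = 11, "1-2" = 10, ...)`).
#'
#' @param counts named integer vector of unordered pair counts.
#' @return a `pair_summary`.
#' @export
pair_summary_from_counts <- function(counts) {
  total <- sum(counts)
  pairs <- data.frame(pair = names(counts), n = as.integer(counts),
                      percent = .round_half_away(100 * as.integer(counts) /
                                                   total),
                      row.names = NULL, stringsAsFactors = FALSE)
  pair_of <- rep(names(counts), counts)
  names(pair_of) <- paste0("patient", seq_along(pair_of))
  structure(list(pairs = pairs, total_patients = total,
                 excluded_patients = character(0),
                 pair_by_patient = pair_of),
            class = "pair_summary")
}

#' Percentage of patients with at least one cavity in a cluster
#'
#' @param summary a `pair_summary`.
#' @param cluster cluster label.
#' @return percentage of total patients, rounded to 1 decimal (half away
#'   from zero).
#' @export
at_least_one_membership <- function(summary, cluster) {
  sides <- strsplit(summary$pairs$pair, "-", fixed = TRUE)
  has <- vapply(sides, function(s) as.character(cluster) %in% s, logical(1))
  .round_half_away(100 * sum(summary$pairs$n[has]) / summary$total_patients)
}

#' Cluster demographics table
#'
#' Per-cluster counts, side and sex ratios and age summaries, with a
#' Pearson chi-square p-value for side and sex and a Kruskal-Wallis
#' p-value for age. Patients with missing demographics are dropped only
#' from the affected statistic; the footnote counts them.
#'
#' @param labels named cluster labels per specimen_id.
#' @param records [specimen_records()] providing patient and side.
#' @param cohort data.frame with `patient_id`, `sex`
#'   (`"female"|"male"|"unknown"`), `age` (years, NA allowed).
#' @return list with `table` (one row per variable), `p_values`,
#'   `missing` (footnote counts).
#' @export
demographics_table <- function(labels, records, cohort) {
  if (is.null(names(labels)))
    .mc_stop("labels must be named by specimen_id", class = "validation_error")
  rec <- records[match(names(labels), records$specimen_id), , drop = FALSE]
  cl <- factor(labels)
  ks <- levels(cl)
  n_k <- as.vector(table(cl))
  pct <- .round_half_away(100 * n_k / sum(n_k))

  demo <- cohort[match(rec$patient_id, cohort$patient_id), , drop = FALSE]
  sex <- demo$sex
  age <- demo$age
  side_tab <- table(factor(rec$side, c("right", "left")), cl)
  sex_known <- !is.na(sex) & sex %in% c("female", "male")
  sex_tab <- table(factor(sex[sex_known], c("female", "male")),
                   cl[sex_known])

  p_side <- p_sex <- p_age <- NA_real_
  note <- character(0)
  if (length(ks) >= 2L) {
    p_side <- chi_square_test(t(side_tab))$p
    if (all(colSums(sex_tab) > 0))
      p_sex <- chi_square_test(t(sex_tab))$p
    age_groups <- split(age[!is.na(age)], cl[!is.na(age)])
    age_groups <- age_groups[lengths(age_groups) > 0]
    if (length(age_groups) >= 2L)
      p_age <- kruskal_wallis_test(age_groups)$p
  } else {
    note <- c(note, "single cluster: no between-cluster tests")
  }

  age_mean <- vapply(ks, function(g) mean(age[cl == g], na.rm = TRUE),
                     numeric(1))
  age_sd <- vapply(ks, function(g) stats::sd(age[cl == g], na.rm = TRUE),
                   numeric(1))
  tab <- data.frame(
    variable = c("n_cavities", "percent", "side_right", "side_left",
                 "sex_female", "sex_male", "age_mean", "age_sd"),
    rbind(n_k, pct, side_tab["right", ], side_tab["left", ],
          sex_tab["female", ], sex_tab["male", ],
          round(age_mean, 1), round(age_sd, 1)),
    row.names = NULL)
  names(tab)[-1] <- paste0("cluster_", ks)
  list(table = tab,
       p_values = c(side = p_side, sex = p_sex, age = p_age),
       missing = c(sex = sum(!sex_known), age = sum(is.na(age))),
       notes = note)
}
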