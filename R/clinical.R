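#' Tinnitus Handicap Inventory global score
#'
#' Sums the 25 item responses of the THI questionnaire. Items are answered
#' "no" (0), "sometimes" (2) or "yes" (4), so the global score is an even
#' integer between 0 and 100; larger means greater tinnitus-produced
#' handicap.
#'
#' @param items numeric vector of exactly 25 values in \{0, 2, 4\}.
#' @return integer score in 0..100.
#' @export
thiScore <- function(items) {
  if (length(items) != 25L) {
    stop("THI requires exactly 25 item responses, got ", length(items))
  }
  if (anyNA(items) || !all(items %in% c(0, 2, 4))) {
    stop("THI item responses must be 0 (no), 2 (sometimes) or 4 (yes)")
  }
  as.integer(sum(items))
}

#' THI severity level from a global score
#'
#' Bins the global score into the published severity grades: 1 "very mild"
#' (2-16), 2 "mild" (18-36), 3 "moderate" (38-56), 4 "severe" (58-76),
#' 5 "catastrophic" (78-100). A score of 0 maps to level 0 ("no handicap"),
#' needed to represent resolved tinnitus. Odd scores are unreachable from
#' the 0/2/4 item coding (the published bins skip 17, 37, 57, 77) and are
#' rejected.
#'
#' @param score even integer in 0..100 (vectorized).
#' @return integer level(s) in 0..5.
#' @export
thiLevel <- function(score) {
  if (anyNA(score) || any(score < 0 | score > 100) || any(score %% 2 != 0)) {
    stop("THI score must be an even integer in 0..100")
  }
  level <- integer(length(score))
  level[score >= 2 & score <= 16] <- 1L
  level[score >= 18 & score <= 36] <- 2L
  level[score >= 38 & score <= 56] <- 3L
  level[score >= 58 & score <= 76] <- 4L
  level[score >= 78] <- 5L
  level
}

#' Classify the pre-to-post change in tinnitus status
#'
#' Compares the THI score before and after resection. An absent session
#' score (NA) means no tinnitus reported at that session. "Resolved" is used
#' only when preoperative tinnitus disappears entirely (post absent or
#' score 0); any other score decrease is "improved".
#'
#' @param preScore preoperative THI score, or NA if no preoperative tinnitus.
#' @param postScore postoperative THI score, or NA if no postoperative
#'   tinnitus.
#' @return one of \code{"resolved"}, \code{"improved"}, \code{"unchanged"},
#'   \code{"worse"}, \code{"new_onset"}, \code{"never"} (vectorized).
#' @export
classifyChange <- function(preScore, postScore) {
  n <- max(length(preScore), length(postScore))
  preScore <- rep_len(preScore, n)
  postScore <- rep_len(postScore, n)
  out <- character(n)
  for (i in seq_len(n)) {
    pre <- preScore[i]
    post <- postScore[i]
    out[i] <- if (is.na(pre) && is.na(post)) {
      "never"
    } else if (is.na(pre)) {
      if (post == 0) "never" else "new_onset"
    } else if (is.na(post) || post == 0) {
      if (pre == 0) "never" else "resolved"
    } else if (is.na(pre) || pre == 0) {
      "new_onset"
    } else if (post < pre) {
      "improved"
    } else if (post > pre) {
      "worse"
    } else {
      "unchanged"
    }
  }
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value with margins fixed: the sum of hypergeometric
#' point probabilities not exceeding that of the observed table (up to a
#' 1 + 1e-7 relative tolerance), the convention implemented by
#' \code{stats::fisher.test} and used for the cohort contingency tables.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows =
#'   characteristic levels, columns = groups).
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(tab) < 1) stop("table total must be at least 1")
  stats::fisher.test(tab)$p.value
}

#' Cohort characteristic summary with Fisher's exact tests
#'
#' Builds a Table-1-style summary: for each characteristic, the level
#' counts within each group, within-group percentages (2 decimals) and the
#' Fisher exact p-value across the level x group contingency table
#' (3 decimals). If a characteristic level is empty in every group the
#' p-value is omitted with a warning, mirroring the blank entries of
#' published cohort tables.
#'
#' @param records data frame of cohort records.
#' @param group name of the two-level grouping column.
#' @param characteristics character vector of characteristic column names.
#' @return data frame with columns \code{characteristic}, \code{level},
#'   per-group \code{n_<group>} / \code{pct_<group>} and \code{p} (repeated
#'   within a characteristic).
#' @export
cohortSummary <- function(records, group, characteristics) {
  g <- factor(records[[group]])
  if (nlevels(g) != 2L) stop("grouping column must have exactly 2 levels")
  rows <- lapply(characteristics, function(ch) {
    f <- if (is.factor(records[[ch]])) records[[ch]] else factor(records[[ch]])
    tab <- table(f, g)
    p <- NA_real_
    if (any(rowSums(tab) == 0)) {
      warning("characteristic '", ch, "' has an empty level; p-value omitted")
    } else {
      p <- round(stats::fisher.test(tab)$p.value, 3L)
    }
    pct <- sweep(tab, 2L, colSums(tab), function(a, b) ifelse(b > 0, a / b, NA))
    out <- data.frame(
      characteristic = ch, level = rownames(tab),
      stringsAsFactors = FALSE
    )
    for (j in seq_len(2L)) {
      out[[paste0("n_", levels(g)[j])]] <- as.integer(tab[, j])
      out[[paste0("pct_", levels(g)[j])]] <- round(100 * as.numeric(pct[, j]), 2L)
    }
    out$p <- p
    out
  })
  do.call(rbind, rows)
}

#' Reference vestibular-schwannoma cohort contingency data
#'
#' Patient-level tables reconstructed from the published cohort counts of a
#' 32-patient unilateral vestibular-schwannoma series: \code{preoperative}
#' crosses each baseline characteristic with preoperative tinnitus status
#' (n = 32, 18 with tinnitus), and \code{postoperative_change} crosses the
#' same characteristics with the tinnitus-change group (n = 22; 6
#' resolved/improved vs 16 unchanged/worse). Each characteristic column
#' reproduces its published 2x2 (or k x 2) margin against the grouping
#' column; the joint distribution across characteristics is otherwise
#' arbitrary.
#'
#' @return list of two data frames, \code{preoperative} and
#'   \code{postoperative_change}.
#' @export
paperCohort <- function() {
  fill2 <- function(n_group1, n_group2, counts1, counts2, levels) {
    # counts1/counts2: per-level counts within group 1 / group 2
    c(rep(levels, times = counts1), rep(levels, times = counts2))
  }
  pre <- data.frame(
    subject_id = sprintf("VS%02d", 1:32),
    tinnitus = rep(c("with", "without"), c(18L, 14L)),
    stringsAsFactors = FALSE
  )
  pre$gender <- fill2(18, 14, c(6, 12), c(6, 8), c("Male", "Female"))
  pre$age_group <- fill2(18, 14, c(8, 10), c(8, 6), c(">=50", "<50"))
  pre$side <- fill2(18, 14, c(9, 9), c(7, 7), c("Left", "Right"))
  pre$aao_hns <- fill2(18, 14, c(4, 5, 2, 7), c(5, 3, 0, 6),
    c("Class A", "Class B", "Class C", "Class D"))
  pre$preop_hearing <- fill2(18, 14, c(9, 9), c(8, 6),
    c("Serviceable", "Unserviceable"))
  pre$tumor_size <- fill2(18, 14, c(3, 15), c(5, 9), c(">3cm", "<=3cm"))
  pre$cochlear_nerve <- fill2(18, 14, c(3, 15), c(1, 13), c("Preserved", "Cut"))
  pre$resection <- fill2(18, 14, c(15, 3), c(8, 6), c("Total", "Subtotal"))
  pre$tumor_nature <- fill2(18, 14, c(12, 6), c(7, 7), c("Solid", "Non-solid"))

  post <- data.frame(
    subject_id = sprintf("VS%02d", 1:22),
    change = rep(c("resolved_improved", "unchanged_worse"), c(6L, 16L)),
    stringsAsFactors = FALSE
  )
  post$gender <- fill2(6, 16, c(4, 2), c(4, 12), c("Male", "Female"))
  post$age_group <- fill2(6, 16, c(3, 3), c(6, 10), c(">=50", "<50"))
  post$preop_hearing <- fill2(6, 16, c(2, 4), c(11, 5),
    c("Serviceable", "Unserviceable"))
  post$tumor_size <- fill2(6, 16, c(5, 1), c(14, 2), c("<=3cm", ">3cm"))
  post$iac_occupation <- fill2(6, 16, c(6, 0), c(10, 6), c("<=1cm", ">1cm"))
  post$tumor_nature <- fill2(6, 16, c(4, 2), c(12, 4), c("Solid", "Non-solid"))
  post$cbs_extrusion <- fill2(6, 16, c(2, 4), c(11, 5), c("Present", "Absent"))
  post$cochlear_nerve <- fill2(6, 16, c(0, 6), c(4, 12), c("Preserved", "Cut"))
  post$resection <- fill2(6, 16, c(5, 1), c(13, 3), c("Total", "Subtotal"))

  list(preoperative = pre, postoperative_change = post)
}
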