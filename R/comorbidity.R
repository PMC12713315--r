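#' 2x2 association-rule statistics for a disease pair
#'
#' Patient-level presence defines the contingency table: a patient "has" a
#' code if any visit record carries it (duplicate records are ignored).
#' Lift is P(C | D) / P(C); the chi-square statistic is the 1-df Pearson
#' statistic on the 2x2 table, without continuity correction.
#'
#' @param visits data frame with `patient_id`, `icd9_code`; an `n_patients`
#'   attribute (as written by [simulate_visits()] / [read_visits()]) fixes
#'   the cohort size, else distinct patients in the table are counted
#' @param D antecedent code
#' @param C consequent code
#' @param continuity apply Yates continuity correction (default FALSE)
#' @return one-row data frame of class `rule_stats`: codes, counts,
#'   `support`, `confidence`, `lift`, `chi2`, `p_value`, `defined` (FALSE
#'   when a zero margin makes lift/chi2 undefined)
#' @export
rule_stats <- function(visits, D, C, continuity = FALSE) {
  uni <- unique(visits$icd9_code)
  if (!D %in% uni || !C %in% uni)
    stop("code not present in visit table: ", if (!D %in% uni) D else C, call. = FALSE)
  key <- paste(visits$patient_id, visits$icd9_code, sep = "\r")
  dedup <- visits[!duplicated(key), , drop = FALSE]
  n_total <- attr(visits, "n_patients")
  if (is.null(n_total)) n_total <- length(unique(dedup$patient_id))
  n_total <- as.integer(n_total)
  if (n_total <= 0) stop("empty cohort: n_total = 0", call. = FALSE)
  pat_D <- unique(dedup$patient_id[dedup$icd9_code == D])
  pat_C <- unique(dedup$patient_id[dedup$icd9_code == C])
  n_D <- length(pat_D); n_C <- length(pat_C)
  n_both <- length(intersect(pat_D, pat_C))
  support <- n_both / n_total
  defined <- n_D > 0 && n_C > 0 && n_D < n_total && n_C < n_total
  confidence <- if (n_D > 0) n_both / n_D else NA_real_
  lift <- if (defined) confidence / (n_C / n_total) else NA_real_
  if (defined) {
    a <- n_both; b <- n_D - n_both; cc <- n_C - n_both
    d <- n_total - n_D - n_C + n_both
    num <- abs(a * d - b * cc)
    if (continuity) num <- max(0, num - n_total / 2)
    chi2 <- n_total * num^2 /
      (as.numeric(n_D) * (n_total - n_D) * n_C * (n_total - n_C))
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_; p <- NA_real_
  }
  out <- data.frame(antecedent = D, consequent = C, n_total = n_total,
                    n_D = n_D, n_C = n_C, n_both = n_both, support = support,
                    confidence = confidence, lift = lift, chi2 = chi2,
                    p_value = p, defined = defined, stringsAsFactors = FALSE)
  class(out) <- c("rule_stats", "data.frame")
  out
}

#' Mine ranked comorbidity rules around an anchor disease
#'
#' One rule per code co-occurring with the anchor, kept when its support
#' (joint prevalence) reaches `min_support`, ranked by lift descending,
#' ties by support descending then code order.  A network edge list
#' (node = code with patient count, edge weight = lift) is attached for
#' export to standard graph tools.
#'
#' @inheritParams rule_stats
#' @param anchor antecedent code (must be present)
#' @param min_support minimum support (joint prevalence) for a rule
#' @param alpha significance level for the chi-square marker
#' @return list of class `rule_set`: `rules` (ranked data frame with a
#'   `significant` flag), `edges` (`source`, `target`, `weight`, `n`)
#' @export
mine_rules <- function(visits, anchor, min_support = 0, alpha = 0.05) {
  if (nrow(visits) == 0) {
    empty <- data.frame()
    return(structure(list(rules = empty, edges = empty, anchor = anchor,
                          alpha = alpha), class = "rule_set"))
  }
  uni <- unique(visits$icd9_code)
  if (!anchor %in% uni) stop("anchor code '", anchor, "' not present", call. = FALSE)
  others <- sort(setdiff(uni, anchor))
  rules <- do.call(rbind, lapply(others, function(code)
    rule_stats(visits, anchor, code)))
  rules <- rules[rules$support >= min_support, , drop = FALSE]
  if (nrow(rules)) {
    rules$significant <- !is.na(rules$p_value) & rules$p_value < alpha
    lift_key <- ifelse(is.na(rules$lift), -Inf, rules$lift)
    ord <- order(-lift_key, -rules$support, rules$consequent)
    rules <- rules[ord, , drop = FALSE]
    rownames(rules) <- NULL
  }
  edges <- if (nrow(rules))
    data.frame(source = rules$antecedent, target = rules$consequent,
               weight = rules$lift, n = rules$n_both, stringsAsFactors = FALSE)
  else data.frame()
  structure(list(rules = rules, edges = edges, anchor = anchor, alpha = alpha),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("comorbidity rules anchored at", x$anchor, "(", nrow(x$rules), "rules )\n")
  if (nrow(x$rules))
    print.data.frame(utils::head(x$rules[, c("consequent", "n_both", "support",
                                             "confidence", "lift", "chi2",
                                             "p_value", "significant")], 10),
                     row.names = FALSE)
  invisible(x)
}

#' Write mined rules and the network edge list
#'
#' @param rule_set a `rule_set` from [mine_rules()]
#' @param prefix output prefix (writes `<prefix>_rules.tsv`,
#'   `<prefix>_edges.tsv`)
#' @return the prefix, invisibly
#' @export
write_rules <- function(rule_set, prefix) {
  utils::write.table(rule_set$rules, paste0(prefix, "_rules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rule_set$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
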