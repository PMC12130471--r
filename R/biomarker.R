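# The preDN-Tem x preDP-Temra quadrant biomarker and its statistical
# evaluation: threshold derivation from healthy references, quadrant
# assignment, binomial proportion CIs (Wald and Wilson), Fisher exact
# comparisons, ROC AUC, DCB derivation and Kaplan-Meier comparison with the
# Gehan-Breslow-Wilcoxon (weighted log-rank) test.

#' Biomarker thresholds
#'
#' Pre-treatment DN-Tem (within Tem) and DP-Temra (within Temra) percentage
#' cutoffs; a donor at or above a cutoff is "hi".  Disease defaults follow
#' the published healthy-quantile derivation: NSCLC (36.0, 17.2), SCLC
#' (42.0, 11.0).
#'
#' @param disease "NSCLC" or "SCLC" (sets defaults), or NULL with explicit
#'   cutoffs.
#' @param dn_tem,dp_temra Explicit percentage cutoffs in (0, 100).
#' @param derivation Free-text provenance tag.
#' @return Object of class \code{biomarker_thresholds}.
#' @export
biomarker_thresholds <- function(disease = c("NSCLC", "SCLC"), dn_tem = NULL,
                                 dp_temra = NULL, derivation = "fixed") {
  if (is.null(dn_tem) || is.null(dp_temra)) {
    disease <- match.arg(disease)
    defaults <- list(NSCLC = c(36.0, 17.2), SCLC = c(42.0, 11.0))[[disease]]
    dn_tem <- dn_tem %||% defaults[1]
    dp_temra <- dp_temra %||% defaults[2]
  } else {
    disease <- if (identical(disease, c("NSCLC", "SCLC"))) "custom" else disease
  }
  if (dn_tem <= 0 || dn_tem >= 100 || dp_temra <= 0 || dp_temra >= 100) {
    stop("thresholds must lie in (0, 100) percent", call. = FALSE)
  }
  structure(list(dn_tem = dn_tem, dp_temra = dp_temra,
                 disease = disease, derivation = derivation),
            class = "biomarker_thresholds")
}

#' Derive a hi/lo threshold from healthy reference values
#'
#' The cutoff is the empirical q-quantile of the healthy values (linear
#' interpolation between order statistics, the standard type-7 convention);
#' a donor is "hi" iff its value is at or above the cutoff, i.e. higher than
#' most (a fraction q of) healthy individuals.
#'
#' @param healthy_values Percent-scale values from >= 5 healthy donors.
#' @param q Quantile (default 0.8).
#' @return Numeric threshold.
#' @export
derive_group_threshold <- function(healthy_values, q = 0.8) {
  healthy_values <- healthy_values[!is.na(healthy_values)]
  if (length(healthy_values) < 5) {
    stop("need at least 5 healthy values to derive a stable threshold", call. = FALSE)
  }
  unname(quantile(healthy_values, q, type = 7))
}

#' Assign donors to biomarker quadrants
#'
#' Quadrants of the (DN-Tem, DP-Temra) percentage plane: Q4 = both low,
#' Q1 = DN-Tem hi / DP-Temra lo, Q2 = both hi, Q3 = DP-Temra hi / DN-Tem lo.
#' Values exactly at a threshold count as hi.  Donors with a missing
#' frequency are excluded with a warning.
#'
#' @param dn_tem,dp_temra Percent-scale frequencies (vectors).
#' @param thr A [biomarker_thresholds()] object.
#' @param donor_id Optional donor ids carried into the output.
#' @return Data frame with donor_id (when given), dn_tem, dp_temra,
#'   quadrant.
#' @export
assign_quadrant <- function(dn_tem, dp_temra, thr, donor_id = NULL) {
  ok <- !is.na(dn_tem) & !is.na(dp_temra)
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " donor(s) with missing frequencies", call. = FALSE)
  }
  dn_hi <- dn_tem >= thr$dn_tem
  dp_hi <- dp_temra >= thr$dp_temra
  quadrant <- ifelse(dp_hi,
                     ifelse(dn_hi, "Q2", "Q3"),
                     ifelse(dn_hi, "Q1", "Q4"))
  quadrant[!ok] <- NA_character_
  out <- data.frame(dn_tem = dn_tem, dp_temra = dp_temra, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  if (!is.null(donor_id)) out <- cbind(data.frame(donor_id = donor_id,
                                                  stringsAsFactors = FALSE), out)
  out[ok, , drop = FALSE]
}

#' Binomial proportion with confidence interval
#'
#' Wald (normal approximation, unclipped: bounds may leave \[0, 100\]) or
#' Wilson score interval, reported on the percent scale.
#'
#' @param successes,n Counts.
#' @param method "wald" or "wilson".
#' @param level Confidence level.
#' @return List of class \code{proportion_ci}: successes, n, estimate,
#'   lower, upper (percent), method, level.
#' @export
response_rate_ci <- function(successes, n, method = c("wald", "wilson"), level = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lower <- p - half; upper <- p + half
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- centre - half; upper <- centre + half
  }
  structure(list(successes = successes, n = n, estimate = 100 * p,
                 lower = 100 * lower, upper = 100 * upper,
                 method = method, level = level),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.2f%% (%d%% CI %.2f-%.2f%%, %s)\n",
              x$successes, x$n, x$estimate, round(100 * x$level),
              x$lower, x$upper, x$method))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass ordering convention (the
#' sum of hypergeometric probabilities no larger than that of the observed
#' table, with fixed margins).  A table with any zero margin carries no
#' information: p is 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table))) {
    stop("table must be a 2x2 matrix of non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate 2x2 table (zero margin); p set to 1", call. = FALSE)
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' ROC AUC by the midrank (Mann-Whitney) formula
#'
#' AUC equals U / (n1 * n0) with U the Mann-Whitney statistic computed from
#' midranks, so ties contribute 1/2.  The published biomarker direction is
#' that *lower* DN-Tem predicts response; with \code{direction = "lower"}
#' scores are negated internally so AUC > 0.5 means discriminative in that
#' direction.
#'
#' @param scores Numeric predictor per donor.
#' @param labels Logical (or 0/1) event indicator (e.g. PR).
#' @param direction "lower" (low score predicts the event; default) or
#'   "higher".
#' @param ci Add a Hanley-McNeil confidence interval.
#' @param level Confidence level for the CI.
#' @return List: auc, n1, n0; with lower/upper when \code{ci}.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher"),
                    ci = FALSE, level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  if (direction == "lower") scores <- -scores
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  out <- list(auc = auc, n1 = n1, n0 = n0)
  if (ci) {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
                 (n1 * n0))
    z <- qnorm(1 - (1 - level) / 2)
    out$lower <- auc - z * se
    out$upper <- auc + z * se
  }
  out
}

#' Durable clinical benefit from the 6-month response
#'
#' DCB is defined as partial response or stable disease maintained at 6
#' months; complete response counts as benefit; a missing 6-month response
#' gives NA.
#'
#' @param response_at_6m Character vector over CR/PR/SD/PD (or NA).
#' @return Logical vector.
#' @export
derive_dcb <- function(response_at_6m) {
  ifelse(is.na(response_at_6m), NA, response_at_6m %in% c("CR", "PR", "SD"))
}

#' Kaplan-Meier comparison with the Gehan-Breslow-Wilcoxon test
#'
#' Weighted log-rank test with weights equal to the total number at risk at
#' each event time (the Gehan-Breslow generalisation of the Wilcoxon test),
#' with a chi-square reference on g - 1 degrees of freedom.  A permutation
#' p-value (group labels permuted, statistic recomputed) is available for
#' small samples.
#'
#' @param times Follow-up times.
#' @param events Event indicators (TRUE = event, FALSE = censored).
#' @param group Group labels (>= 2 groups).
#' @param permutations If > 0, also compute a permutation p from that many
#'   seeded label permutations.
#' @param seed Seed for the permutation draw.
#' @return List: statistic, df, p_value, fit (a \code{survfit} object with
#'   the KM curves), and p_permutation when requested.
#' @export
km_gehan_breslow_wilcoxon <- function(times, events, group, permutations = 0, seed = 1L) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (sum(events) < 1) stop("need at least 1 event", call. = FALSE)
  stat_fun <- function(g) gehan_statistic(times, events, g)
  statistic <- stat_fun(group)
  df <- nlevels(group) - 1
  p <- pchisq(statistic, df = df, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  out <- list(statistic = statistic, df = df, p_value = p, fit = fit)
  if (permutations > 0) {
    perm <- with_seed(seed, {
      vapply(seq_len(permutations), function(i) stat_fun(sample(group)), numeric(1))
    })
    out$p_permutation <- (1 + sum(perm >= statistic)) / (1 + permutations)
  }
  out
}

# Gehan-Breslow-Wilcoxon chi-square statistic: weighted log-rank with
# w(t) = number at risk at t.
gehan_statistic <- function(times, events, group) {
  group <- factor(group)
  g <- nlevels(group)
  etimes <- sort(unique(times[events]))
  U <- numeric(g - 1)
  V <- matrix(0, g - 1, g - 1)
  for (t in etimes) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(events & times == t)
    if (n == 0 || d == 0) next
    ni <- tabulate(group[at_risk], nbins = g)
    di <- tabulate(group[events & times == t], nbins = g)
    e <- d * ni / n
    w <- n
    U <- U + w * (di - e)[seq_len(g - 1)]
    if (n > 1) {
      # hypergeometric covariance of the per-group event counts
      cov_full <- matrix(0, g - 1, g - 1)
      for (i in seq_len(g - 1)) for (j in seq_len(g - 1)) {
        cov_full[i, j] <- if (i == j) {
          d * (ni[i] / n) * (1 - ni[i] / n) * (n - d) / (n - 1)
        } else {
          -d * (ni[i] / n) * (ni[j] / n) * (n - d) / (n - 1)
        }
      }
      V <- V + w^2 * cov_full
    }
  }
  if (all(V == 0)) return(0)
  drop(t(U) %*% solve(V, U))
}

#' Evaluate the quadrant biomarker against clinical outcomes
#'
#' Joins per-donor subset profiles with outcomes, assigns quadrants,
#' computes per-quadrant PR and DCB rates with Wald and Wilson CIs, the
#' Q4-versus-Q1 Fisher exact p-values for PR and DCB, and the ROC AUC of
#' the DN-Tem frequency for PR (lower predicts response).
#'
#' @param profiles A \code{subset_profile} data frame (or any frame with
#'   donor_id and either dn_tem_pct/dp_temra_pct or
#'   freq_Tem_DN/freq_Temra_DP columns).
#' @param outcomes Outcome table with donor_id, best_response,
#'   response_at_6m (or dcb) columns.
#' @param thr A [biomarker_thresholds()] object.
#' @param ci_method Default CI method reported in \code{rates}.
#' @return Object of class \code{biomarker_result}: \code{quadrants} (per
#'   donor), \code{rates} (per quadrant x endpoint with both CI methods),
#'   \code{fisher} (Q4 vs Q1 p-values and tables), \code{auc}, and
#'   \code{counts}.
#' @export
evaluate_biomarker <- function(profiles, outcomes, thr = biomarker_thresholds("NSCLC"),
                               ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  p <- as.data.frame(profiles)
  if (!"dn_tem_pct" %in% names(p)) {
    if (!all(c("freq_Tem_DN", "freq_Temra_DP") %in% names(p))) {
      stop("profiles must carry dn_tem_pct/dp_temra_pct or freq_Tem_DN/freq_Temra_DP",
           call. = FALSE)
    }
    p$dn_tem_pct <- 100 * p$freq_Tem_DN
    p$dp_temra_pct <- 100 * p$freq_Temra_DP
  }
  out_tab <- as.data.frame(outcomes)
  out_tab <- out_tab[, setdiff(names(out_tab), c("quadrant", "dn_tem_pct", "dp_temra_pct")),
                     drop = FALSE]
  merged <- merge(p[, c("donor_id", "dn_tem_pct", "dp_temra_pct")], out_tab,
                  by = "donor_id")
  merged <- merged[!is.na(merged$best_response), , drop = FALSE]
  if (nrow(merged) == 0) stop("no donors with outcomes join the profiles", call. = FALSE)
  qa <- assign_quadrant(merged$dn_tem_pct, merged$dp_temra_pct, thr,
                        donor_id = merged$donor_id)
  merged <- merge(merged, qa[, c("donor_id", "quadrant")], by = "donor_id")
  merged$pr <- merged$best_response %in% c("CR", "PR")
  merged$dcb_flag <- if ("dcb" %in% names(merged) && !all(is.na(merged$dcb))) {
    merged$dcb
  } else {
    derive_dcb(merged$response_at_6m)
  }

  rate_rows <- list()
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    in_q <- merged$quadrant == q
    n_q <- sum(in_q)
    for (endpoint in c("PR", "DCB")) {
      flag <- if (endpoint == "PR") merged$pr[in_q] else merged$dcb_flag[in_q]
      flag <- flag[!is.na(flag)]
      if (length(flag) == 0) {
        rate_rows[[paste(q, endpoint)]] <- data.frame(
          quadrant = q, endpoint = endpoint, successes = NA_integer_,
          n = n_q, rate = NA_real_, lower_wald = NA_real_, upper_wald = NA_real_,
          lower_wilson = NA_real_, upper_wilson = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      wald <- response_rate_ci(sum(flag), length(flag), "wald")
      wil <- response_rate_ci(sum(flag), length(flag), "wilson")
      rate_rows[[paste(q, endpoint)]] <- data.frame(
        quadrant = q, endpoint = endpoint, successes = sum(flag),
        n = length(flag), rate = wald$estimate,
        lower_wald = wald$lower, upper_wald = wald$upper,
        lower_wilson = wil$lower, upper_wilson = wil$upper,
        stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rate_rows)
  rownames(rates) <- NULL
  if (any(rates$n == 0)) {
    warning("quadrant(s) with 0 donors: rates flagged missing", call. = FALSE)
  }

  fisher <- list()
  for (endpoint in c("PR", "DCB")) {
    flag <- if (endpoint == "PR") merged$pr else merged$dcb_flag
    q4 <- merged$quadrant == "Q4" & !is.na(flag)
    q1 <- merged$quadrant == "Q1" & !is.na(flag)
    if (sum(q4) > 0 && sum(q1) > 0) {
      tab <- matrix(c(sum(flag[q4]), sum(!flag[q4]),
                      sum(flag[q1]), sum(!flag[q1])), nrow = 2,
                    dimnames = list(c("yes", "no"), c("Q4", "Q1")))
      fisher[[endpoint]] <- list(table = tab, p_value = fisher_exact_2x2(tab))
    } else {
      fisher[[endpoint]] <- list(table = NULL, p_value = NA_real_)
    }
  }

  auc <- tryCatch(roc_auc(merged$dn_tem_pct, merged$pr, direction = "lower", ci = TRUE),
                  error = function(e) NULL)

  structure(list(quadrants = merged[, c("donor_id", "dn_tem_pct", "dp_temra_pct",
                                        "quadrant", "pr", "dcb_flag")],
                 rates = rates, fisher = fisher, auc = auc,
                 thresholds = thr, ci_method = ci_method,
                 counts = table(merged$quadrant)),
            class = "biomarker_result")
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat("Quadrant biomarker evaluation (DN-Tem >=", x$thresholds$dn_tem,
      "% ; DP-Temra >=", x$thresholds$dp_temra, "%)\n")
  cat("Donors per quadrant:\n")
  print(x$counts)
  cat("\nRates (percent, with Wald and Wilson 95% CIs):\n")
  print(x$rates, digits = 4)
  cat(sprintf("\nFisher exact Q4 vs Q1: PR p = %.4g; DCB p = %.4g\n",
              x$fisher$PR$p_value, x$fisher$DCB$p_value))
  if (!is.null(x$auc)) {
    cat(sprintf("ROC AUC of DN-Tem for PR (lower predicts response): %.4f (95%% CI %.3f-%.3f)\n",
                x$auc$auc, x$auc$lower, x$auc$upper))
  }
  invisible(x)
}
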