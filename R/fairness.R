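#' Privileged / unprivileged group declarations
#'
#' Default assignments for the four audited attributes: male, White, Mac
#' and right-handed are the privileged values (Mac despite its smaller
#' sample, on hardware-homogeneity grounds); every value can be
#' overridden.
#'
#' @param sex,race,device,hand Length-2 character vectors
#'   `c(privileged, unprivileged)`.
#' @return A named list mapping attribute to its privilege declaration and
#'   prediction-table column.
#' @export
privilege_map <- function(sex = c("male", "female"),
                          race = c("White", "Non-White"),
                          device = c("Mac", "Windows"),
                          hand = c("right", "left")) {
  list(
    sex = list(column = "sex", privileged = sex[1], unprivileged = sex[2]),
    race = list(column = "race_binary", privileged = race[1],
                unprivileged = race[2]),
    device = list(column = "device", privileged = device[1],
                  unprivileged = device[2]),
    hand = list(column = "hand", privileged = hand[1], unprivileged = hand[2])
  )
}

#' Confusion counts from a prediction table
#'
#' @param preds Prediction table (`label`, `predicted` columns).
#' @param positive Positive-class value.
#' @return Named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(preds, positive = "PD") {
  lab_pos <- preds$label == positive
  pred_pos <- preds$predicted == positive
  list(TP = sum(lab_pos & pred_pos), FP = sum(!lab_pos & pred_pos),
       TN = sum(!lab_pos & !pred_pos), FN = sum(lab_pos & !pred_pos))
}

#' Performance metrics from confusion counts
#'
#' Precision, recall (sensitivity), specificity, F1 and accuracy; a metric
#' with a zero denominator is `NA` (undefined), never coerced to 0.
#'
#' @param c Confusion counts from [confusion_counts()].
#' @return Named list of the five metrics.
#' @export
performance_metrics <- function(c) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(c$TP, c$TP + c$FP)
  recall <- safe(c$TP, c$TP + c$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * recall * precision / (recall + precision)
  list(precision = precision, recall = recall,
       specificity = safe(c$TN, c$TN + c$FP), f1 = f1,
       accuracy = safe(c$TP + c$TN, c$TP + c$FP + c$TN + c$FN))
}

## splits a prediction table into the two declared groups of an attribute
split_groups <- function(preds, attribute, privilege) {
  a <- privilege[[attribute]]
  if (is.null(a)) stop("unknown attribute: ", attribute, call. = FALSE)
  col <- preds[[a$column]]
  list(u = preds[col == a$unprivileged, , drop = FALSE],
       p = preds[col == a$privileged, , drop = FALSE])
}

group_rates <- function(preds, attribute, privilege, positive = "PD") {
  g <- split_groups(preds, attribute, privilege)
  rate <- function(df) {
    c <- confusion_counts(df, positive)
    n <- nrow(df)
    list(TPR = if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_,
         FPR = if (c$FP + c$TN > 0) c$FP / (c$FP + c$TN) else NA_real_,
         pos_rate = if (n > 0) (c$TP + c$FP) / n else NA_real_,
         n = n)
  }
  list(u = rate(g$u), p = rate(g$p))
}

#' Disparate impact
#'
#' Ratio of the positive-prediction rate of the unprivileged group to that
#' of the privileged group: 1 = parity, below 1 = bias against the
#' unprivileged group.
#'
#' @param preds Prediction table.
#' @param attribute One of `names(privilege)`.
#' @param privilege A [privilege_map()].
#' @param positive Positive-class value.
#' @return DI, or `NA` if the privileged positive rate is 0 or a group is
#'   empty.
#' @export
disparate_impact <- function(preds, attribute, privilege = privilege_map(),
                             positive = "PD") {
  r <- group_rates(preds, attribute, privilege, positive)
  if (is.na(r$u$pos_rate) || is.na(r$p$pos_rate) || r$p$pos_rate == 0)
    return(NA_real_)
  r$u$pos_rate / r$p$pos_rate
}

#' Equal opportunity
#'
#' Ratio of true-positive rates, unprivileged over privileged; 1 = parity.
#'
#' @inheritParams disparate_impact
#' @return EO, or `NA` when a TPR is undefined or the privileged TPR is 0.
#' @export
equal_opportunity <- function(preds, attribute, privilege = privilege_map(),
                              positive = "PD") {
  r <- group_rates(preds, attribute, privilege, positive)
  if (is.na(r$u$TPR) || is.na(r$p$TPR) || r$p$TPR == 0) return(NA_real_)
  r$u$TPR / r$p$TPR
}

#' Equalized odds
#'
#' Worst-case gap between the groups over the TPR and FPR. The default
#' `"absolute"` convention is `max(|TPR_u - TPR_p|, |FPR_u - FPR_p|)`
#' (non-negative, 0 = parity); `"signed"` takes the literal
#' `max(TPR_u - TPR_p, FPR_u - FPR_p)` without absolute values.
#'
#' @inheritParams disparate_impact
#' @param convention `"absolute"` (default) or `"signed"`.
#' @return EOdds, or `NA` when any rate is undefined.
#' @export
equalized_odds <- function(preds, attribute, privilege = privilege_map(),
                           positive = "PD",
                           convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  r <- group_rates(preds, attribute, privilege, positive)
  vals <- c(r$u$TPR - r$p$TPR, r$u$FPR - r$p$FPR)
  if (anyNA(vals)) return(NA_real_)
  if (convention == "absolute") max(abs(vals)) else max(vals)
}

group_metric_set <- function(df, positive = "PD") {
  c <- confusion_counts(df, positive)
  m <- performance_metrics(c)
  auc <- if (length(unique(df$label)) == 2) auroc(df$score, df$label, positive)
         else NA_real_
  list(f1 = m$f1, sensitivity = m$recall, specificity = m$specificity,
       precision = m$precision, auroc = auc)
}

#' Group-balanced bootstrap of performance and fairness metrics
#'
#' Each of `B` replicates draws `m` rows with replacement from the
#' unprivileged group and `m` from the privileged group (`m` = the smaller
#' group size by default, so the two groups contribute equally), then
#' computes per-group F1, sensitivity, specificity, precision and AUROC
#' plus DI, EO and EOdds on the combined replicate. Replicates where a
#' metric is undefined contribute a missing value, which is counted and
#' reported, not silently dropped.
#'
#' @inheritParams disparate_impact
#' @param B Number of bootstrap replicates (default 100).
#' @param m Per-group draw size; default `min` of the two group sizes.
#' @param seed Integer seed.
#' @param eodds_convention Passed to [equalized_odds()].
#' @return A list with `replicates` (one row per replicate), `summary`
#'   (mean, sd and missing count per metric) and `m`, `B`.
#' @export
bootstrap_group_metrics <- function(preds, attribute,
                                    privilege = privilege_map(), B = 100L,
                                    m = NULL, seed = 1L, positive = "PD",
                                    eodds_convention = "absolute") {
  g <- split_groups(preds, attribute, privilege)
  if (nrow(g$u) == 0 || nrow(g$p) == 0)
    stop("both groups must be nonempty for attribute ", attribute,
         call. = FALSE)
  m <- m %||% min(nrow(g$u), nrow(g$p))
  reps <- vector("list", B)
  with_seed(derive_seed(seed, paste0("bootstrap/", attribute)), {
    for (b in seq_len(B)) {
      du <- g$u[sample.int(nrow(g$u), m, replace = TRUE), , drop = FALSE]
      dp <- g$p[sample.int(nrow(g$p), m, replace = TRUE), , drop = FALSE]
      mu <- group_metric_set(du, positive)
      mp <- group_metric_set(dp, positive)
      comb <- rbind(du, dp)
      reps[[b]] <- data.frame(
        replicate = b,
        f1_u = mu$f1, f1_p = mp$f1,
        sensitivity_u = mu$sensitivity, sensitivity_p = mp$sensitivity,
        specificity_u = mu$specificity, specificity_p = mp$specificity,
        precision_u = mu$precision, precision_p = mp$precision,
        auroc_u = mu$auroc, auroc_p = mp$auroc,
        di = disparate_impact(comb, attribute, privilege, positive),
        eo = equal_opportunity(comb, attribute, privilege, positive),
        eodds = equalized_odds(comb, attribute, privilege, positive,
                               eodds_convention))
    }
  })
  replicates <- do.call(rbind, reps)
  metrics <- setdiff(names(replicates), "replicate")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(replicates[metrics], function(v) mean(v, na.rm = TRUE),
                  numeric(1)),
    sd = vapply(replicates[metrics], function(v) stats::sd(v, na.rm = TRUE),
                numeric(1)),
    n_missing = vapply(replicates[metrics], function(v) sum(is.na(v)),
                       numeric(1)),
    row.names = NULL)
  list(replicates = replicates, summary = summary, m = m, B = B,
       attribute = attribute)
}

#' Significance flags from bootstrap replicates
#'
#' For each performance metric, flags a significant group difference when
#' the percentile bootstrap interval of (unprivileged - privileged) across
#' replicates excludes 0 at level `alpha`. Fewer than 30 valid replicates
#' leaves the flag undefined (`NA`).
#'
#' @param boot Result of [bootstrap_group_metrics()].
#' @param alpha Significance level (default 0.05).
#' @param metrics Metrics to flag.
#' @return Named logical vector of flags.
#' @export
significance_flags <- function(boot, alpha = 0.05,
                               metrics = c("f1", "sensitivity", "specificity",
                                           "precision", "auroc")) {
  rep <- boot$replicates
  out <- stats::setNames(rep(NA, length(metrics)), metrics)
  for (mt in metrics) {
    d <- rep[[paste0(mt, "_u")]] - rep[[paste0(mt, "_p")]]
    d <- d[!is.na(d)]
    if (length(d) < 30) next
    ci <- stats::quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    out[mt] <- ci[1] > 0 || ci[2] < 0
  }
  out
}

#' Impurity-based feature importance, optionally on a subgroup
#'
#' Fits a random forest on the selected rows only and reports the
#' mean-decrease-in-impurity importance normalized to sum to 1, ranked.
#'
#' @param features Feature `data.frame` with a label column.
#' @param subset Logical or integer row selector (default all rows).
#' @param seed Integer seed.
#' @param label_col,positive Label column and positive class.
#' @param k Number of top features to return (`Inf` = all).
#' @return `data.frame` of `feature`, `importance`, ranked descending.
#' @export
stratified_importance <- function(features, subset = NULL, seed = 1L,
                                  label_col = "label", positive = "PD",
                                  k = 10L) {
  if (!is.null(subset)) features <- features[subset, , drop = FALSE]
  lab <- features[[label_col]]
  if (length(unique(lab)) < 2)
    stop("subgroup contains a single class; importance undefined",
         call. = FALSE)
  x <- design_matrix(features, label_col)
  rf <- with_seed(derive_seed(seed, "importance"),
    randomForest::randomForest(x = x,
      y = factor(lab == positive, levels = c(FALSE, TRUE))))
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  ord <- order(-imp)
  out <- data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
                    row.names = NULL)
  utils::head(out, k)
}

#' Full fairness report across attributes
#'
#' Runs the group-balanced bootstrap and significance flags for every
#' attribute in the privilege map, mirroring a per-attribute bias table:
#' per-group performance (mean, sd over replicates), DI, EO, EOdds.
#'
#' @inheritParams bootstrap_group_metrics
#' @param alpha Significance level for the flags.
#' @return A `motorfair_fairness_report`: list of per-attribute blocks.
#' @export
fairness_report <- function(preds, privilege = privilege_map(), B = 100L,
                            seed = 1L, alpha = 0.05, positive = "PD",
                            eodds_convention = "absolute") {
  blocks <- lapply(names(privilege), function(a) {
    boot <- bootstrap_group_metrics(preds, a, privilege, B = B, seed = seed,
                                    positive = positive,
                                    eodds_convention = eodds_convention)
    list(attribute = a,
         privileged = privilege[[a]]$privileged,
         unprivileged = privilege[[a]]$unprivileged,
         summary = boot$summary,
         flags = significance_flags(boot, alpha),
         m = boot$m, B = boot$B)
  })
  names(blocks) <- names(privilege)
  structure(list(attributes = blocks, alpha = alpha, B = B),
            class = "motorfair_fairness_report")
}

#' Write a fairness report to JSON and Markdown
#'
#' @param report A [fairness_report()] result.
#' @param json_path,md_path Output paths (`NULL` to skip one format).
#' @return `json_path`, invisibly.
#' @export
write_fairness_report <- function(report, json_path, md_path = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(md_path)) {
    lines <- c("# Fairness audit", "")
    for (b in report$attributes) {
      lines <- c(lines,
        sprintf("## %s (privileged: %s, unprivileged: %s)",
                b$attribute, b$privileged, b$unprivileged),
        "", "| metric | mean | sd | missing |", "|---|---|---|---|",
        sprintf("| %s | %.3f | %.3f | %d |", b$summary$metric,
                b$summary$mean, b$summary$sd, b$summary$n_missing),
        "",
        paste0("Significant group differences (alpha = ", report$alpha,
               "): ",
               paste(sprintf("%s=%s", names(b$flags), b$flags),
                     collapse = ", ")),
        "")
    }
    writeLines(lines, md_path)
  }
  invisible(json_path)
}
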