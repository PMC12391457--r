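# Independent brute-force oracles used to cross-check the package's metric
# implementations. These enumerate rows/pairs directly and share no code
# with the implementations they check.

oracle_confusion <- function(preds, positive = "PD") {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(preds))) {
    lab_pos <- preds$label[i] == positive
    pred_pos <- preds$predicted[i] == positive
    if (lab_pos && pred_pos) tp <- tp + 1L
    else if (!lab_pos && pred_pos) fp <- fp + 1L
    else if (!lab_pos && !pred_pos) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_auroc <- function(scores, labels, positive = "PD") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
                 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_group_fairness <- function(preds, attribute, privilege,
                                  positive = "PD") {
  a <- privilege[[attribute]]
  rate_of <- function(value) {
    rows <- preds[preds[[a$column]] == value, , drop = FALSE]
    tp <- sum(rows$label == positive & rows$predicted == positive)
    fp <- sum(rows$label != positive & rows$predicted == positive)
    fn <- sum(rows$label == positive & rows$predicted != positive)
    tn <- sum(rows$label != positive & rows$predicted != positive)
    list(pos = (tp + fp) / nrow(rows),
         tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  }
  u <- rate_of(a$unprivileged); p <- rate_of(a$privileged)
  list(
    di = if (p$pos == 0) NA_real_ else u$pos / p$pos,
    eo = if (is.na(u$tpr) || is.na(p$tpr) || p$tpr == 0) NA_real_
         else u$tpr / p$tpr,
    eodds_abs = if (anyNA(c(u$tpr, p$tpr, u$fpr, p$fpr))) NA_real_
                else max(abs(u$tpr - p$tpr), abs(u$fpr - p$fpr)),
    eodds_signed = if (anyNA(c(u$tpr, p$tpr, u$fpr, p$fpr))) NA_real_
                   else max(u$tpr - p$tpr, u$fpr - p$fpr)
  )
}

# minimum AUROC-CI sample size by exhaustive upward scan (linear, no
# bisection), for checking min_sample_size
oracle_min_n <- function(auc, prev, width, conf) {
  z <- qnorm(1 - (1 - conf) / 2)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  for (n in 2:100000) {
    np <- prev * n; nn <- (1 - prev) * n
    se <- sqrt((auc * (1 - auc) + (np - 1) * (q1 - auc^2) +
                  (nn - 1) * (q2 - auc^2)) / (np * nn))
    if (z * se <= width / 2) return(n)
  }
  stop("no n found")
}

random_prediction_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("R%03d", seq_len(n)),
    label = sample(c("PD", "non-PD"), n, replace = TRUE),
    score = round(runif(n), 2),  # rounding forces score ties
    predicted = sample(c("PD", "non-PD"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    race_binary = sample(c("White", "Non-White"), n, replace = TRUE),
    device = sample(c("Windows", "Mac", "Linux"), n, replace = TRUE,
                    prob = c(0.6, 0.3, 0.1)),
    hand = sample(c("right", "left"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
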