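#' Stratified train/test split
#'
#' Splits the feature matrix 70/30 (by default), stratified on the label so
#' class proportions are preserved within one row, deterministically given
#' the seed. Train and test are disjoint and exhaustive.
#'
#' @param features Feature `data.frame` including a label column.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param label_col Name of the label column.
#' @param seed Integer seed.
#' @return A list with `train` and `test` data frames.
#' @export
split_train_test <- function(features, train_fraction = 0.7,
                             label_col = "label", seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  lab <- features[[label_col]]
  if (is.null(lab)) stop("label column not found: ", label_col, call. = FALSE)
  classes <- unique(lab)
  if (length(classes) < 2) stop("both classes must be present", call. = FALSE)
  train_idx <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (cl in sort(classes)) {
      idx <- which(lab == cl)
      if (length(idx) < 2)
        stop("need >= 2 rows per class to split, class ", cl, call. = FALSE)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  list(train = features[train_idx, , drop = FALSE],
       test = features[-train_idx, , drop = FALSE])
}

id_like_cols <- function(df)
  intersect(c("participant_id", "label", ".resampled"), names(df))

#' Min--max scaling and one-hot encoding learned on training data
#'
#' Numeric feature columns are mapped to `[0, 1]` using the training
#' minima/maxima; test rows are transformed with the training statistics
#' and may fall outside `[0, 1]`. A constant training column maps to 0.
#' Character/factor feature columns are replaced by one-hot indicator
#' columns (levels taken from the training data). Identifier and label
#' columns pass through untouched.
#'
#' @param train,test Feature data frames (test may be `NULL`).
#' @return A list with `train`, `test`, and `scaler` (the fitted state:
#'   per-column min/max and categorical level maps).
#' @export
fit_transform <- function(train, test = NULL) {
  if (nrow(train) == 0) stop("train must be nonempty", call. = FALSE)
  keep <- id_like_cols(train)
  feat_cols <- setdiff(names(train), keep)
  num_cols <- feat_cols[vapply(train[feat_cols], is.numeric, logical(1))]
  cat_cols <- setdiff(feat_cols, num_cols)
  ranges <- lapply(train[num_cols], function(x) {
    r <- range(x, na.rm = TRUE)
    if (!all(is.finite(r))) r <- c(0, 0)
    r
  })
  levels_map <- lapply(train[cat_cols], function(x) sort(unique(x[!is.na(x)])))
  scaler <- list(num_cols = num_cols, cat_cols = cat_cols,
                 ranges = ranges, levels = levels_map)
  list(train = apply_scaler(train, scaler),
       test = if (!is.null(test)) apply_scaler(test, scaler) else NULL,
       scaler = scaler)
}

#' @rdname fit_transform
#' @param data Data frame to transform with a previously fitted scaler.
#' @param scaler Fitted scaler state from [fit_transform()].
#' @export
apply_scaler <- function(data, scaler) {
  out <- data
  for (cn in scaler$num_cols) {
    r <- scaler$ranges[[cn]]
    out[[cn]] <- if (r[2] > r[1]) (data[[cn]] - r[1]) / (r[2] - r[1])
                 else rep(0, nrow(data))
  }
  for (cn in scaler$cat_cols) {
    for (lv in scaler$levels[[cn]]) {
      safe <- gsub("[^A-Za-z0-9]+", "_", lv)
      out[[paste0(cn, "_", safe)]] <- as.numeric(data[[cn]] == lv)
    }
    out[[cn]] <- NULL
  }
  out
}

#' SMOTE class rebalancing
#'
#' Balances the two classes by synthesizing minority-class rows: each
#' synthetic row is `x + u * (x_nn - x)`, `u ~ U(0, 1)`, interpolating a
#' minority row and one of its `k` nearest minority neighbours (Euclidean
#' distance on the numeric feature columns). Non-numeric and identifier
#' columns are copied from the seed row. Rows from devices listed in
#' `exclude_devices` (Linux by default, too small a group to balance) are
#' dropped before balancing. Intended for the training partition only.
#'
#' @param train Training feature `data.frame` with a `label` column.
#' @param k Number of minority nearest neighbours (default 5).
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @param exclude_devices Devices removed before up-sampling.
#' @param device_col Column naming the device group, if present.
#' @return The balanced `data.frame`; synthetic rows carry
#'   `.smote_parent1` / `.smote_parent2` row indices in
#'   `attr(, "smote_parents")`.
#' @export
smote_upsample <- function(train, k = 5L, seed = 1L, label_col = "label",
                           exclude_devices = "Linux", device_col = "device") {
  dev <- if (device_col %in% names(train)) train[[device_col]] else NULL
  if (!is.null(dev) && length(exclude_devices))
    train <- train[!(dev %in% exclude_devices), , drop = FALSE]
  lab <- train[[label_col]]
  counts <- table(lab)
  if (length(counts) != 2) stop("expected exactly two classes", call. = FALSE)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min <= k)
    stop("minority class has ", n_min, " rows; needs more than k = ", k,
         " (use a smaller k)", call. = FALSE)
  n_new <- n_maj - n_min
  if (n_new == 0) {
    attr(train, "smote_parents") <- data.frame(parent1 = integer(0),
                                               parent2 = integer(0))
    return(train)
  }
  keep <- id_like_cols(train)
  feat_cols <- setdiff(names(train), keep)
  num_cols <- feat_cols[vapply(train[feat_cols], is.numeric, logical(1))]
  min_idx <- which(lab == minority)
  X <- as.matrix(train[min_idx, num_cols, drop = FALSE])
  X[is.na(X)] <- 0  # neighbour search only; copied values keep their NAs
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  with_seed(derive_seed(seed, "smote"), {
    seeds_i <- sample(seq_along(min_idx), n_new, replace = TRUE)
    picks <- vapply(seeds_i, function(i) nn[i, sample.int(k, 1)], integer(1))
    u <- stats::runif(n_new)
  })
  synth <- train[min_idx[seeds_i], , drop = FALSE]
  for (j in seq_along(num_cols)) {
    cn <- num_cols[j]
    a <- train[[cn]][min_idx[seeds_i]]
    b <- train[[cn]][min_idx[picks]]
    synth[[cn]] <- a + u * (b - a)
  }
  if ("participant_id" %in% names(synth))
    synth$participant_id <- sprintf("%s_s%04d",
                                    synth$participant_id, seq_len(n_new))
  out <- rbind(train, synth)
  rownames(out) <- NULL
  attr(out, "smote_parents") <- data.frame(
    row = nrow(train) + seq_len(n_new),
    parent1 = min_idx[seeds_i], parent2 = min_idx[picks])
  out
}

#' Random up-sampling of the Non-White non-PD subgroup
#'
#' Resamples the under-represented subgroup (by default Non-White rows with
#' the non-PD label) with replacement until its count reaches `ratio`
#' times the size of the matching White subgroup. All other rows pass
#' through untouched; duplicated rows are flagged in the `.resampled`
#' provenance column.
#'
#' @param data Feature `data.frame` with `race_binary` and label columns.
#' @param ratio Target size of the subgroup as a fraction of the White
#'   subgroup of the same status (default 1 = parity).
#' @param seed Integer seed.
#' @param status Which diagnostic status defines the subgroup
#'   (default `"non-PD"`).
#' @param label_col,race_col Column names.
#' @return The augmented `data.frame` with a logical `.resampled` column.
#' @export
race_upsample <- function(data, ratio = 1.0, seed = 1L, status = "non-PD",
                          label_col = "label", race_col = "race_binary") {
  sub <- which(data[[race_col]] == "Non-White" & data[[label_col]] == status)
  ref <- which(data[[race_col]] == "White" & data[[label_col]] == status)
  if (!length(sub))
    stop("Non-White ", status, " subgroup is empty; nothing to resample",
         call. = FALSE)
  data$.resampled <- rep(FALSE, nrow(data))
  target <- round(ratio * length(ref))
  n_add <- max(0L, target - length(sub))
  if (n_add == 0) return(data)
  with_seed(derive_seed(seed, "race_upsample"), {
    picks <- sample(sub, n_add, replace = TRUE)
  })
  extra <- data[picks, , drop = FALSE]
  extra$.resampled <- TRUE
  out <- rbind(data, extra)
  rownames(out) <- NULL
  out
}

#' Missing-data policy: row filtering and train-median imputation
#'
#' Rows missing more than `row_missing_max` of their numeric features are
#' dropped; remaining missing numeric values are imputed with the median
#' of the training split only (the test partition never contributes to
#' the imputation statistics).
#'
#' @param train,test Feature data frames (`test` may be `NULL`).
#' @param row_missing_max Maximum tolerated fraction of missing features
#'   per row before the row is removed.
#' @return List with imputed `train`, `test` and the `medians` used.
#' @export
impute_features <- function(train, test = NULL, row_missing_max = 0.2) {
  keep <- id_like_cols(train)
  num_cols <- setdiff(names(train), keep)
  num_cols <- num_cols[vapply(train[num_cols], is.numeric, logical(1))]
  drop_rows <- function(df) {
    if (!nrow(df)) return(df)
    frac <- rowMeans(is.na(df[, num_cols, drop = FALSE]))
    df[frac <= row_missing_max, , drop = FALSE]
  }
  train <- drop_rows(train)
  medians <- vapply(train[num_cols],
                    function(x) stats::median(x, na.rm = TRUE), numeric(1))
  fill <- function(df) {
    for (cn in num_cols) {
      i <- is.na(df[[cn]])
      if (any(i)) df[[cn]][i] <- medians[[cn]]
    }
    df
  }
  list(train = fill(train),
       test = if (!is.null(test)) fill(drop_rows(test)) else NULL,
       medians = medians)
}
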