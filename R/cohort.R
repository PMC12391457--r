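#' Cohort configuration
#'
#' Describes the demographic structure of a simulated study cohort by its
#' marginal counts: diagnostic label, sex, device type, dominant hand, and
#' the joint race-by-status table. The default reproduces the structure of
#' a 251-participant remote PD assessment cohort: 99 PD (diagnosed or
#' suspected, merged into one category) vs 152 controls, 212 male / 39
#' female, 201 Windows / 41 Mac / 8 Linux, 176 right- / 75 left-handed,
#' with the White group split 51 PD / 134 non-PD and the Black group
#' 33 PD / 6 non-PD. The published race margin (250) and device margin
#' (201/41/8 = 250) each fall one short of 251; the defaults place the
#' missing participant in the American-Indian/Alaska-Native group and the
#' Windows group respectively so every margin is consistent at 251.
#'
#' @param n_total Total number of participants.
#' @param n_pd Number of PD-labeled participants.
#' @param sex_counts Named counts for `male` and `female`.
#' @param device_counts Named counts for `Windows`, `Mac`, `Linux`.
#' @param hand_counts Named counts for `right` and `left`.
#' @param race_by_status Matrix of counts, rows = race levels, columns
#'   `PD` and `non-PD`.
#' @param seed Integer seed controlling the joint assignment.
#' @return An object of class `motorfair_cohort_config`.
#' @export
cohort_config <- function(n_total = 251,
                          n_pd = 99,
                          sex_counts = c(male = 212, female = 39),
                          device_counts = c(Windows = 202, Mac = 41, Linux = 8),
                          hand_counts = c(right = 176, left = 75),
                          race_by_status = default_race_by_status(),
                          seed = 1L) {
  cfg <- list(n_total = as.integer(n_total), n_pd = as.integer(n_pd),
              sex_counts = sex_counts, device_counts = device_counts,
              hand_counts = hand_counts, race_by_status = race_by_status,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "motorfair_cohort_config")
}

#' @rdname cohort_config
#' @export
race_levels <- function() {
  c("White", "Black", "American-Indian/Alaska-Native", "Asian",
    "Native-Hawaiian/Pacific-Islander")
}

#' @rdname cohort_config
#' @export
default_race_by_status <- function() {
  m <- matrix(c(51, 134,
                33,   6,
                12,   9,
                 1,   1,
                 2,   2),
              ncol = 2, byrow = TRUE,
              dimnames = list(race_levels(), c("PD", "non-PD")))
  m
}

validate_cohort_config <- function(cfg) {
  n <- cfg$n_total
  if (n < 0 || cfg$n_pd < 0) stop("counts must be non-negative", call. = FALSE)
  if (cfg$n_pd > n) stop("n_pd exceeds n_total", call. = FALSE)
  check <- function(counts, margin) {
    if (any(counts < 0))
      stop(sprintf("negative count in %s margin", margin), call. = FALSE)
    if (sum(counts) != n)
      stop(sprintf("%s margin sums to %d, expected n_total = %d",
                   margin, sum(counts), n), call. = FALSE)
  }
  check(cfg$sex_counts, "sex")
  check(cfg$device_counts, "device")
  check(cfg$hand_counts, "hand")
  rbs <- cfg$race_by_status
  if (any(rbs < 0)) stop("negative count in race_by_status", call. = FALSE)
  if (sum(rbs) != n)
    stop(sprintf("race_by_status sums to %d, expected n_total = %d",
                 sum(rbs), n), call. = FALSE)
  if (sum(rbs[, "PD"]) != cfg$n_pd)
    stop(sprintf("race_by_status PD column sums to %d, expected n_pd = %d",
                 sum(rbs[, "PD"]), cfg$n_pd), call. = FALSE)
  invisible(cfg)
}

#' Generate a demographically structured cohort
#'
#' Reproduces every configured marginal count exactly: the race-by-status
#' joint is taken as given, and sex, device and hand labels are assigned by
#' seeded permutation of vectors holding exactly the configured counts
#' (one-way margins exact; higher-order joints random).
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with columns `id`, `sex`, `race`, `race_binary`,
#'   `device`, `hand`, `label`, one row per participant.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_total
  cols <- c("id", "sex", "race", "race_binary", "device", "hand", "label")
  if (n == 0L) {
    out <- data.frame(id = character(), sex = character(), race = character(),
                      race_binary = character(), device = character(),
                      hand = character(), label = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  rbs <- config$race_by_status
  race <- rep(rep(rownames(rbs), times = ncol(rbs)), times = as.vector(rbs))
  label <- rep(rep(colnames(rbs), each = nrow(rbs)), times = as.vector(rbs))
  with_seed(derive_seed(config$seed, "cohort"), {
    sex <- sample(rep(names(config$sex_counts), times = config$sex_counts))
    device <- sample(rep(names(config$device_counts), times = config$device_counts))
    hand <- sample(rep(names(config$hand_counts), times = config$hand_counts))
  })
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    race = race,
    race_binary = ifelse(race == "White", "White", "Non-White"),
    device = device,
    hand = hand,
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Read or write a cohort CSV
#'
#' The cohort file is a plain CSV with header
#' `id,sex,race,race_binary,device,hand,label`.
#'
#' @param cohort Cohort `data.frame` as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "race", "race_binary", "device", "hand", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}
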