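# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Table-style defaults for the generator: category prevalences 65/39/84/18
# of 206; per-category BMI-class percentages, female %, age mean (SD) from
# the published per-category characteristics. The bulimic BMI-class row
# prints 99.8% in the source and is renormalised.
default_bmi_class_probs <- function() {
  m <- rbind(RD  = c(78.5, 18.5, 1.5, 1.5),
             BD  = c(10.2, 48.7, 10.2, 30.7),
             HD  = c(0.0, 2.4, 2.4, 95.2),
             OED = c(5.6, 22.2, 11.1, 61.1))
  colnames(m) <- bmi_classes()
  sweep(m, 1, rowSums(m), "/")
}

default_bmi_mean_sd <- function() {
  m <- rbind(RD = c(17.6, 3.8), BD = c(25.9, 8.1),
             HD = c(39.1, 7.0), OED = c(30.8, 8.3))
  colnames(m) <- c("mean", "sd")
  m
}

default_age_mean_sd <- function() {
  m <- rbind(RD = c(30.4, 12.1), BD = c(28.5, 9.8),
             HD = c(43.9, 13.9), OED = c(37.1, 15.6))
  colnames(m) <- c("mean", "sd")
  m
}

#' Configuration of the synthetic screen-positive cohort generator
#'
#' Defaults emulate the published validation cohort: category prevalences
#' 65/39/84/18 out of 206; per-category BMI-class, sex and age
#' distributions from the published patient characteristics. BMI values are
#' drawn uniformly within the sampled class by default (class membership,
#' not the exact value, drives the rule); `bmi_sampler = "normal"` instead
#' draws from the per-category normal (published mean/SD) truncated to the
#' class interval.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer RNG seed; the same config always yields the same
#'   cohort.
#' @param prevalence Length-4 probabilities over (RD, BD, HD, OED).
#' @param bmi_class_probs 4x4 matrix, rows = categories, columns = BMI
#'   classes; each row a probability distribution.
#' @param female_prob Length-4 per-category probability of female sex.
#' @param age_mean_sd 4x2 matrix of per-category age mean and SD (years);
#'   ages are truncated at 18 (the inclusion criterion).
#' @param bmi_sampler `"uniform"` (default) or `"normal"`.
#' @param bmi_mean_sd 4x2 matrix of per-category BMI mean and SD, used by
#'   the `"normal"` sampler.
#' @param bmi_range Numeric of length 5: boundaries of the within-class
#'   sampling intervals, default `c(12, 18.5, 25, 30, 60)`.
#' @param epsilon Response-noise probability in \[0, 1\]: with probability
#'   `epsilon` a record's SCOFF pattern is drawn from the patterns NOT
#'   mapping to its true category. Default 0.1.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n = 206, seed = 1,
                          prevalence = c(65, 39, 84, 18) / 206,
                          bmi_class_probs = default_bmi_class_probs(),
                          female_prob = c(0.984, 1.0, 0.917, 0.944),
                          age_mean_sd = default_age_mean_sd(),
                          bmi_sampler = c("uniform", "normal"),
                          bmi_mean_sd = default_bmi_mean_sd(),
                          bmi_range = c(12, 18.5, 25, 30, 60),
                          epsilon = 0.1) {
  bmi_sampler <- match.arg(bmi_sampler)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  prevalence <- as.numeric(prevalence)
  check_probs <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("%s must be nonnegative and sum to 1", what), call. = FALSE)
    }
  }
  check_probs(prevalence, "prevalence")
  bmi_class_probs <- as.matrix(bmi_class_probs)
  stopifnot(all(dim(bmi_class_probs) == c(4, 4)))
  for (i in 1:4) check_probs(bmi_class_probs[i, ],
                             sprintf("bmi_class_probs row %d", i))
  if (length(female_prob) != 4 || any(female_prob < 0 | female_prob > 1)) {
    stop("female_prob must be 4 probabilities", call. = FALSE)
  }
  age_mean_sd <- as.matrix(age_mean_sd)
  bmi_mean_sd <- as.matrix(bmi_mean_sd)
  stopifnot(all(dim(age_mean_sd) == c(4, 2)), all(dim(bmi_mean_sd) == c(4, 2)))
  if (length(bmi_range) != 5 || is.unsorted(bmi_range, strictly = TRUE)) {
    stop("bmi_range must be 5 strictly increasing boundaries", call. = FALSE)
  }
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be in [0, 1]", call. = FALSE)
  }
  structure(list(n = n, seed = seed, prevalence = prevalence,
                 bmi_class_probs = unname(bmi_class_probs),
                 female_prob = as.numeric(female_prob),
                 age_mean_sd = unname(age_mean_sd),
                 bmi_sampler = bmi_sampler,
                 bmi_mean_sd = unname(bmi_mean_sd),
                 bmi_range = as.numeric(bmi_range),
                 epsilon = epsilon),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: n = %d, seed = %d, epsilon = %.2f, bmi_sampler = %s\n",
              x$n, x$seed, x$epsilon, x$bmi_sampler))
  cat("  prevalence (RD/BD/HD/OED):",
      paste(sprintf("%.3f", x$prevalence), collapse = "/"), "\n")
  invisible(x)
}

#' Read a generator config from JSON or YAML
#'
#' Unknown fields are rejected; missing fields take the defaults of
#' [cohort_config()].
#'
#' @param path File ending in .json, .yaml or .yml.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("config must be a .json, .yaml or .yml file", call. = FALSE)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (f in c("bmi_class_probs", "age_mean_sd", "bmi_mean_sd")) {
    # row-lists deserialise either as a list of vectors or, when jsonlite
    # simplifies, as a matrix already
    if (!is.null(fields[[f]]) && is.list(fields[[f]])) {
      fields[[f]] <- do.call(rbind, fields[[f]])
    }
  }
  do.call(cohort_config, fields)
}

#' Write a generator config (or the default template) as JSON
#'
#' @param config A `cohort_config`; default the package defaults.
#' @param path Output path; `NULL` returns the JSON text.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_cohort_config <- function(config = cohort_config(), path = NULL) {
  x <- unclass(config)
  for (f in c("bmi_class_probs", "age_mean_sd", "bmi_mean_sd")) {
    x[[f]] <- lapply(seq_len(nrow(x[[f]])), function(i) unname(x[[f]][i, ]))
  }
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# per (class, category) sets of compatible pattern indices under a table
compatible_sets <- function(table) {
  pat_keys <- rownames(eligible_patterns())
  lookup <- rule_lookup(table)
  sets <- list()
  for (cls in bmi_classes()) {
    cats <- lookup[cell_key(pat_keys, cls)]
    sets[[cls]] <- lapply(stats::setNames(nm = broad_categories()),
                          function(cat) which(unname(cats) == cat))
  }
  sets
}

#' Restrict a config to category-compatible BMI classes
#'
#' Zeroes out, for each category, the probability of BMI classes in which
#' the rule table has no cell mapping to that category (e.g. no bulimic
#' cell exists in the underweight class), then renormalises. With
#' `epsilon = 0`, a cohort generated under the resulting config is in
#' perfect physician/algorithm agreement by construction.
#'
#' @param config A `cohort_config`.
#' @param table A `rule_table`.
#' @return The adjusted `cohort_config`.
#' @export
compatible_config <- function(config, table = default_rule_table()) {
  sets <- compatible_sets(table)
  probs <- config$bmi_class_probs
  for (i in seq_along(broad_categories())) {
    cat <- broad_categories()[i]
    ok <- vapply(bmi_classes(), function(cls) length(sets[[cls]][[cat]]) > 0,
                 logical(1))
    probs[i, !ok] <- 0
    if (sum(probs[i, ]) == 0) {
      stop(sprintf("category %s has no compatible BMI class under this table", cat),
           call. = FALSE)
    }
    probs[i, ] <- probs[i, ] / sum(probs[i, ])
  }
  config$bmi_class_probs <- probs
  config
}

# sample one index from a set (safe for length-1 sets)
sample_one <- function(x) x[sample.int(length(x), 1L)]

# truncated-normal draw on [lo, hi] by inverse CDF
rtnorm <- function(k, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(k, plo, phi), mean, sd)
}

#' Generate a synthetic screen-positive cohort
#'
#' Each record draws a true broad category from the prevalence vector, a
#' BMI class from the category's class distribution, a BMI value within
#' the class, sex and age from the category parameters, and a DSM-5 label
#' uniformly from the category's members. The SCOFF pattern follows the
#' response model: with probability 1 - epsilon a uniform draw from the
#' eligible patterns that the rule table maps, in the drawn BMI class, to
#' the true category (falling back to a uniform eligible pattern when no
#' such cell exists, which models structural misclassification); with
#' probability epsilon a uniform draw over the other eligible patterns.
#' All records are screen-positive by construction, and identical
#' (config, table) pairs give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param table A `rule_table`.
#' @return Cohort data frame in the Patient CSV layout, with extra columns
#'   `true_category` and `dsm5_diagnosis`.
#' @export
generate_cohort <- function(config, table = default_rule_table()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!inherits(table, "rule_table")) stop("table must be a rule_table", call. = FALSE)
  pat <- eligible_patterns()
  sets <- compatible_sets(table)
  cats <- broad_categories()
  classes <- bmi_classes()
  with_seed(config$seed, {
    n <- config$n
    cat_idx <- sample.int(4, n, replace = TRUE, prob = config$prevalence)
    cls_idx <- integer(n)
    bmi <- numeric(n)
    age <- numeric(n)
    sex <- character(n)
    dx <- character(n)
    for (k in 1:4) {
      idx <- which(cat_idx == k)
      if (length(idx) == 0) next
      cls_idx[idx] <- sample.int(4, length(idx), replace = TRUE,
                                 prob = config$bmi_class_probs[k, ])
      age[idx] <- rtnorm(length(idx), config$age_mean_sd[k, 1],
                         config$age_mean_sd[k, 2], 18, Inf)
      sex[idx] <- ifelse(stats::runif(length(idx)) < config$female_prob[k],
                         "female", "male")
      members <- dsm5_members(cats[k])
      dx[idx] <- members[sample.int(length(members), length(idx), replace = TRUE)]
    }
    lo <- config$bmi_range[cls_idx]
    hi <- config$bmi_range[cls_idx + 1]
    if (config$bmi_sampler == "uniform") {
      bmi <- stats::runif(n, lo, hi)
    } else {
      bmi <- rtnorm(n, config$bmi_mean_sd[cat_idx, 1],
                    config$bmi_mean_sd[cat_idx, 2], lo, hi)
    }
    # round for output but keep strictly inside the drawn class
    # (upper boundaries belong to the next class)
    bmi <- pmax(lo, pmin(round(bmi, 2), hi - 0.01))
    noisy <- stats::runif(n) < config$epsilon
    pat_idx <- vapply(seq_len(n), function(i) {
      compat <- sets[[classes[cls_idx[i]]]][[cats[cat_idx[i]]]]
      pool <- if (noisy[i]) setdiff(seq_len(26L), compat) else compat
      if (length(pool) == 0) pool <- seq_len(26L)
      sample_one(pool)
    }, integer(1))
    answers <- pat[pat_idx, , drop = FALSE]
    colnames(answers) <- scoff_columns()
    records <- data.frame(id = sprintf("S%05d", seq_len(n)), sex = sex,
                          age = round(age, 1), bmi = bmi,
                          answers, dsm5_diagnosis = dx,
                          true_category = cats[cat_idx],
                          stringsAsFactors = FALSE)
    validate_cohort(records)
  })
}

#' Parameter-recovery harness for the generator
#'
#' Generates `reps` cohorts (seeds `config$seed`, `config$seed + 1`, ...),
#' evaluates the diagnostics on each, and summarises per-category
#' sensitivity and specificity and Cohen's kappa across replicates.
#' Categories absent from a replicate contribute `NA` for that replicate.
#'
#' @param config A [cohort_config()].
#' @param table A `rule_table`.
#' @param reps Number of replicate cohorts (>= 1).
#' @return List of class `recovery_summary`: `per_category` data frame
#'   (category, sens_mean, sens_sd, spec_mean, spec_sd), `kappa_mean`,
#'   `kappa_sd`, `reps`, `n`.
#' @export
recover_operating_characteristics <- function(config, table = default_rule_table(),
                                              reps = 20) {
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1) stop("reps must be >= 1", call. = FALSE)
  sens <- spec <- matrix(NA_real_, nrow = reps, ncol = 4,
                         dimnames = list(NULL, broad_categories()))
  kap <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    records <- generate_cohort(cfg, table)
    cm <- build_confusion(records, table)
    for (j in seq_along(broad_categories())) {
      k <- ovr_counts(cm, broad_categories()[j])
      if (k$tp + k$fn > 0) sens[r, j] <- k$tp / (k$tp + k$fn)
      if (k$tn + k$fp > 0) spec[r, j] <- k$tn / (k$tn + k$fp)
    }
    kap[r] <- cohen_kappa(cm)$kappa
  }
  per_category <- data.frame(category = broad_categories(),
                             sens_mean = colMeans(sens, na.rm = TRUE),
                             sens_sd = apply(sens, 2, stats::sd, na.rm = TRUE),
                             spec_mean = colMeans(spec, na.rm = TRUE),
                             spec_sd = apply(spec, 2, stats::sd, na.rm = TRUE),
                             row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_category = per_category, kappa_mean = mean(kap),
                 kappa_sd = stats::sd(kap), reps = reps, n = config$n),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Operating-characteristic recovery over %d cohorts of n = %d\n",
              x$reps, x$n))
  print(x$per_category, digits = 3)
  cat(sprintf("kappa: mean %.3f, sd %.3f\n", x$kappa_mean,
              if (is.na(x$kappa_sd)) 0 else x$kappa_sd))
  invisible(x)
}
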