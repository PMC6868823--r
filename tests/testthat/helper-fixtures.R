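# Shared fixtures built in code.

# All 32 possible answer vectors, as a 32x5 0/1 matrix in item order.
all_patterns <- function() {
  g <- as.matrix(expand.grid(food = 0:1, fat = 0:1, one_stone = 0:1,
                             control = 0:1, sick = 0:1))
  g[, rev(colnames(g))]
}

# One (pattern, bmi) probe per algorithm category under the default table,
# verified by the tests themselves.
algo_probes <- function() {
  list(RD = list(bits = c(0, 0, 1, 1, 0), bmi = 16.5),
       BD = list(bits = c(1, 1, 0, 0, 0), bmi = 21),
       HD = list(bits = c(0, 1, 0, 0, 1), bmi = 34),
       OED = list(bits = c(0, 0, 0, 1, 1), bmi = 22))
}

# representative DSM-5 label per broad category
truth_labels <- c(RD = "anorexia_nervosa", BD = "bulimia_nervosa",
                  HD = "binge_eating_disorder", OED = "night_eating_syndrome")

# Build a cohort whose (physician, algorithm) pairs tally to `counts`
# (4x4, truth rows x algorithm columns) under the default rule table.
make_tallied_cohort <- function(counts) {
  cats <- broad_categories()
  probes <- algo_probes()
  rows <- list()
  id <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      k <- counts[i, j]
      if (k == 0) next
      probe <- probes[[cats[j]]]
      for (r in seq_len(k)) {
        id <- id + 1
        rows[[id]] <- data.frame(
          id = sprintf("T%04d", id), sex = "female", age = 30,
          bmi = probe$bmi,
          scoff_sick = probe$bits[1], scoff_control = probe$bits[2],
          scoff_one_stone = probe$bits[3], scoff_fat = probe$bits[4],
          scoff_food = probe$bits[5],
          dsm5_diagnosis = truth_labels[[cats[i]]],
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_cohort(do.call(rbind, rows))
}

# Per-record oracle: tally a cohort by classifying one record at a time
# with classify(), independently of classify_cohort()/build_confusion().
tally_per_record <- function(records, table) {
  m <- matrix(0L, 4, 4, dimnames = list(broad_categories(), broad_categories()))
  for (r in seq_len(nrow(records))) {
    resp <- scoff_response(records$scoff_sick[r], records$scoff_control[r],
                           records$scoff_one_stone[r], records$scoff_fat[r],
                           records$scoff_food[r])
    res <- classify(resp, records$bmi[r], table)
    truth <- as.character(map_dsm5_to_broad(records$dsm5_diagnosis[r]))
    m[truth, res$category] <- m[truth, res$category] + 1L
  }
  m
}
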