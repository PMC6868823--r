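#' Enumerate the eligible SCOFF answer patterns
#'
#' A pattern is eligible for the classification rule when at least two of
#' the five answers are positive; 26 of the 32 possible patterns qualify.
#' Patterns are returned in canonical lexicographic order over the
#' (sick, control, one_stone, fat, food) bit tuple.
#'
#' @return Integer matrix with 26 rows and columns named after the items.
#' @export
#' @examples
#' nrow(eligible_patterns()) # 26
eligible_patterns <- function() {
  grid <- as.matrix(expand.grid(food = 0:1, fat = 0:1, one_stone = 0:1,
                                control = 0:1, sick = 0:1))
  grid <- grid[, rev(colnames(grid))]
  keep <- rowSums(grid) >= 2
  pat <- grid[keep, , drop = FALSE]
  ord <- do.call(order, as.data.frame(pat))
  pat <- pat[ord, , drop = FALSE]
  rownames(pat) <- apply(pat, 1, paste, collapse = "")
  storage.mode(pat) <- "integer"
  pat
}

pattern_key <- function(bits) paste(as.integer(bits), collapse = "")

cell_key <- function(pattern_keys, bmi_class) {
  paste(pattern_keys, bmi_class, sep = "|")
}

#' Published marginal counts of the rule table
#'
#' The per-BMI-class distribution of the 104 cells over the four broad
#' categories, as published for the original algorithm: every underweight
#' cell is RD; overweight and obese rows are identical (8 BD, 7 HD,
#' 11 OED); category totals are 29/34/15/26.
#'
#' @return 4x4 integer matrix, rows = BMI classes, columns = categories.
#' @export
published_marginals <- function() {
  m <- rbind(underweight = c(26, 0, 0, 0),
             normal      = c(3, 18, 1, 4),
             overweight  = c(0, 8, 7, 11),
             obese       = c(0, 8, 7, 11))
  colnames(m) <- broad_categories()
  storage.mode(m) <- "integer"
  m
}

# The three published worked assignments: pattern bits, BMI value, category.
worked_examples <- function() {
  data.frame(
    sick = c(0L, 1L, 0L), control = c(0L, 1L, 1L), one_stone = c(1L, 0L, 0L),
    fat = c(1L, 0L, 0L), food = c(0L, 0L, 1L),
    bmi = c(16.5, 21, 34),
    category = c("RD", "BD", "HD"),
    stringsAsFactors = FALSE
  )
}

new_rule_table <- function(cells, provenance) {
  rownames(cells) <- NULL
  structure(cells, class = c("rule_table", "data.frame"),
            provenance = provenance)
}

#' Default reconstructed rule table
#'
#' The original 104-cell expert mapping is proprietary and unpublished;
#' only its per-class marginal counts and three worked assignments are on
#' record. This constructor builds a clearly-labelled DEFAULT
#' RECONSTRUCTION that (a) reproduces the published marginals exactly,
#' (b) satisfies the three worked examples, and (c) fills the remaining
#' cells by fixed clinical-heuristic rankings:
#'
#' * underweight: every eligible pattern maps to RD;
#' * normal: the 3 RD cells are the weight-loss/feeling-fat patterns
#'   (one_stone & fat) least contaminated by bulimic items; the single HD
#'   cell is loss-of-control + food-dominates without vomiting; the 18 BD
#'   cells are the most bulimic remaining patterns (sick first, then
#'   control); the rest are OED;
#' * overweight and obese (identical): the 7 HD cells are
#'   control-and-food patterns (binge signature), non-vomiting ones first;
#'   the 8 BD cells are the most bulimic of the rest; no RD; 11 OED.
#'
#' Cells beyond the published constraints are reconstruction, not the
#' original expert assignments; swap in any user table with
#' [load_rule_table()].
#'
#' @return A `rule_table`: data frame with columns `sick, control,
#'   one_stone, fat, food, bmi_class, category` (104 rows), provenance
#'   `"default-reconstruction"`.
#' @export
default_rule_table <- function() {
  pat <- eligible_patterns()
  n_bits <- rowSums(pat)
  s <- pat[, "sick"]; c_ <- pat[, "control"]; o <- pat[, "one_stone"]
  f1 <- pat[, "fat"]; f2 <- pat[, "food"]
  lex <- seq_len(nrow(pat)) # rows already in canonical order

  # greedy quota filling: pick `quota` unassigned patterns ranked by `ord`
  take <- function(assigned, eligible_idx, ord, quota) {
    pool <- setdiff(eligible_idx, assigned)
    pool[order(ord[pool])][seq_len(quota)]
  }

  assign_class <- function(bmi_class) {
    cat_of <- rep(NA_character_, nrow(pat))
    if (bmi_class == "underweight") {
      cat_of[] <- "RD"
      return(cat_of)
    }
    done <- integer(0)
    if (bmi_class == "normal") {
      # RD: recent weight loss + feeling fat, fewest bulimic items first
      rd <- take(done, which(o == 1 & f1 == 1), order(order(s + c_, lex)), 3)
      cat_of[rd] <- "RD"; done <- c(done, rd)
      # HD: loss of control + food dominates, no vomiting; fewest extras first
      hd <- take(done, which(c_ == 1 & f2 == 1 & s == 0),
                 order(order(n_bits, lex)), 1)
      cat_of[hd] <- "HD"; done <- c(done, hd)
      # BD: most bulimic remaining (vomiting first, then loss of control)
      bd <- take(done, seq_len(nrow(pat)), order(order(-s, -c_, lex)), 18)
      cat_of[bd] <- "BD"; done <- c(done, bd)
    } else { # overweight, obese
      hd <- take(done, which(c_ == 1 & f2 == 1), order(order(s, n_bits, lex)), 7)
      cat_of[hd] <- "HD"; done <- c(done, hd)
      bd <- take(done, which(s == 1), order(order(-c_, lex)), 8)
      cat_of[bd] <- "BD"; done <- c(done, bd)
    }
    cat_of[is.na(cat_of)] <- "OED"
    cat_of
  }

  cells <- do.call(rbind, lapply(bmi_classes(), function(cls) {
    data.frame(pat, bmi_class = cls, category = assign_class(cls),
               stringsAsFactors = FALSE)
  }))
  new_rule_table(cells, "default-reconstruction")
}

#' Load a rule table from CSV
#'
#' Format: header `sick,control,one_stone,fat,food,bmi_class,category`,
#' bits as 0/1, `bmi_class` in underweight/normal/overweight/obese,
#' `category` in RD/BD/HD/OED, exactly 104 data rows (26 eligible patterns
#' x 4 BMI classes). Row order is irrelevant on load; [write_rule_table()]
#' emits canonical order.
#'
#' @param path Path to the rule-table CSV.
#' @return A `rule_table` with provenance set to `path`.
#' @export
load_rule_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c(scoff_items(), "bmi_class", "category")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("rule table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rows <- seq_len(nrow(raw)) + 1L # header is line 1
  for (item in scoff_items()) {
    bad <- !raw[[item]] %in% c(0L, 1L)
    if (any(bad)) {
      stop(sprintf("row %d: item '%s' must be 0 or 1", rows[bad][1], item),
           call. = FALSE)
    }
  }
  bad_class <- !raw$bmi_class %in% bmi_classes()
  if (any(bad_class)) {
    stop(sprintf("row %d: unknown bmi_class '%s'",
                 rows[bad_class][1], raw$bmi_class[bad_class][1]), call. = FALSE)
  }
  bad_cat <- !raw$category %in% broad_categories()
  if (any(bad_cat)) {
    stop(sprintf("row %d: unknown category '%s'",
                 rows[bad_cat][1], raw$category[bad_cat][1]), call. = FALSE)
  }
  bits <- as.matrix(raw[, scoff_items()])
  ineligible <- rowSums(bits) < 2
  if (any(ineligible)) {
    stop(sprintf("row %d: pattern %s not eligible (fewer than 2 positive answers)",
                 rows[ineligible][1],
                 pattern_key(bits[which(ineligible)[1], ])),
         call. = FALSE)
  }
  keys <- cell_key(apply(bits, 1, paste, collapse = ""), raw$bmi_class)
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop(sprintf("row %d: duplicate cell (%s)", rows[duplicated(keys)][1], dup),
         call. = FALSE)
  }
  expected <- cell_key(rep(rownames(eligible_patterns()), times = 4),
                       rep(bmi_classes(), each = 26))
  absent <- setdiff(expected, keys)
  if (length(absent) > 0) {
    stop(sprintf("rule table incomplete: %d missing cell(s), first: %s",
                 length(absent), absent[1]), call. = FALSE)
  }
  # reorder to canonical: class blocks, lexicographic patterns inside
  cells <- raw[order(match(keys, expected)), need]
  for (item in scoff_items()) cells[[item]] <- as.integer(cells[[item]])
  new_rule_table(cells, path)
}

#' Write a rule table to CSV in canonical order
#'
#' @param table A `rule_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(table, path) {
  stopifnot(inherits(table, "rule_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# fast lookup: named character vector key -> category
rule_lookup <- function(table) {
  bits <- apply(as.matrix(table[, scoff_items()]), 1, paste, collapse = "")
  stats::setNames(table$category, cell_key(bits, table$bmi_class))
}

#' Validate a rule table against the published marginal counts
#'
#' Compares, per BMI class, the observed category counts with the published
#' marginals ([published_marginals()]), and checks the three published
#' worked assignments. Failures are reported, not thrown.
#'
#' @param table A `rule_table`.
#' @param expected Expected marginal matrix; default [published_marginals()].
#' @return A list of class `rule_table_report`: `observed` and `expected`
#'   matrices, `row_pass` logical per BMI class, `examples` data frame with
#'   observed vs expected categories, `pass` overall.
#' @export
validate_rule_table <- function(table, expected = published_marginals()) {
  stopifnot(inherits(table, "rule_table"))
  observed <- base::table(factor(table$bmi_class, levels = bmi_classes()),
                          factor(table$category, levels = broad_categories()))
  observed <- matrix(as.integer(observed), nrow = 4,
                     dimnames = list(bmi_classes(), broad_categories()))
  row_pass <- vapply(bmi_classes(), function(cls) {
    all(observed[cls, ] == expected[cls, ])
  }, logical(1))
  wex <- worked_examples()
  lookup <- rule_lookup(table)
  wex$observed <- vapply(seq_len(nrow(wex)), function(i) {
    bits <- as.integer(wex[i, scoff_items()])
    cls <- as.character(classify_bmi(wex$bmi[i]))
    unname(lookup[cell_key(pattern_key(bits), cls)])
  }, character(1))
  wex$pass <- wex$observed == wex$category
  structure(list(observed = observed, expected = expected,
                 row_pass = row_pass, examples = wex,
                 pass = all(row_pass) && all(wex$pass)),
            class = "rule_table_report")
}

#' @export
print.rule_table_report <- function(x, ...) {
  cat("Rule-table validation against published marginals\n\n")
  for (cls in rownames(x$observed)) {
    cat(sprintf("  %-11s observed %s | expected %s | %s\n", cls,
                paste(sprintf("%2d", x$observed[cls, ]), collapse = " "),
                paste(sprintf("%2d", x$expected[cls, ]), collapse = " "),
                if (x$row_pass[cls]) "pass" else "FAIL"))
  }
  cat(sprintf("  category totals: observed %s | expected %s\n",
              paste(colSums(x$observed), collapse = "/"),
              paste(colSums(x$expected), collapse = "/")))
  cat("\n  worked examples:\n")
  for (i in seq_len(nrow(x$examples))) {
    e <- x$examples[i, ]
    cat(sprintf("    pattern %s, BMI %4.1f -> %s (expected %s) %s\n",
                pattern_key(as.integer(e[scoff_items()])), e$bmi, e$observed,
                e$category, if (e$pass) "pass" else "FAIL"))
  }
  cat(sprintf("\n  overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("Rule table: 104 cells (26 eligible SCOFF patterns x 4 BMI classes)\n"))
  cat(sprintf("  provenance: %s\n", attr(x, "provenance")))
  tab <- table(factor(x$bmi_class, levels = bmi_classes()),
               factor(x$category, levels = broad_categories()))
  print(tab)
  invisible(x)
}

#' Classify a screen-positive response and BMI with a rule table
#'
#' Applies the decision rule: a response with fewer than two positive
#' answers is screen-negative and gets no category; otherwise the category
#' is the table cell for (answer pattern, BMI class).
#'
#' @param resp A [scoff_response()] or length-5 binary vector.
#' @param bmi BMI in kg/m^2.
#' @param table A `rule_table`; default [default_rule_table()].
#' @return A list of class `classification_result`: `status`
#'   ("screen_negative" or "classified"), `category` (`NA` when
#'   screen-negative), `pattern`, `bmi_class`, `score`.
#' @export
#' @examples
#' classify(scoff_response(one_stone = TRUE, fat = TRUE), 16.5)$category # "RD"
classify <- function(resp, bmi, table = default_rule_table()) {
  resp <- as_scoff_response(resp)
  bmi_class <- as.character(classify_bmi(bmi))
  score <- sum(resp)
  if (score < 2L) {
    res <- list(status = "screen_negative", category = NA_character_,
                pattern = as.integer(resp), bmi_class = bmi_class, score = score)
    return(structure(res, class = "classification_result"))
  }
  lookup <- rule_lookup(table)
  key <- cell_key(pattern_key(as.integer(resp)), bmi_class)
  category <- unname(lookup[key])
  if (is.na(category)) {
    stop(sprintf("rule table has no cell for %s", key), call. = FALSE)
  }
  structure(list(status = "classified", category = category,
                 pattern = as.integer(resp), bmi_class = bmi_class,
                 score = score),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  if (x$status == "screen_negative") {
    cat(sprintf("screen-negative (SCOFF score %d < 2); no category assigned\n",
                x$score))
  } else {
    cat(sprintf("pattern %s, %s BMI -> %s\n", pattern_key(x$pattern),
                x$bmi_class, x$category))
  }
  invisible(x)
}

#' Classify every row of a patient cohort
#'
#' Vectorised application of [classify()]: appends `scoff_score`,
#' `screen_positive`, `bmi_class` and `expali_category` (empty string for
#' screen-negative rows) to the cohort, preserving row order and all input
#' columns.
#'
#' @param records Validated cohort data frame (see [validate_cohort()]).
#' @param table A `rule_table`.
#' @return `records` with the four derived columns appended.
#' @export
classify_cohort <- function(records, table = default_rule_table()) {
  answers <- as.matrix(records[, scoff_columns()])
  score <- rowSums(answers)
  positive <- score >= 2
  cls <- as.character(classify_bmi(records$bmi))
  lookup <- rule_lookup(table)
  keys <- cell_key(apply(answers, 1, paste, collapse = ""), cls)
  category <- ifelse(positive, unname(lookup[keys]), "")
  records$scoff_score <- as.integer(score)
  records$screen_positive <- positive
  records$bmi_class <- cls
  records$expali_category <- category
  records
}
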