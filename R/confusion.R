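#' Construct a 4x4 confusion matrix
#'
#' Rows are the physician (gold standard) broad category, columns the
#' algorithm's category, both in (RD, BD, HD, OED) order.
#'
#' @param counts 4x4 matrix (or coercible) of nonnegative integer counts.
#' @return Object of class `confusion4`: an integer matrix with dimnames
#'   `physician` x `algorithm`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4))) {
    stop("counts must be a 4x4 matrix", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix is empty (n = 0)", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(physician = broad_categories(),
                           algorithm = broad_categories())
  structure(counts, class = c("confusion4", "matrix", "array"))
}

#' Agreement counts from the original validation cohort
#'
#' The published 4x4 agreement table between the senior physicians'
#' DSM-5-derived broad category (rows) and the algorithm's category
#' (columns) for the 206 SCOFF-positive patients of the original
#' validation study. Row totals 65/39/84/18, column totals 55/48/82/21.
#'
#' @return A `confusion4` matrix with n = 206.
#' @export
reference_confusion <- function() {
  confusion_matrix(rbind(c(50, 6, 3, 6),
                         c(4, 27, 7, 1),
                         c(0, 6, 67, 11),
                         c(1, 9, 5, 3)))
}

#' Tally a diagnosed cohort against a rule table
#'
#' Every record must carry a DSM-5 diagnosis and be screen-positive; the
#' cell (i, j) counts records whose physician category
#' ([map_dsm5_to_broad()]) is i and whose algorithm category
#' ([classify_cohort()]) is j.
#'
#' @param records Validated cohort data frame with `dsm5_diagnosis`.
#' @param table A `rule_table`.
#' @return A `confusion4` matrix.
#' @export
build_confusion <- function(records, table = default_rule_table()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (!"dsm5_diagnosis" %in% names(records)) {
    stop("records lack a dsm5_diagnosis column", call. = FALSE)
  }
  no_dx <- is.na(records$dsm5_diagnosis) | records$dsm5_diagnosis == ""
  if (any(no_dx)) {
    stop(sprintf("record(s) without diagnosis: %s",
                 paste(utils::head(records$id[no_dx], 5), collapse = ", ")),
         call. = FALSE)
  }
  classified <- classify_cohort(records, table)
  neg <- !classified$screen_positive
  if (any(neg)) {
    stop(sprintf("screen-negative record(s): %s",
                 paste(utils::head(records$id[neg], 5), collapse = ", ")),
         call. = FALSE)
  }
  truth <- map_dsm5_to_broad(records$dsm5_diagnosis)
  algo <- factor(classified$expali_category, levels = broad_categories())
  confusion_matrix(unclass(base::table(truth, algo)))
}

#' @export
print.confusion4 <- function(x, ...) {
  cat(sprintf("Physician x algorithm agreement, n = %d\n", sum(x)))
  m <- unclass(x)
  m <- cbind(m, total = rowSums(m))
  m <- rbind(m, total = colSums(m))
  print(m)
  invisible(x)
}

#' Write / read a confusion matrix as labelled CSV
#'
#' @param cm A `confusion4`.
#' @param path File path.
#' @return `path` (write) or a `confusion4` (read).
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(physician = broad_categories(), unclass(cm))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(df$physician, broad_categories())) {
    stop("confusion CSV must have physician rows RD, BD, HD, OED", call. = FALSE)
  }
  confusion_matrix(as.matrix(df[, broad_categories()]))
}
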