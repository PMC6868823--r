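#' SCOFF item names, in instrument order
#'
#' The five SCOFF items in their original order: Sick ("Do you make yourself
#' Sick because you feel uncomfortably full?"), Control ("Do you worry you
#' have lost Control over how much you eat?"), One stone ("Have you recently
#' lost more than One stone in a 3-month period?"), Fat ("Do you believe
#' yourself to be Fat when others say you are too thin?"), Food ("Would you
#' say that Food dominates your life?").
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' scoff_items()
scoff_items <- function() {
  c("sick", "control", "one_stone", "fat", "food")
}

#' Construct a SCOFF response
#'
#' Each item is a single yes/no answer. Accepted encodings: logical,
#' 0/1, "yes"/"no", "y"/"n", "true"/"false" (case-insensitive).
#'
#' @param sick,control,one_stone,fat,food Binary answers to the five items.
#' @return An object of class `scoff_response`: a named logical vector of
#'   length five in instrument order.
#' @export
#' @examples
#' scoff_response(one_stone = "yes", fat = "yes")
scoff_response <- function(sick = FALSE, control = FALSE, one_stone = FALSE,
                           fat = FALSE, food = FALSE) {
  raw <- list(sick = sick, control = control, one_stone = one_stone,
              fat = fat, food = food)
  ans <- vapply(scoff_items(), function(item) {
    parse_binary_answer(raw[[item]], item)
  }, logical(1))
  structure(ans, class = "scoff_response")
}

# Normalizes one binary answer; errors name the offending item.
parse_binary_answer <- function(x, item) {
  if (length(x) != 1 || is.na(x)) {
    stop(sprintf("SCOFF item '%s': answer is missing or not a single value", item),
         call. = FALSE)
  }
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (x %in% c(0, 1)) return(x == 1)
    stop(sprintf("SCOFF item '%s': numeric answer must be 0 or 1, got %s", item, x),
         call. = FALSE)
  }
  key <- tolower(trimws(as.character(x)))
  yes <- c("1", "yes", "y", "true", "t")
  no <- c("0", "no", "n", "false", "f")
  if (key %in% yes) return(TRUE)
  if (key %in% no) return(FALSE)
  stop(sprintf("SCOFF item '%s': cannot interpret answer '%s' as yes/no", item, x),
       call. = FALSE)
}

as_scoff_response <- function(x) {
  if (inherits(x, "scoff_response")) return(x)
  if (is.logical(x) && length(x) == 5) {
    return(do.call(scoff_response, as.list(x)))
  }
  if (is.numeric(x) && length(x) == 5) {
    return(do.call(scoff_response, as.list(x)))
  }
  stop("expected a scoff_response or a length-5 binary vector", call. = FALSE)
}

#' Score a SCOFF response
#'
#' The SCOFF score is the number of positive (yes) answers, 0 to 5.
#'
#' @param resp A [scoff_response()] or a length-5 binary vector in
#'   (sick, control, one_stone, fat, food) order.
#' @return Integer in 0..5.
#' @export
#' @examples
#' score_scoff(scoff_response(one_stone = TRUE, fat = TRUE)) # 2
score_scoff <- function(resp) {
  resp <- as_scoff_response(resp)
  sum(resp)
}

#' Is a SCOFF response a positive screen?
#'
#' A screen is positive when at least two of the five answers are yes.
#' Respondents scoring 0 or 1 are outside the scope of the classification
#' rule.
#'
#' @inheritParams score_scoff
#' @return `TRUE` iff the score is at least 2.
#' @export
#' @examples
#' is_screen_positive(scoff_response(sick = TRUE))               # FALSE
#' is_screen_positive(scoff_response(sick = TRUE, food = TRUE))  # TRUE
is_screen_positive <- function(resp) {
  score_scoff(resp) >= 2L
}

#' @export
print.scoff_response <- function(x, ...) {
  marks <- ifelse(x, "yes", "no")
  cat("SCOFF response:", paste(sprintf("%s=%s", names(x), marks), collapse = ", "),
      sprintf("(score %d, screen %s)\n", sum(x),
              if (sum(x) >= 2) "positive" else "negative"))
  invisible(x)
}
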