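#' Broad eating-disorder category labels
#'
#' The four broad categories: RD (restrictive disorders), BD (bulimic
#' disorders), HD (hyperphagic disorders), OED (other eating disorders).
#' Order is fixed to (RD, BD, HD, OED) everywhere in the package.
#'
#' @return Character vector of the four labels.
#' @export
broad_categories <- function() {
  c("RD", "BD", "HD", "OED")
}

#' DSM-5 diagnosis vocabulary
#'
#' The closed vocabulary of DSM-5 eating-disorder labels the package
#' recognises, each mapping to exactly one broad category.
#'
#' @return Character vector of ten diagnosis labels.
#' @export
dsm5_vocabulary <- function() {
  names(dsm5_broad_map())
}

# diagnosis -> broad category lookup; grouping:
#   RD: anorexia nervosa, restrictive food intake disorder, atypical AN
#   BD: bulimia nervosa (incl. low frequency/duration)
#   HD: binge eating disorder (incl. low frequency/duration)
#   OED: purging disorder, night eating syndrome, any other ED
dsm5_broad_map <- function() {
  c(anorexia_nervosa = "RD",
    restrictive_food_intake_disorder = "RD",
    atypical_anorexia_nervosa = "RD",
    bulimia_nervosa = "BD",
    bulimia_nervosa_low_freq = "BD",
    binge_eating_disorder = "HD",
    binge_eating_disorder_low_freq = "HD",
    purging_disorder = "OED",
    night_eating_syndrome = "OED",
    other_ed = "OED")
}

#' Map a DSM-5 diagnosis to its broad category
#'
#' Anorexia nervosa, restrictive food intake disorder and atypical anorexia
#' nervosa fold into RD; bulimia nervosa (typical or low-frequency) into BD;
#' binge eating disorder (typical or low-frequency) into HD; purging
#' disorder, night eating syndrome and any other eating disorder into OED.
#'
#' @param dx Character vector of labels from [dsm5_vocabulary()].
#' @return Factor with levels [broad_categories()].
#' @export
#' @examples
#' map_dsm5_to_broad(c("anorexia_nervosa", "night_eating_syndrome"))
map_dsm5_to_broad <- function(dx) {
  map <- dsm5_broad_map()
  dx <- as.character(dx)
  unknown <- setdiff(unique(dx[!is.na(dx)]), names(map))
  if (length(unknown) > 0) {
    stop(sprintf("unknown DSM-5 label(s): %s\nvocabulary: %s",
                 paste(unknown, collapse = ", "),
                 paste(names(map), collapse = ", ")),
         call. = FALSE)
  }
  factor(unname(map[dx]), levels = broad_categories())
}

#' DSM-5 members of each broad category
#'
#' @param cat One broad-category label.
#' @return Character vector of the DSM-5 labels folding into `cat`.
#' @export
dsm5_members <- function(cat) {
  cat <- match.arg(cat, broad_categories())
  map <- dsm5_broad_map()
  names(map)[map == cat]
}
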