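# Quality (modifier) vocabulary for EQ annotations.
#
# Phenotype profiles describe cell states with state qualities
# (present/absent plus configured extensions such as 'joined'); mechanism-
# change profiles describe macroscale changes with change qualities
# (up/moderately_up/down). Every quality carries exactly one polarity.

#' Core quality vocabulary
#'
#' Returns the modifier vocabulary as a tibble. The core set consists of
#' `present`, `absent`, `up`, `moderately_up` and `down`; `joined` ships as
#' a predeclared extension state quality (used in the epithelial example
#' profile for cell membranes). Additional extension qualities can be
#' registered with [add_quality()], each declaring its polarity and class.
#'
#' @return A tibble with columns
#'   * `quality` — token (single word; `moderately up` is stored as
#'     `moderately_up` for TSV friendliness),
#'   * `polarity` — `"positive"` or `"negative"`,
#'   * `class` — `"state"` (phenotype profiles) or `"change"`
#'     (mechanism-change profiles),
#'   * `core` — whether the quality belongs to the core set.
#' @export
default_qualities <- function() {
  tibble(
    quality  = c("present", "absent", "up", "moderately_up", "down", "joined"),
    polarity = c("positive", "negative", "positive", "positive", "negative",
                 "positive"),
    class    = c("state", "state", "change", "change", "change", "state"),
    core     = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Register an extension quality
#'
#' @param qualities A quality table as returned by [default_qualities()].
#' @param quality Token for the new quality.
#' @param polarity `"positive"` or `"negative"`.
#' @param class `"state"` or `"change"`.
#' @return The extended quality table.
#' @export
add_quality <- function(qualities, quality, polarity, class) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  class <- match.arg(class, c("state", "change"))
  if (quality %in% qualities$quality) {
    abort(sprintf("quality '%s' is already declared", quality))
  }
  bind_rows(qualities, tibble(quality = quality, polarity = polarity,
                              class = class, core = FALSE))
}

quality_polarity <- function(quality, qualities = default_qualities()) {
  idx <- match(quality, qualities$quality)
  if (anyNA(idx)) {
    abort(sprintf("unknown quality: %s",
                  paste(unique(quality[is.na(idx)]), collapse = ", ")))
  }
  qualities$polarity[idx]
}

#' Default quality-compatibility table
#'
#' Symmetric weights kappa(q1, q2) in [0, 1] used to weight term-similarity
#' contributions across quality pairs when scoring profiles. The default:
#' 1 on the diagonal; 0 for every cross-polarity pair (an upregulation can
#' never match a downregulation); 0.5 between `up` and `moderately_up`
#' (graded agreement); 0 for all remaining pairs, including extension
#' qualities against anything but themselves. Override by passing an edited
#' table wherever a `compat` argument is accepted.
#'
#' @param qualities Quality vocabulary (see [default_qualities()]).
#' @return A tibble with columns `q1`, `q2`, `kappa` covering every ordered
#'   pair of declared qualities (the table is symmetric).
#' @export
default_compatibility <- function(qualities = default_qualities()) {
  grid <- tidyr::expand_grid(q1 = qualities$quality, q2 = qualities$quality)
  pol <- stats::setNames(qualities$polarity, qualities$quality)
  grid |>
    mutate(kappa = dplyr::case_when(
      .data$q1 == .data$q2 ~ 1,
      pol[.data$q1] != pol[.data$q2] ~ 0,
      (.data$q1 == "up" & .data$q2 == "moderately_up") |
        (.data$q1 == "moderately_up" & .data$q2 == "up") ~ 0.5,
      TRUE ~ 0
    ))
}

#' Look up the compatibility weight of a quality pair
#'
#' @param q1,q2 Quality tokens known to the table.
#' @param compat Compatibility table (see [default_compatibility()]).
#' @return A single weight in [0, 1]; the lookup is symmetric.
#' @export
quality_compatibility <- function(q1, q2, compat = default_compatibility()) {
  hit <- compat$kappa[compat$q1 == q1 & compat$q2 == q2]
  if (length(hit) == 0) {
    abort(sprintf("quality pair (%s, %s) not in compatibility table", q1, q2))
  }
  hit[[1]]
}

# Fast lookup closure over the long-format table; errors on unknown pairs.
compat_fun <- function(compat) {
  key <- paste(compat$q1, compat$q2, sep = "\r")
  tab <- stats::setNames(compat$kappa, key)
  function(q1, q2) {
    v <- tab[paste(q1, q2, sep = "\r")]
    if (anyNA(v)) abort("quality pair missing from compatibility table")
    unname(v)
  }
}
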