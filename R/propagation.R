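# Polarity-aware annotation propagation.
#
# Propagation makes the annotations that are logically implied by asserted
# ones explicit. Under all-some has_part semantics the direction is the
# reverse of the anatomical part_of case: a positive annotation of a whole
# (the cell has a tight junction; the TJ network is starting up) entails
# positive annotations of all its necessary parts, and of its superclasses
# via is_a. 'absent' flows contrapositively from parts to wholes: a whole
# cannot be present if a necessary part is missing. 'down' is not logically
# entailed in either direction (a part may serve other wholes), so in sound
# mode it stays where it was asserted; heuristic mode propagates it
# whole-to-part symmetrically with 'up' for users who want that.

propagation_modes <- c("sound", "heuristic")

# Scope direction for one quality under one mode: "out" = positive scope,
# "in" = negative scope, "self" = no propagation.
propagation_direction <- function(quality, mode, qualities) {
  q <- qualities[match(quality, qualities$quality), ]
  if (anyNA(q$quality)) {
    abort(sprintf("unknown quality: %s", quality))
  }
  dplyr::case_when(
    q$polarity == "positive" ~ "out",
    q$class == "state" ~ "in",              # absent and negative state extensions
    mode == "heuristic" ~ "out",            # heuristic: down flows whole->part
    TRUE ~ "self"                           # sound: down stays put
  )
}

#' Propagate a single EQ annotation
#'
#' Expands one entity/quality pair into the full set of annotations it
#' entails over the ontology. Positive qualities cover the entity's
#' [positive_scope()]; `absent` (and negative state extensions) covers the
#' [negative_scope()]; `down` yields only itself in sound mode and the
#' positive scope in heuristic mode. The result always contains the input
#' annotation.
#'
#' @param entity_id A term id of `ontology`.
#' @param quality A declared quality token.
#' @param ontology A valid [ceq_ontology()].
#' @param mode `"sound"` (default; only logically entailed annotations) or
#'   `"heuristic"`.
#' @param qualities Quality vocabulary.
#' @return A tibble with columns `entity_id`, `quality`.
#' @export
propagate_annotation <- function(entity_id, quality, ontology,
                                 mode = c("sound", "heuristic"),
                                 qualities = default_qualities()) {
  mode <- match.arg(mode)
  assert_known_term(ontology, entity_id)
  dir <- propagation_direction(quality, mode, qualities)
  targets <- switch(dir,
                    out = positive_scope(ontology, entity_id),
                    `in` = negative_scope(ontology, entity_id),
                    self = entity_id)
  tibble(entity_id = targets, quality = quality)
}

#' Propagate annotation profiles over an ontology
#'
#' Applies [propagate_annotation()] to every row of a corpus and returns
#' the union per profile, with a logical `asserted` column separating
#' directly curated rows (`TRUE`) from inferred ones. Kind and timestamp
#' are preserved; each propagated profile is a superset of its input, and
#' propagation is idempotent.
#'
#' If inference lands an annotation of one polarity on an entity that the
#' profile directly asserts with the other polarity, the asserted
#' annotation wins: the conflicting inferred rows are dropped and recorded
#' in the `"conflicts"` attribute of the result (see
#' [propagation_conflicts()]). Curated data outranks inference.
#'
#' @param profiles A corpus tibble, valid against `ontology`.
#' @param ontology A valid [ceq_ontology()].
#' @param mode `"sound"` or `"heuristic"`; see [propagate_annotation()].
#' @param qualities Quality vocabulary.
#' @return The propagated corpus tibble (same profile ids) with an
#'   `asserted` column; conflicts, if any, in `attr(, "conflicts")`.
#' @export
propagate_profiles <- function(profiles, ontology,
                               mode = c("sound", "heuristic"),
                               qualities = default_qualities()) {
  mode <- match.arg(mode)
  profiles <- check_profile_frame(profiles)
  assert_valid_profiles(profiles, ontology, qualities)
  if ("asserted" %in% names(profiles)) {
    # Re-propagating: keep only the asserted layer as input.
    profiles <- profiles |> filter(.data$asserted) |> select(-"asserted")
  }
  if (nrow(profiles) == 0) {
    out <- profiles |> mutate(asserted = logical(0))
    attr(out, "conflicts") <- conflict_frame()
    return(out)
  }

  scopes <- list(out = scope_table(ontology, "out"),
                 `in` = scope_table(ontology, "in"))
  asserted <- profiles |> distinct()
  expanded <- asserted |>
    mutate(.dir = propagation_direction(.data$quality, .env$mode, qualities)) |>
    mutate(.targets = purrr::pmap(
      list(.data$entity_id, .data$.dir),
      function(e, d) if (d == "self") e else scopes[[d]][[e]])) |>
    select(-"entity_id", -".dir") |>
    tidyr::unnest_longer(".targets") |>
    rename(entity_id = ".targets") |>
    select(all_of(profile_cols)) |>
    distinct()

  inferred <- expanded |>
    anti_join(asserted, by = profile_cols) |>
    mutate(asserted = FALSE)
  combined <- bind_rows(asserted |> mutate(asserted = TRUE), inferred)

  # Conflict resolution: inferred polarity against a directly asserted
  # opposite polarity on the same entity -> drop the inferred rows.
  pol <- stats::setNames(qualities$polarity, qualities$quality)
  combined <- combined |> mutate(.pol = unname(pol[.data$quality]))
  asserted_pol <- combined |>
    filter(.data$asserted) |>
    distinct(.data$profile_id, .data$entity_id, .data$.pol) |>
    rename(.apol = ".pol")
  flagged <- combined |>
    left_join(asserted_pol, by = c("profile_id", "entity_id"),
              relationship = "many-to-many") |>
    mutate(.drop = !.data$asserted & !is.na(.data$.apol) &
             .data$.apol != .data$.pol) |>
    group_by(across(all_of(c(profile_cols, "asserted", ".pol")))) |>
    summarise(.drop = any(.data$.drop), .groups = "drop")
  conflicts <- flagged |>
    filter(.data$.drop) |>
    select(all_of(c("profile_id", "entity_id", "quality"))) |>
    arrange(.data$profile_id, .data$entity_id)
  out <- flagged |>
    filter(!.data$.drop) |>
    select(all_of(c(profile_cols, "asserted"))) |>
    arrange(.data$profile_id, .data$entity_id, .data$quality,
            dplyr::desc(.data$asserted))
  attr(out, "conflicts") <- conflicts
  out
}

conflict_frame <- function() {
  tibble(profile_id = character(), entity_id = character(),
         quality = character())
}

#' Conflicts recorded by the last propagation
#'
#' @param propagated The result of [propagate_profiles()].
#' @return A tibble of inferred annotations that were dropped because a
#'   directly asserted annotation of the opposite polarity exists on the
#'   same entity of the same profile.
#' @export
propagation_conflicts <- function(propagated) {
  attr(propagated, "conflicts") %||% conflict_frame()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
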