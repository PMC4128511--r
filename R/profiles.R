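# EQ annotation profiles and their TSV serialization.
#
# A corpus of profiles is a plain tibble, one annotation per row:
#   profile_id   chr   profile the row belongs to
#   kind         chr   "phenotype" or "mechanism-change"
#   timestamp_h  dbl   hours after intervention; NA = unset ("." on disk)
#   entity_id    chr   term id in the profile's ontology
#   quality      chr   modifier token (see default_qualities())
# A single profile is just the subset of rows sharing one profile_id, so
# every operation composes with dplyr verbs.

profile_cols <- c("profile_id", "kind", "timestamp_h", "entity_id", "quality")
profile_kinds <- c("phenotype", "mechanism-change")

#' Assemble an annotation-profile tibble
#'
#' Convenience constructor for a single profile in the corpus layout used
#' throughout the package (see [read_profiles_tsv()] for the on-disk form).
#'
#' @param profile_id Profile identifier.
#' @param kind `"phenotype"` (cell state described with state qualities) or
#'   `"mechanism-change"` (macroscale change described with up/down
#'   qualities).
#' @param entity_id Character vector of term ids.
#' @param quality Character vector of quality tokens (recycled if length 1).
#' @param timestamp_h Hours after intervention; `NA` when unset (e.g. the
#'   state before an intervention).
#' @return A corpus tibble with one row per annotation.
#' @examples
#' annotation_profile(
#'   "epithelial", "phenotype",
#'   entity_id = c("CPH:0008", "CPH:0009"),
#'   quality = "present"
#' )
#' @export
annotation_profile <- function(profile_id, kind, entity_id, quality,
                               timestamp_h = NA_real_) {
  kind <- match.arg(kind, profile_kinds)
  tibble(profile_id = profile_id, kind = kind,
         timestamp_h = as.numeric(timestamp_h),
         entity_id = as.character(entity_id),
         quality = as.character(quality))
}

check_profile_frame <- function(profiles) {
  profiles <- as_tibble(profiles)
  missing <- setdiff(profile_cols, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("profile table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  profiles
}

#' Validate annotation profiles against an ontology
#'
#' Checks every profile in the corpus and reports violations as a tibble
#' (empty iff all profiles are valid). Checked: profile ids non-empty;
#' `kind` drawn from phenotype/mechanism-change and constant within a
#' profile; entity ids resolving in `ontology`; qualities declared in
#' `qualities`; quality class matching the profile kind (state qualities in
#' phenotype profiles, change qualities in mechanism-change profiles); no
#' entity annotated with both a positive and a negative quality in one
#' profile; timestamps non-negative and constant within a profile.
#' Duplicate rows (same entity, same quality) are legal — readers merge
#' them silently.
#'
#' @param profiles A corpus tibble (see [annotation_profile()]).
#' @param ontology The [ceq_ontology()] the entities refer to.
#' @param qualities Quality vocabulary, see [default_qualities()].
#' @return A tibble with columns `profile_id`, `rule`, `item`, `message`.
#' @export
validate_profiles <- function(profiles, ontology,
                              qualities = default_qualities()) {
  profiles <- check_profile_frame(profiles)
  out <- list(tibble(profile_id = character(), rule = character(),
                     item = character(), message = character()))
  viol <- function(pid, rule, item, message) {
    tibble(profile_id = pid, rule = rule, item = item, message = message)
  }

  bad_kind <- profiles |> filter(!.data$kind %in% profile_kinds)
  if (nrow(bad_kind) > 0) {
    out <- c(out, list(viol(unique(bad_kind$profile_id), "unknown_kind",
                            unique(bad_kind$kind),
                            "kind must be phenotype or mechanism-change")))
  }
  mixed <- profiles |>
    group_by(.data$profile_id) |>
    summarise(nk = n_distinct(.data$kind),
              nt = n_distinct(.data$timestamp_h), .groups = "drop")
  mk <- mixed |> filter(.data$nk > 1)
  if (nrow(mk) > 0) {
    out <- c(out, list(viol(mk$profile_id, "mixed_kind", mk$profile_id,
                            "profile mixes phenotype and mechanism-change rows")))
  }
  mt <- mixed |> filter(.data$nt > 1)
  if (nrow(mt) > 0) {
    out <- c(out, list(viol(mt$profile_id, "mixed_timestamp", mt$profile_id,
                            "profile rows carry different timestamps")))
  }
  neg_t <- profiles |> filter(!is.na(.data$timestamp_h), .data$timestamp_h < 0)
  if (nrow(neg_t) > 0) {
    out <- c(out, list(viol(unique(neg_t$profile_id), "negative_timestamp",
                            unique(neg_t$profile_id),
                            "timestamp_h must be non-negative")))
  }
  unknown_e <- profiles |> filter(!.data$entity_id %in% ontology$terms$id)
  if (nrow(unknown_e) > 0) {
    u <- unknown_e |> distinct(.data$profile_id, .data$entity_id)
    out <- c(out, list(viol(u$profile_id, "unknown_entity", u$entity_id,
                            "entity id does not resolve in the ontology")))
  }
  unknown_q <- profiles |> filter(!.data$quality %in% qualities$quality)
  if (nrow(unknown_q) > 0) {
    u <- unknown_q |> distinct(.data$profile_id, .data$quality)
    out <- c(out, list(viol(u$profile_id, "unknown_quality", u$quality,
                            "quality is not declared in the vocabulary")))
  }
  known <- profiles |>
    filter(.data$quality %in% qualities$quality,
           .data$kind %in% profile_kinds) |>
    left_join(qualities, by = "quality")
  mism <- known |>
    filter((.data$kind == "phenotype" & .data$class != "state") |
             (.data$kind == "mechanism-change" & .data$class != "change")) |>
    distinct(.data$profile_id, .data$entity_id, .data$quality)
  if (nrow(mism) > 0) {
    out <- c(out, list(viol(mism$profile_id, "kind_quality_mismatch",
                            paste(mism$entity_id, mism$quality),
                            "quality class does not fit the profile kind")))
  }
  confl <- known |>
    group_by(.data$profile_id, .data$entity_id) |>
    summarise(np = n_distinct(.data$polarity), .groups = "drop") |>
    filter(.data$np > 1)
  if (nrow(confl) > 0) {
    out <- c(out, list(viol(confl$profile_id, "polarity_conflict",
                            confl$entity_id,
                            "entity carries both a positive and a negative quality")))
  }
  bind_rows(out)
}

assert_valid_profiles <- function(profiles, ontology,
                                  qualities = default_qualities(),
                                  context = "profiles") {
  rep <- validate_profiles(profiles, ontology, qualities)
  if (nrow(rep) > 0) {
    abort(c(sprintf("%s are not valid", context),
            stats::setNames(
              paste(rep$profile_id, rep$rule, rep$item, sep = ": "),
              rep("x", nrow(rep)))))
  }
  invisible(profiles)
}

#' Read annotation profiles from TSV
#'
#' Reads the tab-separated profile layout: UTF-8, header
#' `profile_id  kind  timestamp_h  entity_id  quality`, one annotation per
#' row, the timestamp repeated on every row of a profile and `"."` for
#' unset. Rows are grouped by `profile_id`; exact duplicate annotations are
#' merged silently; the result is validated against `ontology` and reading
#' fails (with the offending rows) if any profile is invalid.
#'
#' @param path File to read.
#' @param ontology The [ceq_ontology()] the entities must resolve in.
#' @param qualities Quality vocabulary.
#' @return A corpus tibble (see [annotation_profile()]).
#' @export
read_profiles_tsv <- function(path, ontology, qualities = default_qualities()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing <- setdiff(profile_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("profile TSV lacks columns: ", paste(missing, collapse = ", ")))
  }
  ts <- raw$timestamp_h
  parsed <- suppressWarnings(as.numeric(ifelse(ts == ".", NA, ts)))
  bad <- which(!is.na(ts) & ts != "." & is.na(parsed))
  if (length(bad) > 0) {
    abort(sprintf("unparseable timestamp_h on data row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  profiles <- raw |>
    mutate(timestamp_h = parsed) |>
    select(all_of(profile_cols)) |>
    distinct()
  assert_valid_profiles(profiles, ontology, qualities,
                        context = sprintf("profiles in '%s'", path))
  profiles
}

#' Write annotation profiles to TSV
#'
#' Deterministic serialization of a corpus: rows sorted by `profile_id`
#' then `entity_id` (then `quality`), unset timestamps written as `"."`,
#' LF line endings. `write_profiles_tsv()` followed by
#' [read_profiles_tsv()] reproduces the corpus exactly, and two writes of
#' the same corpus are byte-identical. An `asserted` logical column (added
#' by [propagate_profiles()]) is preserved as a trailing 1/0 column.
#'
#' @param profiles A corpus tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  profiles <- check_profile_frame(profiles)
  keep <- c(profile_cols, intersect("asserted", names(profiles)))
  out <- profiles |>
    select(all_of(keep)) |>
    distinct() |>
    arrange(.data$profile_id, .data$entity_id, .data$quality) |>
    mutate(timestamp_h = ifelse(is.na(.data$timestamp_h), ".",
                                format(.data$timestamp_h, trim = TRUE,
                                       scientific = FALSE)))
  if ("asserted" %in% names(out)) {
    out$asserted <- as.integer(out$asserted)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Split a corpus into a named list of per-profile tibbles (stable order).
split_profiles <- function(profiles) {
  profiles <- check_profile_frame(profiles)
  ids <- sort(unique(profiles$profile_id))
  stats::setNames(lapply(ids, function(i) {
    profiles |> filter(.data$profile_id == i)
  }), ids)
}

profile_timestamp <- function(profile) {
  if (nrow(profile) == 0) return(NA_real_)
  profile$timestamp_h[[1]]
}
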