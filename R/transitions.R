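# Deriving mechanism-change profiles from time-stamped phenotype profiles.
#
# A cell transition is an occurrent: it cannot be read off a single
# phenotype snapshot, but it can be derived by qualitative differential
# analysis of two snapshots. The link between the two ontologies is an
# explicit mechanism map; it is curated input, never inferred, because the
# interconnections between cell parts and the mechanisms they participate
# in must be explicitly established.
#
# Rules are strictly qualitative and open-world: an entity not mentioned
# in a profile is unknown (not absent), and only an explicit
# absent <-> present flip fires a rule.

#' Construct a mechanism map
#'
#' Two rule families connect the phenotype ontology to the mechanism
#' ontology:
#' * marker rules — one phenotype structure/cell term whose appearance
#'   (disappearance) signals the start-up (shutdown) of a mechanism
#'   network or event;
#' * participant rules — a molecular-interaction term with its set of at
#'   least two molecular participants; the interaction starts up when the
#'   participants become jointly present.
#'
#' @param rule_type Character vector, `"marker"` or `"participant"`.
#' @param mechanism_id Mechanism-ontology term id per rule.
#' @param phenotype_ids List of character vectors (or a single character
#'   vector for all-marker maps): the phenotype-ontology ids per rule.
#' @return A `ceq_mechanism_map` tibble with a list-column `phenotype_ids`.
#' @export
mechanism_map <- function(rule_type, mechanism_id, phenotype_ids) {
  if (is.character(phenotype_ids)) phenotype_ids <- as.list(phenotype_ids)
  out <- tibble(rule_type = as.character(rule_type),
                mechanism_id = as.character(mechanism_id),
                phenotype_ids = lapply(phenotype_ids, as.character))
  class(out) <- c("ceq_mechanism_map", class(out))
  out
}

#' Validate a mechanism map against the two ontologies
#'
#' Reports (as data) unknown rule types, dangling phenotype or mechanism
#' ids, marker rules not targeting a mechanism-network or ultrastructural-
#' event term, participant rules not sourcing a molecular-interaction
#' term, participant rules with fewer than two participants, and
#' participant entries that are not molecule terms.
#'
#' @param map A [mechanism_map()].
#' @param onto_phen The phenotype [ceq_ontology()].
#' @param onto_mech The mechanism [ceq_ontology()].
#' @return A tibble with columns `rule`, `item`, `message`; empty iff valid.
#' @export
validate_mechanism_map <- function(map, onto_phen, onto_mech) {
  stopifnot(inherits(onto_phen, "ceq_ontology"),
            inherits(onto_mech, "ceq_ontology"))
  if (onto_phen$kind != "phenotype" || onto_mech$kind != "mechanism") {
    abort("expected a phenotype ontology and a mechanism ontology, in that order")
  }
  out <- list(empty_report())
  mcat <- stats::setNames(onto_mech$terms$category, onto_mech$terms$id)
  pcat <- stats::setNames(onto_phen$terms$category, onto_phen$terms$id)
  for (i in seq_len(nrow(map))) {
    rt <- map$rule_type[[i]]
    mid <- map$mechanism_id[[i]]
    pids <- map$phenotype_ids[[i]]
    tag <- sprintf("rule %d (%s -> %s)", i, paste(pids, collapse = ","), mid)
    if (!rt %in% c("marker", "participant")) {
      out <- c(out, list(violation("unknown_rule_type", tag,
                                   sprintf("rule_type '%s'", rt))))
      next
    }
    if (!mid %in% onto_mech$terms$id) {
      out <- c(out, list(violation("dangling_mechanism_id", tag,
                                   "mechanism id not in the mechanism ontology")))
    }
    missing <- pids[!pids %in% onto_phen$terms$id]
    if (length(missing) > 0) {
      out <- c(out, list(violation("dangling_phenotype_id", tag,
                                   paste("unknown:", paste(missing, collapse = ",")))))
    }
    if (rt == "marker") {
      if (length(pids) != 1) {
        out <- c(out, list(violation("marker_arity", tag,
                                     "marker rules take exactly one phenotype term")))
      }
      if (mid %in% names(mcat) &&
          !mcat[[mid]] %in% c("mechanism-network", "ultrastructural-event")) {
        out <- c(out, list(violation(
          "marker_target_category", tag,
          "marker rules must target a mechanism-network or ultrastructural-event term")))
      }
    } else {
      if (length(pids) < 2) {
        out <- c(out, list(violation("participant_arity", tag,
                                     "participant rules need at least two molecules")))
      }
      if (mid %in% names(mcat) && mcat[[mid]] != "molecular-interaction") {
        out <- c(out, list(violation(
          "participant_source_category", tag,
          "participant rules must source a molecular-interaction term")))
      }
      nonmol <- pids[pids %in% names(pcat) & pcat[pids] != "molecule"]
      if (length(nonmol) > 0) {
        out <- c(out, list(violation(
          "participant_not_molecule", tag,
          paste("not molecule terms:", paste(nonmol, collapse = ",")))))
      }
    }
  }
  bind_rows(out)
}

#' Read / write a mechanism map as TSV
#'
#' Layout: header `rule_type	mechanism_id	phenotype_ids`, one rule per
#' row, participants comma-separated. Writing is deterministic (rows
#' sorted by rule_type, mechanism_id) and round-trips with reading.
#'
#' @param path File to read or write.
#' @return `read_mechanism_map()`: a [mechanism_map()];
#'   `write_mechanism_map()`: `path`, invisibly.
#' @export
read_mechanism_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("rule_type", "mechanism_id", "phenotype_ids")
  if (!all(need %in% names(raw))) {
    abort(paste0("mechanism map TSV lacks columns: ",
                 paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  mechanism_map(raw$rule_type, raw$mechanism_id,
                strsplit(raw$phenotype_ids, ","))
}

#' @rdname read_mechanism_map
#' @param map A [mechanism_map()].
#' @export
write_mechanism_map <- function(map, path) {
  out <- tibble(rule_type = map$rule_type,
                mechanism_id = map$mechanism_id,
                phenotype_ids = map_chr(map$phenotype_ids,
                                        ~ paste(sort(.x), collapse = ","))) |>
    arrange(.data$rule_type, .data$mechanism_id, .data$phenotype_ids)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# present/absent/unknown status of entities in one phenotype profile.
presence_status <- function(profile, qualities) {
  pol <- stats::setNames(qualities$polarity, qualities$quality)
  profile |>
    mutate(.status = ifelse(unname(pol[.data$quality]) == "positive",
                            "present", "absent")) |>
    distinct(.data$entity_id, .data$.status)
}

status_of <- function(status, entity) {
  hit <- status$.status[status$entity_id == entity]
  if (length(hit) == 0) "unknown" else hit[[1]]
}

#' Derive a mechanism-change profile from two phenotype snapshots
#'
#' Qualitative differential analysis of two phenotype profiles of one cell
#' (`a` earlier, `b` later) under a [mechanism_map()]:
#' * marker rule `s -> m`: `s` absent in `a` and present in `b` yields
#'   `(m, up)`; present in `a` and absent in `b` yields `(m, down)`;
#' * participant rule `i <- M`: all of `M` present in `b` and at least one
#'   explicitly absent in `a` yields `(i, up)`; all present in `a` and at
#'   least one absent in `b` yields `(i, down)`.
#'
#' Entities a profile does not mention are unknown and never fire a rule;
#' a quality change within one polarity (e.g. `present` to `joined`) does
#' not fire either. The derived profile inherits its start and end time
#' from the timestamps of `a` and `b`.
#'
#' @param profiles Corpus tibble holding both snapshots (kind phenotype).
#' @param from,to Profile ids of the earlier and later snapshot;
#'   `from`'s timestamp must be unset or strictly smaller than `to`'s.
#' @param map A [mechanism_map()], valid against the two ontologies.
#' @param onto_phen,onto_mech The phenotype and mechanism ontologies.
#' @param qualities Quality vocabulary.
#' @param id Profile id for the derived profile; default
#'   `"<from>_to_<to>"`.
#' @return A corpus tibble of kind `"mechanism-change"` with extra columns
#'   `start_h` and `end_h` (class `ceq_transition`); zero rows when the
#'   snapshots do not differ on any rule.
#' @export
derive_transition <- function(profiles, from, to, map, onto_phen, onto_mech,
                              qualities = default_qualities(),
                              id = paste0(from, "_to_", to)) {
  profiles <- check_profile_frame(profiles)
  a <- profiles |> filter(.data$profile_id == from)
  b <- profiles |> filter(.data$profile_id == to)
  if (nrow(a) == 0) abort(sprintf("profile '%s' not found", from))
  if (nrow(b) == 0) abort(sprintf("profile '%s' not found", to))
  if (!all(c(a$kind, b$kind) == "phenotype")) {
    abort("transitions are derived from phenotype profiles only")
  }
  rep <- validate_mechanism_map(map, onto_phen, onto_mech)
  if (nrow(rep) > 0) {
    abort(c("mechanism map is not valid",
            stats::setNames(paste(rep$rule, rep$item, sep = ": "),
                            rep("x", nrow(rep)))))
  }
  assert_valid_profiles(bind_rows(a, b), onto_phen, qualities)
  start_h <- profile_timestamp(a)
  end_h <- profile_timestamp(b)
  if (!is.na(start_h)) {
    if (is.na(end_h) || end_h <= start_h) {
      abort("profile timestamps must increase from `from` to `to`")
    }
  }

  sa <- presence_status(a, qualities)
  sb <- presence_status(b, qualities)
  rows <- list()
  for (i in seq_len(nrow(map))) {
    mid <- map$mechanism_id[[i]]
    pids <- map$phenotype_ids[[i]]
    if (map$rule_type[[i]] == "marker") {
      st_a <- status_of(sa, pids)
      st_b <- status_of(sb, pids)
      if (st_a == "absent" && st_b == "present") {
        rows <- c(rows, list(c(mid, "up")))
      } else if (st_a == "present" && st_b == "absent") {
        rows <- c(rows, list(c(mid, "down")))
      }
    } else {
      st_a <- vapply(pids, function(p) status_of(sa, p), "")
      st_b <- vapply(pids, function(p) status_of(sb, p), "")
      if (all(st_b == "present") && any(st_a == "absent")) {
        rows <- c(rows, list(c(mid, "up")))
      } else if (all(st_a == "present") && any(st_b == "absent")) {
        rows <- c(rows, list(c(mid, "down")))
      }
    }
  }
  ann <- if (length(rows) == 0) {
    tibble(entity_id = character(), quality = character())
  } else {
    tibble(entity_id = map_chr(rows, 1), quality = map_chr(rows, 2)) |>
      distinct() |>
      arrange(.data$entity_id)
  }
  out <- tibble(profile_id = rep(id, nrow(ann)),
                kind = rep("mechanism-change", nrow(ann)),
                timestamp_h = rep(end_h, nrow(ann)),
                entity_id = ann$entity_id,
                quality = ann$quality,
                start_h = rep(start_h, nrow(ann)),
                end_h = rep(end_h, nrow(ann)))
  attr(out, "start_h") <- start_h
  attr(out, "end_h") <- end_h
  class(out) <- c("ceq_transition", class(out))
  out
}

#' Derive the transition chain of a time-stamped profile series
#'
#' Orders the phenotype profiles of a series by timestamp (an unset
#' timestamp sorts first: the state before the intervention) and applies
#' [derive_transition()] to each consecutive pair, so `n` snapshots yield
#' `n - 1` mechanism-change profiles with chained start/end times.
#'
#' @param profiles Corpus tibble: the series' phenotype profiles, with
#'   strictly increasing timestamps (at most the first unset).
#' @inheritParams derive_transition
#' @return A corpus tibble stacking the derived transitions (columns as in
#'   [derive_transition()]).
#' @export
series_transitions <- function(profiles, map, onto_phen, onto_mech,
                               qualities = default_qualities()) {
  profiles <- check_profile_frame(profiles)
  meta <- profiles |>
    distinct(.data$profile_id, .data$timestamp_h) |>
    arrange(!is.na(.data$timestamp_h) * 1, .data$timestamp_h)
  if (nrow(meta) < 2) abort("a series needs at least two profiles")
  if (sum(is.na(meta$timestamp_h)) > 1) {
    abort("at most one profile (the first) may have an unset timestamp")
  }
  ts <- meta$timestamp_h[!is.na(meta$timestamp_h)]
  if (any(diff(ts) <= 0)) {
    abort("series timestamps must be strictly increasing")
  }
  out <- vector("list", nrow(meta) - 1)
  for (i in seq_len(nrow(meta) - 1)) {
    out[[i]] <- derive_transition(profiles,
                                  from = meta$profile_id[[i]],
                                  to = meta$profile_id[[i + 1]],
                                  map, onto_phen, onto_mech, qualities)
  }
  bind_rows(lapply(out, as_tibble))
}
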