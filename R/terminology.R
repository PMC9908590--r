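#' Unified three-level annotation terminology
#'
#' The annotation vocabulary is a forest with three levels: diagnostic
#' *classes* (e.g. adenocarcinoma, adenoma, normal) at the root, diagnostic
#' *subtypes* below them (e.g. "Poorly differentiated adenocarcinoma"), and
#' morphological *reason* labels below the subtypes (e.g. "Cribriform
#' structure"). A `terminology_tree` wraps a tibble with one row per entry
#' and validates the forest structure on construction.
#'
#' @param entries A data frame with columns `id`, `level` (one of `"class"`,
#'   `"subtype"`, `"reason"`), `parent_id` (`NA` for classes), `name`, and
#'   `order` (integer display rank).
#' @param version Version string carried through serialization.
#' @return A `terminology_tree`: a tibble with class and version attributes.
#' @examples
#' tree <- terminology_tree(tibble::tibble(
#'   id = c("c1", "s1", "r1"),
#'   level = c("class", "subtype", "reason"),
#'   parent_id = c(NA, "c1", "s1"),
#'   name = c("Adenoma", "Low-grade adenoma", "Tubular structure"),
#'   order = 1:3
#' ))
#' terminology_counts(tree)
#' @export
terminology_tree <- function(entries, version = "1.0") {
  entries <- as_tibble(entries)
  req <- c("id", "level", "parent_id", "name", "order")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0) {
    wsianno_abort("STRUCTURE_ERROR", paste0(
      "terminology table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(entries) == 0) {
    wsianno_abort("EMPTY_TERMINOLOGY", "terminology table has no entries")
  }
  entries <- entries %>%
    mutate(
      id = as.character(.data$id),
      level = as.character(.data$level),
      parent_id = as.character(.data$parent_id),
      name = as.character(.data$name),
      order = as.integer(.data$order)
    ) %>%
    arrange(.data$level, .data$order, .data$id)

  if (anyDuplicated(entries$id)) {
    wsianno_abort("STRUCTURE_ERROR", paste0(
      "duplicate terminology id(s): ",
      paste(unique(entries$id[duplicated(entries$id)]), collapse = ", ")
    ))
  }
  bad_level <- setdiff(unique(entries$level), c("class", "subtype", "reason"))
  if (length(bad_level) > 0) {
    wsianno_abort("STRUCTURE_ERROR",
      paste0("unknown terminology level(s): ", paste(bad_level, collapse = ", ")))
  }

  # parent linkage: class has none; subtype -> class; reason -> subtype
  idx <- setNames(entries$level, entries$id)
  for (lvl in c("class", "subtype", "reason")) {
    rows <- entries[entries$level == lvl, ]
    if (lvl == "class") {
      if (any(!is.na(rows$parent_id))) {
        wsianno_abort("STRUCTURE_ERROR", "class entries must have no parent")
      }
      next
    }
    want <- if (lvl == "subtype") "class" else "subtype"
    if (any(is.na(rows$parent_id))) {
      wsianno_abort("STRUCTURE_ERROR", paste0(lvl, " entries must have a parent"))
    }
    orphan <- rows$parent_id[!(rows$parent_id %in% entries$id)]
    if (length(orphan) > 0) {
      wsianno_abort("STRUCTURE_ERROR",
        paste0("parent id(s) not present in table: ", paste(unique(orphan), collapse = ", ")))
    }
    wrong <- rows$parent_id[idx[rows$parent_id] != want]
    if (length(wrong) > 0) {
      wsianno_abort("STRUCTURE_ERROR", paste0(
        lvl, " entries must have a ", want, " parent; offending parent(s): ",
        paste(unique(wrong), collapse = ", ")
      ))
    }
  }
  # ambiguity: (level, name) must identify a single entry
  dup_names <- entries %>%
    count(.data$level, .data$name) %>%
    filter(.data$n > 1)
  if (nrow(dup_names) > 0) {
    wsianno_abort("STRUCTURE_ERROR", paste0(
      "ambiguous (level, name) pair(s): ",
      paste(paste0(dup_names$level, "/", dup_names$name), collapse = "; ")
    ))
  }
  structure(entries, class = c("terminology_tree", class(entries)), version = version)
}

#' @export
print.terminology_tree <- function(x, ...) {
  cnt <- terminology_counts(x)
  cat(sprintf(
    "<terminology_tree v%s: %d classes, %d subtypes, %d reason labels>\n",
    attr(x, "version"), cnt$totals$n_classes, cnt$totals$n_subtypes,
    cnt$totals$n_reason_labels
  ))
  NextMethod()
}

#' Count subtypes and reason labels per class
#'
#' @param tree A [terminology_tree()].
#' @return A list with `per_class`, a tibble (`class_id`, `class_name`,
#'   `n_subtypes`, `n_reason_labels`), and `totals`, a one-row tibble of
#'   overall counts. Totals always equal the per-class sums.
#' @export
terminology_counts <- function(tree) {
  stopifnot(inherits(tree, "terminology_tree"))
  tb <- as_tibble(tree)
  classes <- tb %>% filter(.data$level == "class")
  subtypes <- tb %>% filter(.data$level == "subtype")
  reasons <- tb %>% filter(.data$level == "reason")
  reason_class <- setNames(subtypes$parent_id, subtypes$id)[reasons$parent_id]
  per_class <- tibble(
    class_id = classes$id,
    class_name = classes$name,
    n_subtypes = map_int(classes$id, ~ sum(subtypes$parent_id == .x)),
    n_reason_labels = map_int(classes$id, ~ sum(reason_class == .x))
  )
  list(
    per_class = per_class,
    totals = tibble(
      n_classes = nrow(classes),
      n_subtypes = sum(per_class$n_subtypes),
      n_reason_labels = sum(per_class$n_reason_labels)
    )
  )
}

#' Resolve a terminology entry and its ancestor path
#'
#' @param tree A [terminology_tree()].
#' @param id Entry id; give either `id` or both `level` and `name`.
#' @param level,name Look up by display name within a level.
#' @return A list with `entry` (one-row tibble) and `path`, a tibble of the
#'   ancestors from the class root down to the entry itself.
#' @export
resolve_label <- function(tree, id = NULL, level = NULL, name = NULL) {
  stopifnot(inherits(tree, "terminology_tree"))
  tb <- as_tibble(tree)
  if (!is.null(id)) {
    hit <- tb %>% filter(.data$id == !!id)
  } else if (!is.null(level) && !is.null(name)) {
    hit <- tb %>% filter(.data$level == !!level, .data$name == !!name)
  } else if (!is.null(name)) {
    hit <- tb %>% filter(.data$name == !!name)
    if (nrow(hit) > 1) {
      wsianno_abort("UNKNOWN_TERM",
        paste0("name '", name, "' is ambiguous without a level"))
    }
  } else {
    wsianno_abort("UNKNOWN_TERM", "supply an id, or a (level, name) pair")
  }
  if (nrow(hit) != 1) {
    wsianno_abort("UNKNOWN_TERM", paste0(
      "no terminology entry for ",
      if (!is.null(id)) paste0("id '", id, "'")
      else paste0("(", level %||% "?", ", ", name, ")")
    ))
  }
  path <- hit
  cur <- hit
  while (!is.na(cur$parent_id)) {
    cur <- tb %>% filter(.data$id == cur$parent_id)
    path <- bind_rows(cur, path)
  }
  list(entry = hit, path = path)
}

# ancestor ids of an entry (class first), excluding the entry itself
term_ancestors <- function(tree, id) {
  p <- resolve_label(tree, id = id)$path
  head(p$id, -1)
}

#' Load the bundled colorectal terminology fixture
#'
#' A terminology table with the printed structure of the colorectal
#' decision-to-reason vocabulary: 3 classes, 12 subtypes and 77 reason
#' labels (adenocarcinoma 9 subtypes + 34 reasons, adenoma 2 + 25, normal
#' 1 + 18). Published term names are used where available; the remainder
#' are clearly-flagged synthetic placeholders (the full vocabulary is not
#' publicly deposited), so the fixture tests structure, not nomenclature.
#'
#' @return A [terminology_tree()].
#' @export
crc_terminology <- function() {
  path <- system.file("extdata", "terminology_crc_synthetic.tsv", package = "wsianno")
  load_terminology(path)
}
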