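#' Path to the packaged 22-group food taxonomy
#'
#' Returns the path of the YAML taxonomy shipped with the package: 22 food
#' groups (11 heart-protective, 11 discouraged) mapping Oxford WebQ-style 24 h
#' recall items to groups, with per-group serve sizes and scoring directions.
#'
#' @return file path of the packaged taxonomy YAML.
#' @export
hpds_taxonomy_file <- function() {
  system.file("extdata", "hpds_taxonomy.yaml", package = "hpds", mustWork = TRUE)
}

#' Load and validate a food-group taxonomy
#'
#' Reads a YAML taxonomy config (groups with scoring `direction` of +1 or -1,
#' `serve_size_g` in grams per serve, and an `items` list) and validates its
#' structural invariants: item identifiers unique across the whole taxonomy,
#' directions exactly +1 or -1, positive serve sizes, and -- for the full
#' heart-protective score -- exactly 22 groups split 11/11 by direction.
#' Item identifiers are slugified from the item names (see [slugify()]).
#'
#' @param path taxonomy YAML file; defaults to the packaged 22-group taxonomy.
#' @param check_group_count if `TRUE` (default) require exactly 22 groups with
#'   an 11/11 direction split; set `FALSE` to load reduced taxonomies, e.g.
#'   for toy examples.
#' @return an object of class `hpds_taxonomy`: a list with elements `name`,
#'   `groups` (data.frame: group_id, name, direction, serve_size_g, n_items),
#'   `items` (data.frame: item_id, item_name, group_id), and `ignore_items`
#'   (character vector of item identifiers excluded from scoring).
#' @examples
#' tax <- load_taxonomy()
#' nrow(tax$groups)         # 22
#' table(tax$groups$direction)
#' @export
load_taxonomy <- function(path = hpds_taxonomy_file(), check_group_count = TRUE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || !length(cfg$groups)) {
    hpds_error("taxonomy config has no 'groups' entry", "hpds_taxonomy_error")
  }
  groups <- do.call(rbind, lapply(cfg$groups, function(g) {
    for (f in c("group_id", "direction", "serve_size_g", "items")) {
      if (is.null(g[[f]])) {
        hpds_error(sprintf("group '%s' is missing field '%s'",
                           if (is.null(g$group_id)) "<unnamed>" else g$group_id, f),
                   "hpds_taxonomy_error")
      }
    }
    data.frame(
      group_id = g$group_id,
      name = if (is.null(g$name)) g$group_id else g$name,
      direction = as.integer(g$direction),
      serve_size_g = as.numeric(g$serve_size_g),
      n_items = length(g$items),
      stringsAsFactors = FALSE
    )
  }))
  items <- do.call(rbind, lapply(cfg$groups, function(g) {
    data.frame(
      item_id = slugify(unlist(g$items)),
      item_name = unlist(g$items),
      group_id = g$group_id,
      stringsAsFactors = FALSE
    )
  }))
  tax <- structure(
    list(
      name = if (is.null(cfg$name)) "taxonomy" else cfg$name,
      groups = groups,
      items = items,
      ignore_items = as.character(unlist(cfg$ignore_items))
    ),
    class = "hpds_taxonomy"
  )
  validate_taxonomy(tax, check_group_count = check_group_count)
  tax
}

#' Validate taxonomy invariants
#'
#' @param tax an `hpds_taxonomy` object.
#' @inheritParams load_taxonomy
#' @return `tax`, invisibly; signals a classed error on any violation.
#' @export
validate_taxonomy <- function(tax, check_group_count = TRUE) {
  groups <- tax$groups
  if (anyDuplicated(groups$group_id)) {
    hpds_error("duplicate group_id in taxonomy", "hpds_taxonomy_error")
  }
  bad_dir <- !groups$direction %in% c(-1L, 1L)
  if (any(bad_dir)) {
    hpds_error(sprintf("direction must be +1 or -1; offending group(s): %s",
                       paste(groups$group_id[bad_dir], collapse = ", ")),
               "hpds_taxonomy_error")
  }
  if (any(!is.finite(groups$serve_size_g) | groups$serve_size_g <= 0)) {
    bad <- groups$group_id[!is.finite(groups$serve_size_g) | groups$serve_size_g <= 0]
    hpds_error(sprintf("serve_size_g must be > 0; offending group(s): %s",
                       paste(bad, collapse = ", ")), "hpds_taxonomy_error")
  }
  dup <- tax$items$item_id[duplicated(tax$items$item_id)]
  if (length(dup)) {
    owners <- tax$items[tax$items$item_id %in% dup, c("item_id", "group_id")]
    hpds_error(sprintf(
      "item(s) assigned to more than one group: %s",
      paste(sprintf("%s (%s)", owners$item_id, owners$group_id), collapse = "; ")
    ), "hpds_structural_error")
  }
  if (length(intersect(tax$items$item_id, tax$ignore_items))) {
    hpds_error("an item cannot be both scored and on the ignore list",
               "hpds_structural_error")
  }
  if (check_group_count) {
    if (nrow(groups) != 22L) {
      hpds_error(sprintf("expected 22 food groups, found %d", nrow(groups)),
                 "hpds_taxonomy_error")
    }
    if (sum(groups$direction == 1L) != 11L) {
      hpds_error(sprintf(
        "expected 11 groups of each direction, found %d positive / %d negative",
        sum(groups$direction == 1L), sum(groups$direction == -1L)
      ), "hpds_taxonomy_error")
    }
  }
  invisible(tax)
}

#' @export
print.hpds_taxonomy <- function(x, ...) {
  cat(sprintf("<hpds_taxonomy> %s: %d groups (%d positive, %d negative), %d items\n",
              x$name, nrow(x$groups), sum(x$groups$direction == 1),
              sum(x$groups$direction == -1), nrow(x$items)))
  invisible(x)
}

#' Read a 24 h recall table
#'
#' Reads a CSV/TSV with columns `participant_id`, `recall_index`, `item_id`,
#' `amount_g` (grams, or mL for drinks, consumed in one 24 h window) and
#' validates nonnegative amounts and uniqueness of
#' (participant, recall occasion, item).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @return a validated recall data.frame.
#' @export
read_recalls <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  validate_recalls(utils::read.table(path, sep = sep, header = TRUE,
                                     stringsAsFactors = FALSE))
}

#' Validate a recall table
#'
#' @param recalls data.frame with columns `participant_id`, `recall_index`,
#'   `item_id`, `amount_g`.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_recalls <- function(recalls) {
  check_columns(recalls, c("participant_id", "recall_index", "item_id", "amount_g"),
                "recall table")
  if (any(!is.finite(recalls$amount_g) | recalls$amount_g < 0)) {
    hpds_error("recall amounts must be finite and >= 0", "hpds_recall_error")
  }
  key <- paste(recalls$participant_id, recalls$recall_index, recalls$item_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    hpds_error("duplicate (participant, recall_index, item) rows in recall table",
               "hpds_recall_error")
  }
  recalls
}

#' Aggregate item-level recalls to group-level weekly intakes
#'
#' Maps each recall item to its taxonomy food group and converts 24 h amounts
#' to grams/week (one 24 h recall contributes `amount * 7`). Items on the
#' taxonomy's ignore list (or in `extra_ignore`) are dropped; any other
#' unmapped item is an error naming the offending identifiers.
#'
#' Two recall policies are supported. With `"earliest"` (the default, which
#' maximises downstream follow-up time) only each participant's lowest
#' `recall_index` occasion is used. With `"mean_of_first_k"` the per-group
#' weekly amounts of the available occasions with `recall_index <= k` are
#' averaged.
#'
#' @param recalls recall data.frame (see [read_recalls()]).
#' @param taxonomy an `hpds_taxonomy`.
#' @param recall_policy `"earliest"` or `"mean_of_first_k"`.
#' @param k number of occasions averaged under `"mean_of_first_k"`.
#' @param extra_ignore additional item identifiers to drop without error.
#' @return a numeric matrix (participants x groups, grams/week) with
#'   participant identifiers as row names and taxonomy `group_id`s as column
#'   names, in taxonomy order; class `hpds_intake`.
#' @export
aggregate_group_intake <- function(recalls, taxonomy,
                                   recall_policy = c("earliest", "mean_of_first_k"),
                                   k = 3, extra_ignore = character()) {
  recall_policy <- match.arg(recall_policy)
  recalls <- validate_recalls(recalls)
  stopifnot(inherits(taxonomy, "hpds_taxonomy"))

  ignore <- c(taxonomy$ignore_items, extra_ignore)
  recalls <- recalls[!recalls$item_id %in% ignore, , drop = FALSE]
  unmapped <- setdiff(unique(recalls$item_id), taxonomy$items$item_id)
  if (length(unmapped)) {
    hpds_error(sprintf("recall item(s) not in taxonomy and not ignored: %s",
                       paste(sort(unmapped), collapse = ", ")),
               "hpds_mapping_error")
  }

  participants <- sort(unique(recalls$participant_id))
  group_ids <- taxonomy$groups$group_id
  out <- matrix(0, nrow = length(participants), ncol = length(group_ids),
                dimnames = list(participants, group_ids))
  if (!nrow(recalls)) {
    class(out) <- c("hpds_intake", class(out))
    return(out)
  }

  recalls$group_id <- taxonomy$items$group_id[
    match(recalls$item_id, taxonomy$items$item_id)]

  if (recall_policy == "earliest") {
    first <- stats::ave(recalls$recall_index, recalls$participant_id, FUN = min)
    used <- recalls[recalls$recall_index == first, , drop = FALSE]
    agg <- stats::aggregate(amount_g ~ participant_id + group_id, used, sum)
    out[cbind(match(agg$participant_id, participants),
              match(agg$group_id, group_ids))] <- 7 * agg$amount_g
  } else {
    used <- recalls[recalls$recall_index <= k, , drop = FALSE]
    # weekly total per participant x occasion x group, then average occasions
    agg <- stats::aggregate(amount_g ~ participant_id + recall_index + group_id,
                            used, sum)
    n_occ <- stats::aggregate(
      recall_index ~ participant_id,
      unique(used[c("participant_id", "recall_index")]),
      length
    )
    per_group <- stats::aggregate(amount_g ~ participant_id + group_id, agg, sum)
    per_group$n_occ <- n_occ$recall_index[
      match(per_group$participant_id, n_occ$participant_id)]
    out[cbind(match(per_group$participant_id, participants),
              match(per_group$group_id, group_ids))] <-
      7 * per_group$amount_g / per_group$n_occ
    # participants seen only at occasions > k keep all-zero rows
    only_late <- setdiff(participants, used$participant_id)
    if (length(only_late)) {
      warning(sprintf("%d participant(s) have no recall occasion <= %d; rows are zero",
                      length(only_late), k), call. = FALSE)
    }
  }
  class(out) <- c("hpds_intake", class(out))
  out
}
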