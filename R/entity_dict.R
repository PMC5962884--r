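ENTITY_GROUPS <- c("parent_company", "foundation", "institute_bihw",
                   "north_america", "subsidiary_participating",
                   "subsidiary_nonparticipating", "other_cola")

# Groups whose funding places a study inside the transparency-participating
# brand perimeter (parent company, foundation, research institute, North
# American arm, and subsidiaries that published transparency lists).
PARTICIPATING_GROUPS <- c("parent_company", "foundation", "institute_bihw",
                          "north_america", "subsidiary_participating")

#' Read a funder entity dictionary
#'
#' The dictionary maps every textual variant of a funder entity (parent
#' company, foundation, research institute, regional subsidiaries,
#' confounder brands such as other colas) to a canonical name and a group
#' label that drives screening and brand-eligibility decisions.
#'
#' @param path YAML file with an `entities` list; each entity has
#'   `canonical`, `group` (one of `r paste(ENTITY_GROUPS, collapse = ", ")`)
#'   and `variants`.
#' @return A tibble with columns `canonical`, `group`, `variant`,
#'   `variant_folded`, ordered longest-variant first.
#' @export
read_entity_dictionary <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  spec <- yaml::read_yaml(path)
  if (is.null(spec$entities)) abort("entity dictionary lacks an 'entities' key")
  rows <- purrr::map_dfr(spec$entities, function(e) {
    if (is.null(e$variants) || length(e$variants) == 0) {
      abort(sprintf("entity %s has no variants", e$canonical %||% "?"))
    }
    if (!(e$group %in% ENTITY_GROUPS)) {
      abort(sprintf("unknown entity group: %s", e$group))
    }
    tibble::tibble(canonical = e$canonical, group = e$group,
                   variant = unlist(e$variants))
  })
  rows$variant_folded <- fold_chr(rows$variant)
  if (anyDuplicated(rows$variant_folded)) {
    dup <- rows$variant[duplicated(rows$variant_folded)]
    abort(paste0("variant not unique across entities: ", paste(dup, collapse = ", ")))
  }
  rows[order(-nchar(rows$variant_folded)), ]
}

#' The packaged default entity dictionary
#'
#' Loads the dictionary shipped in `inst/extdata/entity_dictionary.yaml`,
#' covering the cola-brand funder universe used throughout the package.
#'
#' @return See [read_entity_dictionary()].
#' @export
default_entity_dictionary <- function() {
  read_entity_dictionary(system.file("extdata", "entity_dictionary.yaml",
                                     package = "fundaudit", mustWork = TRUE))
}
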