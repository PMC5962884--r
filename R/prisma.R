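#' Summarise screening decisions as a conserving PRISMA-style ledger
#'
#' Each stage's decisions are tallied into input / included / excluded counts
#' with per-reason breakdowns. Conservation (`input = included + excluded`
#' and reason tallies summing to the exclusions) is asserted at every stage;
#' a violation indicates a pipeline bug and is fatal.
#'
#' @param stages Ordered, named list of decision tibbles (columns
#'   `record_id`, `stage`, `included`, `reason_code`), e.g. the `decisions`
#'   elements produced by the screening functions.
#' @return A `prisma_summary` object: a tibble with one row per stage
#'   (`stage`, `n_in`, `n_included`, `n_excluded`, `reasons` as a compact
#'   string) and the full reason tally in `attr(, "reasons")`.
#' @export
prisma_summary <- function(stages) {
  if (is.data.frame(stages)) stages <- split(stages, stages$stage)
  rows <- purrr::map_dfr(stages, function(d) {
    n_in <- nrow(d)
    n_inc <- sum(d$included)
    n_exc <- sum(!d$included)
    if (n_in != n_inc + n_exc) abort("PRISMA conservation violated: input != included + excluded")
    if (any(d$included & d$reason_code != "included")) {
      abort("included decision carries an exclusion reason")
    }
    if (any(!d$included & d$reason_code == "included")) {
      abort("PRISMA conservation violated: excluded decision lacks a reason code")
    }
    tal <- table(d$reason_code[!d$included])
    if (sum(tal) != n_exc) abort("PRISMA conservation violated: reason tallies")
    tibble::tibble(
      stage = d$stage[1] %||% "empty",
      n_in = n_in, n_included = n_inc, n_excluded = n_exc,
      reasons = paste(sprintf("%s=%d", names(tal), as.integer(tal)), collapse = "; ")
    )
  })
  reasons <- purrr::map_dfr(stages, function(d) {
    excl <- d[!d$included, ]
    if (nrow(excl) == 0) return(tibble::tibble())
    dplyr::count(excl, .data$stage, .data$reason_code, name = "n")
  })
  structure(rows, reasons = reasons, class = c("prisma_summary", class(rows)))
}

#' @export
print.prisma_summary <- function(x, ...) {
  cat("PRISMA ledger (input = included + excluded at every stage)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-24s %5d -> %5d  (excluded %d%s)\n", x$stage[i],
                x$n_in[i], x$n_included[i], x$n_excluded[i],
                if (nzchar(x$reasons[i])) paste0(": ", x$reasons[i]) else ""))
  }
  invisible(x)
}

#' Export a PRISMA summary
#'
#' @param summary A `prisma_summary`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_prisma <- function(summary, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(stages = as.data.frame(summary),
           reasons = as.data.frame(attr(summary, "reasons"))),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
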